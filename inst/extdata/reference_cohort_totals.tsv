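key	value
n_trios	12252
mother_events	43
father_events	44
transmitted_maternal	24
transmitted_paternal	15
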