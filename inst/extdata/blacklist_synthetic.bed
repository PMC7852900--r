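1	0	500000	tel_1p
1	121000000	125000000	cen_1
1	248750621	249250621	tel_1q
3	0	500000	tel_3p
3	90000000	94000000	cen_3
3	197522430	198022430	tel_3q
7	0	500000	tel_7p
7	57500000	62000000	cen_7
7	158638663	159138663	tel_7q
15	0	19000000	acro_cen_15
15	102031392	102531392	tel_15q
16	0	500000	tel_16p
16	34500000	47000000	cen_16
16	89854753	90354753	tel_16q
17	0	500000	tel_17p
17	22000000	25800000	cen_17
17	80695210	81195210	tel_17q
22	0	16000000	acro_cen_22
22	50804566	51304566	tel_22q
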