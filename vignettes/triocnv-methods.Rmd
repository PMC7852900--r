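---
title: "Methods: trio-based detection and inheritance analysis of recurrent NDD CNVs"
author: "triocnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio-based detection and inheritance analysis of recurrent NDD CNVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triocnv)
```

# Scope and overall design

`triocnv` analyses recurrent copy number variants (CNVs) at 13 genomic
regions implicated in neurodevelopmental disorders (NDDs) in
mother–father–child trios genotyped on SNP arrays. These regions are
flanked by low-copy repeats and are recurrently rearranged by nonallelic
homologous recombination (NAHR), so events in different individuals share
breakpoints and can be treated as alleles of a common locus.

The package has two complementary modes:

* **Counts mode**: all population statistics (prevalence with Wilson
  score intervals, deletion-vs-duplication two-proportion Z-tests,
  transmission disequilibrium tests) computed directly from a count
  table. The packaged tables (`reference_region_counts()`,
  `reference_cohort_totals()`) carry the per-region and cohort-level
  counts observed in a reference population cohort of 12,252 newborn
  trios, making those published counts a first-class input that needs no
  raw signal data.
* **Signal mode**: a full pipeline from per-marker Log R Ratio (LRR) and
  B Allele Frequency (BAF) values to the same tables — HMM segmentation,
  fragment merging, quality control with a trio-level gate, population
  filters, NDD-region matching, inheritance classification,
  parent-of-origin inference and mosaic-fraction estimation.

Because raw genotype data of such cohorts is access-controlled, signal
mode is exercised on synthetic cohorts with known ground truth; the
simulator is first-class, tested code.

# The synthetic-trio generator

## What it emulates

* **Marker maps.** Markers are placed by a piecewise-uniform density:
  NDD regions are boosted (default 60× background, topped up to at least
  20 markers), each region is flanked by a moderately dense window
  (default 1.5 Mb at 8×), and the remaining genome is sparse background.
  This emulates the region-focused economy of the analysis while keeping
  realistic marker resistance at the breakpoints: with a purely sparse
  background a decoded boundary can jump across a "marker desert" to a
  single distant marker, something that cannot happen on a real dense
  array. Per-marker population B-allele frequencies (pfb) are uniform on
  (0.05, 0.95).
* **Genotypes.** Parental haplotypes are Hardy–Weinberg draws at the
  marker pfb; each child allele is one transmitted maternal plus one
  transmitted paternal allele with the transmitted homolog recorded.
  Transmission is drawn per marker (free recombination): adequate for the
  diploid background, while implanted events impose the within-span
  consistency themselves.
* **Events.** Per (region, class): parental carriers appear with a
  configured carrier rate and transmit with a configured probability;
  de novo child events appear with a configured rate and parental origin.
  Deletions are CN1 and duplications CN3 by default (`implant_cnv()` also
  supports CN0 and CN4). A configurable fraction of de novo duplications
  is mosaic with cell fraction drawn uniformly (default 0.4–0.8).
  Breakpoints extend the reference region boundary by up to 40 kb of
  uniform jitter, emulating breakpoint spread inside the flanking
  low-copy repeats. The default rates are calibrated to the reference
  cohort: de novo rates are observed counts / 12,252; parental carrier
  rates are inherited-child counts divided by 12,252 and by the global
  transmission rates (24/43 maternal, 15/44 paternal), so expected totals
  match the observed 43 maternal and 44 paternal events; the de novo
  fraction of child events is then the observed 20/59.
* **Signals.** `LRR = state mean + wave + Gaussian noise`, with state
  means per copy number 0..4 of (−3.5, −0.66, 0, 0.40, 0.68) — the
  conventional array calibration — and linear interpolation at
  fractional (mosaic) copy number. `BAF = B/(A+B) + truncated Gaussian
  noise` clipped to [0, 1]; markers with zero copies, and a small
  outlier fraction, get uniform BAF. A mosaic gain of fraction *f*
  therefore shows heterozygous bands at 1/(2+f) and (1+f)/(2+f). Default
  noise: LRR SD 0.12 (sample-level LRR SDs near the ~0.1 reported for
  well-behaved arrays), BAF SD 0.03, outlier rate 0.002, wave amplitude
  0.01 with 40 Mb period.

## What it does not emulate

No GC-content-driven waves (the wave is a pure sinusoid), no
batch/cluster-file artifacts, no genotyping-error model beyond BAF noise
and outliers, no sex chromosomes (all 13 regions are autosomal), no
linkage disequilibrium or realistic recombination maps, and no nested
atypical events within regions. Passing tests on these cohorts therefore
demonstrate the correctness of the algorithms under the stated noise
model, not calling performance on any particular real array product.

# The CNV caller

A six-state hidden Markov model per sample and chromosome: CN0, CN1, CN2
(neutral), CN2-LOH (copy-neutral loss of heterozygosity), CN3, CN4.

* **Emissions.** LRR is Gaussian per state (means as above, SD 0.2; CN0
  uses 0.35 since deleted probes behave erratically). BAF is a mixture of
  genotype bands — {0,1} for CN1 and CN2-LOH, {0,½,1} for CN2, quarters
  and thirds for CN4/CN3 — weighted by binomial functions of the marker
  pfb, with a uniform outlier component (weight 0.01). Observations at
  exactly 0 or 1 use the clipped tail mass of each band instead of a
  density, so boundary observations are handled consistently across
  states.
* **Transitions.** P(state change between markers at distance *d*) =
  ε·(1 − exp(−d/D)) with ε = 10⁻⁴ and D = 100 kb, split uniformly over
  the five non-self states. Two tunables give the distance awareness
  that makes short noise blips expensive and real multi-marker segments
  cheap.
* **Decoding.** Exact Viterbi; ties are broken toward CN2, so the caller
  is conservative under exact score equality. The decoded path is
  verified in the tests against exhaustive enumeration over all 6ⁿ state
  paths on instances of up to 8 markers — the enumerator is a separate
  code path kept as an independent oracle. Maximal non-CN2 runs become
  calls; CN2-LOH runs are decoded (so they are not absorbed into
  flanking states) but dropped from the output, since the downstream
  analyses concern deletions and duplications only.
* **Merging.** Adjacent same-state fragments merge when
  gap/merged-span ≤ 0.20, iterated to a fixpoint.
* **Breakpoint refinement.** Each boundary extends outward while the
  flanking marker's emission log-odds favour the call state over CN2 by a
  margin (default 2); calls never shrink. This automates the manual
  practice of extending a call across flanking signal consistent with a
  continuing CNV.
* **Trio handling.** Samples are decoded independently; trio information
  enters through the classification rules below rather than a joint
  family likelihood. This is a deliberate simplification: the
  recurrent-region analyses need region-level genotypes, not joint
  breakpoints.

# Quality control

Per sample: `lrr_sd` (SD of LRR), `baf_drift` (fraction of markers with
BAF in (0.2, 0.25) ∪ (0.75, 0.8) — the conventional off-band windows),
`wf` (signed wave factor: amplitude of a least-squares sinusoid fitted to
LRR along the genome, signed by its sine coefficient), and `n_calls`
(post-merge, pre-filter call count). A trio passes only when all three
members satisfy `lrr_sd < 0.3`, `baf_drift < 0.001`, `|wf| < 0.05`,
`n_calls < 100` (a denser-array batch uses `n_calls < 130`).

One design choice matters on region-focused maps: a sample's own called
spans are excluded from its `lrr_sd`, `baf_drift` and `wf`. On real
arrays CNV spans are a negligible fraction of markers, but on a compact
map a genuine 5.8 Mb duplication would dominate its carrier's noise
statistics and make QC failure correlate with carrier status — a
prevalence bias, not a quality judgement. The gate is monotone: tightening
any threshold never converts a failing trio into a passing one
(property-tested).

# Population filters and region matching

1. **Parental frequency.** Calls are clustered by ≥ 50% reciprocal
   overlap within class (union-find over the overlap graph); a cluster's
   frequency is distinct parental carriers / number of parents, and
   clusters above 1% are removed cohort-wide. Only parents contribute to
   the denominator and numerator — offspring-only variants always
   survive.
2. **Blacklist.** Any 1-bp overlap with a packaged blacklist
   (centromeric/telomeric windows and the acrocentric p-arms for the
   seven chromosomes carrying NDD regions; a synthetic stand-in for the
   usual exclusion tracks) removes the call.
3. **Size.** Calls must span ≥ 100 kb and ≥ 10 markers.
4. **Region matching.** A call matches an NDD region when it covers at
   least 50% of the region's span; deletions (CN < 2) and duplications
   are matched separately. The packaged GRCh37 coordinates reproduce the
   published region lengths to 6 decimals.

# Inheritance, parent of origin, and mosaicism

* **Inheritance.** A child call is inherited from a parent carrying a
  same-class call with ≥ 50% reciprocal overlap; neither parent → de
  novo; both parents → flagged ambiguous and excluded from per-parent
  tallies (observed cohorts contain no such case; guessing would be
  worse than flagging).
* **Deletion origin.** At each CN1 marker the retained allele is tested
  against both parents; a parent that could not have transmitted it
  identifies the deleted homolog as coming from the *other* parent's
  side — i.e. the deletion arose on the homolog of the parent that fails
  the test. Verdicts aggregate by majority with ≥ 3 informative markers
  and ≥ 80% concordance, otherwise unresolved.
* **Duplication origin.** At each CN3 marker the child's three-allele
  count vector is tested against "duplicated pair from mother + one
  paternal allele" and the mirror hypothesis. By default the duplicated
  pair may combine both homologs of the origin parent (interchromosomal
  NAHR); a strict same-allele mode is available. One hypothesis only →
  informative; both → uninformative; neither → inconsistent. An
  inconsistent rate above 10% of assessed markers raises an integrity
  warning (a genotyping-error proxy). CN4 events are left unresolved
  with a warning.
* **Allele counts from signals.** In signal mode, allele counts come
  from BAF band assignment: nearest band k/cn within tolerance 0.08,
  markers outside tolerance discarded. The tolerance is ~2.7 noise SDs
  at the default BAF SD, so mis-assignment is rare and discarded markers
  cost information rather than correctness.
* **Mosaic fraction.** For a duplication call, folded BAF values in the
  heterozygous-band window are averaged robustly (10% trimmed mean) to
  estimate the lower band centre b, inverted as f = 1/b − 2 and clipped
  to [0, 1]; the event is reported mosaic for 0 < f < 0.9. The window is
  (1/3 − 0.025, 0.5] rather than the naive (0.2, 0.5): gains whose extra
  copy differs from a homozygous base genotype emit a second band at
  f/(2+f), which enters (0.2, 0.5) for f ≳ 0.55 and would bias the
  estimate upward by ~0.08 at f = 0.7; the theoretical heterozygous band
  1/(2+f) always lies in [1/3, 0.5), so the tighter window removes the
  contaminant without losing signal.

# Statistics

Prevalence is events / QC-passing trios. The Wilson score interval is
used throughout because it behaves well at the small counts typical of
per-region rows — the lower bound is exactly 0 at zero events (upper
bound ≈ 3·10⁻⁴ at n = 12,252) and the interval always contains the point
estimate. Deletions and duplications are compared with the pooled
two-proportion Z-test. Transmission is tested with the classic
one-degree-of-freedom TDT chi-square (T − NT)²/(T + NT); an exact
binomial option exists but is not the default, as the chi-square form is
what reproduces the published transmission p-values (0.03 paternal, 0.33
combined). No multiple-testing correction is applied, matching the
descriptive character of the tables. Report rounding (prevalence per
10,000 to 2 decimals, Z to 2, p to 2 significant figures) is applied only
at output; full precision is kept internally.

```{r example-stats}
wilson_ci(59, 12252) * 1e4        # per 10,000
two_prop_z(12, 12252, 27, 12252)  # inherited deletions vs duplications
tdt(15, 44)                       # paternal transmission
```

# Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere inside the package; BED
  conversion happens only at the file boundary.
* Emission densities below exp(−24.5) within a band are treated as 0;
  the uniform outlier component keeps every marker's total emission
  positive.
* `wilson_ci`, `two_prop_z` and `tdt` validate their inputs and refuse
  degenerate cases (n = 0; pooled proportion 0 or 1) rather than
  returning NaN.
* Empty call sets flow through every filter and table builder, producing
  all-zero tables whose intervals still have informative upper bounds.
* All randomness is seed-controlled; cohorts are reproducible
  bit-for-bit given (config, seed), and seeded helpers restore the
  caller's RNG state.

# Validation studies and problem sizes

The test suite runs four simulation studies, sized to exercise the full
pipeline at meaningful scale:

* **Caller recovery**: 100 replicates of a 1 Mb event (~50 markers, LRR
  SD 0.15, alternating CN1/CN3); ≥ 95% must be recovered as a single
  call of the right state with both boundaries within 2 markers, and
  noise-free diploid samples must produce zero calls.
* **Decoder oracle**: Viterbi output equals exhaustive 6ⁿ enumeration on
  200 random instances of 2–8 markers.
* **Parent-of-origin recovery**: 500 de novo events (250-marker spans,
  BAF SD 0.02) classified from BAF-derived allele counts; among events
  with ≥ 20 informative markers, ≥ 99% must recover the implanted
  origin.
* **Prevalence coverage**: 50 cohorts of 2,000 trios at the
  reference-calibrated rates, compact maps of 1,600 markers; the
  pipeline's 95% Wilson interval must cover the configured true rate in
  ≥ 90% of runs, and pooled inherited/de novo labels must agree with
  truth in ≥ 99% of recovered events.

# Known limitations

* Joint trio decoding (a family-likelihood HMM) is not implemented;
  de novo evidence comes from post-hoc classification, which on real,
  noisier data would be less sensitive than joint decoding.
* The QC wave factor assumes the configured wave period; waves at very
  different periods are only partially captured.
* The frequency filter's cluster semantics (50% reciprocal overlap) is
  one reasonable choice among several used in practice; with the
  recurrent, breakpoint-sharing events analysed here the clusters are
  unambiguous.
* Mosaic detection covers the two-band gain mixture only; isodicentric
  CN4 mosaics and mosaic losses are out of scope.
* The simulator's economies (compact maps, free recombination, pure
  sinusoid waves) are stated above; conclusions about real-array
  sensitivity and specificity require real intensity data.
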