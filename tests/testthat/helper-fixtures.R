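# shared fixtures, all built in code

zero_noise <- function() {
  noise_model(lrr_sd = 0, baf_sd = 0, outlier_rate = 0, wave_amplitude = 0)
}

# evenly spaced deterministic marker map on one chromosome
even_map <- function(n, len = 1e7, chrom = "1", pfb = NULL, seed = 1) {
  pos <- round(seq(len / (n + 1), len * n / (n + 1), length.out = n))
  if (is.null(pfb)) pfb <- withr::with_seed(seed, runif(n, 0.05, 0.95))
  data.frame(name = sprintf("m%05d", seq_len(n)), chrom = chrom,
             position = pos, pfb = pfb, stringsAsFactors = FALSE)
}

# hand-built single-trio genotypes from per-marker haplotype vectors
# (0 = A, 1 = B); child transmitted alleles default to homolog 1 of each
# parent
toy_geno <- function(map, mother_h1, mother_h2, father_h1, father_h2,
                     mat_hom = NULL, pat_hom = NULL) {
  n <- nrow(map)
  m <- function(x) matrix(as.integer(x), nrow = n, ncol = 1)
  mat_hom <- mat_hom %||% rep(1L, n)
  pat_hom <- pat_hom %||% rep(1L, n)
  mh1 <- m(mother_h1); mh2 <- m(mother_h2)
  fh1 <- m(father_h1); fh2 <- m(father_h2)
  cm <- ifelse(mat_hom == 1L, mh1, mh2)
  cp <- ifelse(pat_hom == 1L, fh1, fh2)
  structure(list(
    map = map,
    trios = data.frame(family = "T1", child = "T1_c", father = "T1_f",
                       mother = "T1_m", stringsAsFactors = FALSE),
    mother_h1 = mh1, mother_h2 = mh2, father_h1 = fh1, father_h2 = fh2,
    child_mat = m(cm), child_pat = m(cp),
    child_mat_hom = m(mat_hom), child_pat_hom = m(pat_hom)),
    class = "trio_genotypes")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-event truth row
event_row <- function(carrier, start, end, cn, origin = "maternal",
                      mode = "de_novo", mosaic = 1, chrom = "1",
                      region = "R1") {
  data.frame(region = region, chrom = chrom, start = start, end = end,
             carrier = carrier, copy_number = cn, origin_parent = origin,
             mode = mode, mosaic_fraction = mosaic, stringsAsFactors = FALSE)
}

# a small cohort config with inflated rates so that events are plentiful
quick_config <- function(n_trios = 200, rate_scale = 30, ...) {
  rates <- default_region_rates()
  rates$denovo_rate <- pmin(rates$denovo_rate * rate_scale, 0.5)
  rates$maternal_carrier_rate <- pmin(rates$maternal_carrier_rate * rate_scale, 0.5)
  rates$paternal_carrier_rate <- pmin(rates$paternal_carrier_rate * rate_scale, 0.5)
  cohort_config(n_trios = n_trios, region_rates = rates,
                n_markers = 1500, region_boost = 40, flank_bp = 1e6,
                flank_boost = 6, min_region_markers = 18, ...)
}

# canonical call table row
call_row <- function(sample, start, end, cn, chrom = "1", n_markers = 20,
                     mean_lrr = 0) {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             copy_number = cn, n_markers = n_markers, mean_lrr = mean_lrr,
             stringsAsFactors = FALSE)
}
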