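#' Construct an array-noise model
#'
#' Describes the stochastic components of SNP-array intensity signals:
#' Gaussian LRR noise, within-band BAF noise (truncated to \[0, 1\]), a
#' long-range sinusoidal LRR wave artifact, and sporadic outlier markers
#' whose BAF is uniform.
#'
#' @param lrr_sd Standard deviation of per-marker LRR noise. The default
#'   0.12 gives sample-level LRR SDs comparable to a well-behaved array
#'   run (median around 0.1-0.15) and passes the QC gate with margin.
#' @param baf_sd SD of BAF noise around each genotype band.
#' @param outlier_rate Fraction of marker/sample pairs replaced by uniform
#'   BAF (must be < 0.05; the default keeps BAF drift well under the QC
#'   threshold of 0.001).
#' @param wave_amplitude Amplitude of the sinusoidal LRR wave.
#' @param wave_period Wave period in bp (long-range, tens of Mb).
#' @return A `noise_model` list.
#' @export
noise_model <- function(lrr_sd = 0.12, baf_sd = 0.03, outlier_rate = 0.002,
                        wave_amplitude = 0.01, wave_period = 4e7) {
  stopifnot(lrr_sd >= 0, baf_sd >= 0, outlier_rate >= 0,
            wave_amplitude >= 0, wave_period > 0)
  if (outlier_rate >= 0.05) stop("outlier_rate must be < 0.05")
  structure(list(lrr_sd = lrr_sd, baf_sd = baf_sd,
                 outlier_rate = outlier_rate,
                 wave_amplitude = wave_amplitude, wave_period = wave_period),
            class = "noise_model")
}

#' Default LRR means per integer copy-number state
#'
#' PennCNV-like state means; fractional (mosaic) copy numbers are rendered
#' by linear interpolation between the neighbouring integer states.
#' @return Numeric vector of LRR means for copy numbers 0..4.
#' @export
lrr_state_means <- function() {
  c(`0` = -3.5, `1` = -0.66, `2` = 0, `3` = 0.40, `4` = 0.68)
}

# piecewise-linear LRR mean for (possibly fractional) total copy number;
# integer copy numbers (the vast majority) take a direct lookup
lrr_mean_for_cn <- function(cn, means = lrr_state_means()) {
  rng <- range(cn)
  if (rng[1] < -1e-9 || rng[2] > 4 + 1e-9) stop("unknown copy number")
  mm <- unname(means)
  r <- round(cn)
  out <- mm[r + 1L]
  frac <- which(abs(cn - r) > 1e-9)
  if (length(frac)) {
    cf <- cn[frac]
    lo <- floor(cf); w <- cf - lo
    out[frac] <- (1 - w) * mm[lo + 1L] + w * mm[lo + 2L]
  }
  out
}

#' Render LRR/BAF signals from allele copy counts
#'
#' Each marker/sample pair gets `LRR = state mean + wave + noise` where the
#' state mean interpolates [lrr_state_means()] at the total copy number,
#' and `BAF = B / (A + B) + noise` clipped to \[0, 1\] (uniform BAF where
#' the total copy number is 0, and at outlier markers).
#'
#' @param ac An `allele_counts` object (see [implant_cnv()]).
#' @param noise A [noise_model()].
#' @param seed Optional integer seed.
#' @param lrr_means LRR state means for copy numbers 0..4.
#' @return A `signal_set` carrying the map (with `pfb`), with the `truth`
#'   attribute of `ac` propagated.
#' @export
render_signals <- function(ac, noise = noise_model(), seed = NULL,
                           lrr_means = lrr_state_means()) {
  stopifnot(inherits(ac, "allele_counts"))
  total <- ac$A + ac$B
  if (any(total > 4 + 1e-9)) stop("unknown copy number (> 4)")
  with_seed(seed, {
    n <- nrow(total); m <- ncol(total)
    lrr <- matrix(lrr_mean_for_cn(as.vector(total), lrr_means), n, m)
    if (noise$wave_amplitude > 0) {
      phase <- runif(m, 0, 2 * pi)
      wave <- outer(2 * pi * ac$map$position / noise$wave_period,
                    phase, `+`)
      lrr <- lrr + noise$wave_amplitude * sin(wave)
    }
    if (noise$lrr_sd > 0) lrr <- lrr + rnorm(n * m, 0, noise$lrr_sd)

    baf <- ac$B / total           # NaN where the total copy number is 0
    if (noise$baf_sd > 0) {
      baf <- baf + rnorm(n * m, 0, noise$baf_sd)
      baf <- pmin(pmax(baf, 0), 1)
    }
    null <- is.nan(baf)           # CN0 markers carry no allelic signal
    if (noise$outlier_rate > 0)
      null <- null | runif(n * m) < noise$outlier_rate
    baf[null] <- runif(sum(null))
    dimnames(lrr) <- dimnames(baf) <- list(ac$map$name, ac$samples)
    sig <- signal_set(ac$map, lrr, baf)
    attr(sig, "truth") <- attr(ac, "truth")
    sig
  })
}
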