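#' Default sample-level QC thresholds
#'
#' Pass criteria per sample: `lrr_sd < 0.3`, `baf_drift < 0.001`,
#' `|wf| < 0.05`, `n_calls < 100`. Genotyping batches on denser arrays use
#' a higher call-count limit (e.g. `n_calls = 130`).
#'
#' @param lrr_sd,baf_drift,wf,n_calls Threshold values; a sample passes
#'   when each metric is strictly below its threshold (absolute value for
#'   `wf`).
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(lrr_sd = 0.3, baf_drift = 0.001, wf = 0.05,
                          n_calls = 100) {
  list(lrr_sd = lrr_sd, baf_drift = baf_drift, wf = wf, n_calls = n_calls)
}

#' Compute per-sample signal QC metrics
#'
#' Four metrics per sample: `lrr_sd` (SD of autosomal LRR), `baf_drift`
#' (fraction of markers with BAF in the off-band windows
#' `(0.2, 0.25) U (0.75, 0.8)`), `wf` (signed wave factor: amplitude of a
#' least-squares sinusoid of period `wave_period` fitted to LRR along the
#' genome, signed by its sine coefficient) and `n_calls` (CNV calls for
#' the sample, counted post-merge and pre-frequency-filter).
#'
#' When `calls` are supplied, a sample's called spans are excluded from its
#' `lrr_sd`, `baf_drift` and `wf`: the metrics describe the diploid
#' backbone. On real dense arrays CNV spans are a negligible marker
#' fraction, but on region-focused maps a genuine large CNV would
#' otherwise dominate its carrier's noise statistics.
#'
#' @param signals A `signal_set` (>= 100 markers).
#' @param calls Optional CNV call data.frame used for `n_calls` (0 when
#'   absent).
#' @param drift_windows Numeric vector `c(lo1, hi1, lo2, hi2)` of the two
#'   open off-band windows.
#' @param wave_period Period (bp) of the fitted wave.
#' @return data.frame: `sample`, `lrr_sd`, `baf_drift`, `wf`, `n_calls`.
#' @export
compute_qc_metrics <- function(signals, calls = NULL,
                               drift_windows = c(0.2, 0.25, 0.75, 0.8),
                               wave_period = 4e7) {
  stopifnot(inherits(signals, "signal_set"))
  if (nrow(signals$map) < 100L) stop("QC metrics require >= 100 markers")
  x <- signals$map$position
  s1 <- sin(2 * pi * x / wave_period); c1 <- cos(2 * pi * x / wave_period)
  X <- cbind(1, s1, c1)
  XtX_inv <- solve(crossprod(X))
  wf_fit <- XtX_inv %*% crossprod(X, signals$lrr)  # 3 x samples
  amp <- sqrt(wf_fit[2, ]^2 + wf_fit[3, ]^2)
  wf <- sign(wf_fit[2, ]) * amp

  drift <- (signals$baf > drift_windows[1] & signals$baf < drift_windows[2]) |
    (signals$baf > drift_windows[3] & signals$baf < drift_windows[4])
  n_calls <- if (is.null(calls)) rep(0L, length(signals$samples)) else
    vapply(signals$samples, function(s) sum(calls$sample == s), integer(1))
  nm <- nrow(signals$lrr)
  mu <- colMeans(signals$lrr)
  lrr_sd <- sqrt((colSums(signals$lrr^2) - nm * mu^2) / (nm - 1))
  baf_drift <- colMeans(drift)

  # recompute metrics on the diploid backbone for samples with calls
  carriers <- if (is.null(calls)) character(0) else unique(calls$sample)
  for (s in intersect(carriers, signals$samples)) {
    cs <- calls[calls$sample == s, , drop = FALSE]
    inside <- rep(FALSE, nm)
    for (k in seq_len(nrow(cs)))
      inside <- inside | (signals$map$chrom == cs$chrom[k] &
                            signals$map$position >= cs$start[k] &
                            signals$map$position <= cs$end[k])
    keep <- !inside
    if (sum(keep) < 100L) next
    j <- match(s, signals$samples)
    lrr_sd[j] <- sd(signals$lrr[keep, j])
    baf_drift[j] <- mean(drift[keep, j])
    fit <- XtX_cache(X[keep, , drop = FALSE], signals$lrr[keep, j])
    wf[j] <- sign(fit[2]) * sqrt(fit[2]^2 + fit[3]^2)
  }
  data.frame(sample = signals$samples,
             lrr_sd = lrr_sd,
             baf_drift = baf_drift,
             wf = wf,
             n_calls = n_calls,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Trio-level QC gate
#'
#' A trio passes only when all three members pass all four sample-level
#' criteria; failures report each violated (member, metric) pair.
#'
#' @param qc QC metric data.frame from [compute_qc_metrics()].
#' @param pedigree Trio pedigree.
#' @param thresholds [qc_thresholds()] (use `n_calls = 130` for the denser
#'   array batch).
#' @return data.frame: `family`, `pass`, `reasons` (semicolon-separated
#'   `member:metric` strings, empty when passing).
#' @export
apply_trio_gate <- function(qc, pedigree, thresholds = qc_thresholds()) {
  idx <- function(ids) {
    i <- match(ids, qc$sample)
    if (anyNA(i)) stop("missing QC metrics for sample(s): ",
                       paste(ids[is.na(i)], collapse = ", "))
    i
  }
  members <- list(mother = idx(pedigree$mother),
                  father = idx(pedigree$father),
                  child = idx(pedigree$child))
  reasons <- rep("", nrow(pedigree))
  for (role in names(members)) {
    m <- qc[members[[role]], ]
    fail <- cbind(
      LRR_SD = !(m$lrr_sd < thresholds$lrr_sd),
      BAF_drift = !(m$baf_drift < thresholds$baf_drift),
      WF = !(abs(m$wf) < thresholds$wf),
      NumCNV = !(m$n_calls < thresholds$n_calls))
    for (metric in colnames(fail)) {
      hit <- fail[, metric]
      reasons[hit] <- paste0(reasons[hit],
                             ifelse(reasons[hit] == "", "", ";"),
                             role, ":", metric)
    }
  }
  data.frame(family = pedigree$family, pass = reasons == "",
             reasons = reasons, stringsAsFactors = FALSE)
}

# least-squares fit of intercept + sinusoid basis, returning coefficients
XtX_cache <- function(X, y) as.vector(solve(crossprod(X), crossprod(X, y)))
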