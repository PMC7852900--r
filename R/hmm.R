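#' Parameters of the six-state copy-number HMM
#'
#' States are CN0, CN1, CN2 (neutral), CN2-LOH (copy-neutral loss of
#' heterozygosity), CN3 and CN4. Emissions are Gaussian in LRR (per-state
#' mean/SD) and, in BAF, genotype-band mixtures weighted by the marker's
#' population B-allele frequency, with a uniform outlier component.
#' The probability of a state change between markers at distance `d` bp is
#' `eps * (1 - exp(-d / scale))`, split uniformly over the five non-self
#' states; decoding ties are broken toward CN2.
#'
#' @param lrr_means,lrr_sds Length-6 numeric vectors (state order above).
#' @param baf_sd Within-band BAF SD assumed by the emission model.
#' @param outlier_weight Mixture weight of the uniform BAF outlier
#'   component.
#' @param eps Base state-change probability at large distance.
#' @param scale Distance scale `D` (bp) of the transition model.
#' @param init Initial state probabilities.
#' @return An `hmm_params` list.
#' @export
hmm_params <- function(lrr_means = c(-3.5, -0.66, 0, 0, 0.40, 0.68),
                       lrr_sds = c(0.35, 0.2, 0.2, 0.2, 0.2, 0.2),
                       baf_sd = 0.03, outlier_weight = 0.01,
                       eps = 1e-4, scale = 1e5,
                       init = c(0.001, 0.001, 0.995, 0.001, 0.001, 0.001)) {
  stopifnot(length(lrr_means) == 6L, length(lrr_sds) == 6L,
            all(lrr_sds > 0), eps > 0, eps < 1, scale > 0,
            length(init) == 6L, all(init > 0))
  structure(list(lrr_means = lrr_means, lrr_sds = lrr_sds, baf_sd = baf_sd,
                 outlier_weight = outlier_weight, eps = eps, scale = scale,
                 init = init / sum(init)),
            class = "hmm_params")
}

hmm_state_labels <- c("CN0", "CN1", "CN2", "CN2_LOH", "CN3", "CN4")
hmm_state_cn <- c(0L, 1L, 2L, 2L, 3L, 4L)

#' Per-marker emission log-densities
#'
#' @param lrr,baf,pfb Numeric vectors over markers for one sample.
#' @param params [hmm_params()].
#' @return Numeric matrix (markers x 6 states) of log emission densities.
#' @export
emission_matrix <- function(lrr, baf, pfb, params = hmm_params()) {
  m <- emission_logdens_cpp(lrr, baf, pfb, params$lrr_means, params$lrr_sds,
                            params$baf_sd, params$outlier_weight)
  colnames(m) <- hmm_state_labels
  m
}

#' Decode the full state path for one sample on one chromosome
#'
#' @param lrr,baf,pfb,positions Numeric vectors over markers (positions
#'   strictly increasing).
#' @param params [hmm_params()].
#' @return Character vector of state labels per marker.
#' @export
decode_states <- function(lrr, baf, pfb, positions, params = hmm_params()) {
  if (length(lrr) == 0L) stop("empty signal")
  if (is.unsorted(positions, strictly = TRUE)) stop("unsorted markers")
  logem <- emission_matrix(lrr, baf, pfb, params)
  path <- viterbi_decode_cpp(logem, positions, params$eps, params$scale,
                             log(params$init))
  hmm_state_labels[path]
}

#' Segment LRR/BAF signals into CNV calls
#'
#' Runs the six-state Viterbi decoder independently per sample and
#' chromosome and emits maximal runs of non-neutral states as calls.
#' Copy-neutral LOH runs are decoded but dropped from the output (the
#' downstream analyses concern deletions and duplications only).
#'
#' @param signals A `signal_set` whose map carries `pfb`.
#' @param params [hmm_params()].
#' @param keep_loh If `TRUE`, CN2-LOH runs are retained with
#'   `copy_number = 2`.
#' @return CNV call data.frame: `sample`, `chrom`, `start`, `end` (1-based
#'   inclusive marker positions), `copy_number`, `n_markers`, `mean_lrr`.
#' @export
viterbi_segment <- function(signals, params = hmm_params(),
                            keep_loh = FALSE) {
  stopifnot(inherits(signals, "signal_set"))
  if (is.null(signals$map$pfb)) stop("signal map must carry pfb")
  if (nrow(signals$map) == 0L) stop("empty signal")
  out <- list()
  for (cc in unique(signals$map$chrom)) {
    idx <- which(signals$map$chrom == cc)
    pos <- signals$map$position[idx]
    if (is.unsorted(pos, strictly = TRUE)) stop("unsorted markers")
    seg <- segment_samples_cpp(
      signals$lrr[idx, , drop = FALSE], signals$baf[idx, , drop = FALSE],
      pos, signals$map$pfb[idx], params$lrr_means, params$lrr_sds,
      params$baf_sd, params$outlier_weight, params$eps, params$scale,
      log(params$init))
    if (length(seg$sample_idx) == 0L) next
    out[[cc]] <- data.frame(
      sample = signals$samples[seg$sample_idx],
      chrom = cc,
      start = pos[seg$start_idx],
      end = pos[seg$end_idx],
      state = hmm_state_labels[seg$state],
      copy_number = hmm_state_cn[seg$state],
      n_markers = seg$n_markers,
      mean_lrr = seg$mean_lrr,
      stringsAsFactors = FALSE)
  }
  calls <- if (length(out)) do.call(rbind, out) else
    cbind(empty_calls(), state = character(0))
  if (!keep_loh) calls <- calls[calls$state != "CN2_LOH", , drop = FALSE]
  rownames(calls) <- NULL
  calls[c("sample", "chrom", "start", "end", "copy_number", "n_markers",
          "mean_lrr")]
}
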