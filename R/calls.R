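#' Merge adjacent CNV fragments
#'
#' Two neighbouring calls of the same sample, chromosome and copy number
#' are merged when the gap between them is a small fraction of the merged
#' span: `gap_length / merged_span <= gap_fraction`. Merging is applied
#' iteratively until a fixpoint, so chains of fragments collapse.
#'
#' @param calls CNV call data.frame (see [viterbi_segment()]).
#' @param gap_fraction Maximal gap-to-span ratio (default 0.20).
#' @param map Optional marker map; if given, `n_markers` of merged calls is
#'   recomputed from the map (markers in the gap count), otherwise marker
#'   counts are summed.
#' @return Merged call data.frame.
#' @export
merge_adjacent <- function(calls, gap_fraction = 0.2, map = NULL) {
  if (nrow(calls) == 0L) return(calls)
  # overlapping same-sample calls of different copy number are malformed
  for (s in unique(calls$sample)) {
    cs <- calls[calls$sample == s, , drop = FALSE]
    hits <- GenomicRanges::findOverlaps(as_granges_calls(cs),
                                        drop.self = TRUE,
                                        drop.redundant = TRUE)
    if (any(cs$copy_number[S4Vectors::queryHits(hits)] !=
            cs$copy_number[S4Vectors::subjectHits(hits)]))
      stop("overlapping calls of different copy number for sample ", s)
  }
  key <- paste(calls$sample, calls$chrom, calls$copy_number)
  pieces <- lapply(split(calls, key), function(cs) {
    cs <- cs[order(cs$start), , drop = FALSE]
    repeat {
      if (nrow(cs) < 2L) break
      gap <- cs$start[-1] - cs$end[-nrow(cs)] - 1
      span <- cs$end[-1] - cs$start[-nrow(cs)] + 1
      mergeable <- which(gap / span <= gap_fraction)
      if (length(mergeable) == 0L) break
      i <- mergeable[1]
      w <- cs$n_markers[i] + cs$n_markers[i + 1]
      cs$mean_lrr[i] <- (cs$mean_lrr[i] * cs$n_markers[i] +
                           cs$mean_lrr[i + 1] * cs$n_markers[i + 1]) / w
      cs$end[i] <- cs$end[i + 1]
      cs$n_markers[i] <- w
      cs <- cs[-(i + 1), , drop = FALSE]
    }
    cs
  })
  out <- do.call(rbind, pieces)
  if (!is.null(map)) {
    out$n_markers <- vapply(seq_len(nrow(out)), function(i) {
      sum(map$chrom == out$chrom[i] & map$position >= out$start[i] &
            map$position <= out$end[i])
    }, integer(1))
  }
  out <- out[order(out$sample, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extend call breakpoints into supporting flanks
#'
#' Greedily extends each call boundary outward while the flanking marker's
#' emission log-odds favour the call's state over neutral CN2 by at least
#' `margin`. Calls never shrink below their original span. This automates
#' the manual breakpoint correction of flanking signal consistent with a
#' continuing CNV.
#'
#' @param calls CNV call data.frame.
#' @param signals The `signal_set` the calls were made from.
#' @param params [hmm_params()].
#' @param margin Required per-marker log-odds margin (`Inf` disables
#'   extension).
#' @return Call data.frame with possibly extended `start`/`end` and updated
#'   `n_markers`/`mean_lrr`.
#' @export
refine_breakpoints <- function(calls, signals, params = hmm_params(),
                               margin = 2) {
  if (nrow(calls) == 0L || is.infinite(margin)) return(calls)
  state_idx <- match(paste0("CN", calls$copy_number),
                     c("CN0", "CN1", "CN2", "CN2_LOH", "CN3", "CN4"))
  for (i in seq_len(nrow(calls))) {
    idx <- which(signals$map$chrom == calls$chrom[i])
    pos <- signals$map$position[idx]
    j <- idx[pos >= calls$start[i] & pos <= calls$end[i]]
    if (length(j) == 0L) next
    s <- calls$sample[i]
    logem <- emission_matrix(signals$lrr[idx, s], signals$baf[idx, s],
                             signals$map$pfb[idx], params)
    lo <- match(j[1], idx); hi <- match(j[length(j)], idx)
    while (lo > 1L &&
           logem[lo - 1L, state_idx[i]] - logem[lo - 1L, 3L] > margin)
      lo <- lo - 1L
    while (hi < length(idx) &&
           logem[hi + 1L, state_idx[i]] - logem[hi + 1L, 3L] > margin)
      hi <- hi + 1L
    calls$start[i] <- pos[lo]
    calls$end[i] <- pos[hi]
    calls$n_markers[i] <- hi - lo + 1L
    calls$mean_lrr[i] <- mean(signals$lrr[idx[lo:hi], s])
  }
  calls
}
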