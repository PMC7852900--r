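#' Classify inheritance of offspring CNV calls
#'
#' A child call is inherited from a parent when that parent carries a call
#' of the same class (deletion/duplication) with at least `min_ro`
#' reciprocal overlap; if neither parent does, the call is de novo. The
#' rare case where both parents qualify is flagged ambiguous and excluded
#' from per-parent tallies rather than guessed.
#'
#' @param matched Matched child calls from [match_ndd_regions()] (must
#'   carry `sample`, `chrom`, `start`, `end`, `copy_number`, `class`).
#' @param parent_calls Post-filter CNV calls of the parental samples.
#' @param pedigree data.frame `family`, `child`, `father`, `mother`.
#' @param min_ro Reciprocal-overlap threshold (default 0.5).
#' @return The matched records plus `status` (`inherited_maternal`,
#'   `inherited_paternal`, `de_novo`, `ambiguous`) and `origin`
#'   (`maternal`, `paternal`, `unresolved`; de novo origin stays
#'   unresolved until parent-of-origin inference).
#' @export
classify_inheritance <- function(matched, parent_calls, pedigree,
                                 min_ro = 0.5) {
  n <- nrow(matched)
  matched$status <- character(n)
  matched$origin <- character(n)
  if (n == 0L) return(matched)
  ped_idx <- match(matched$sample, pedigree$child)
  if (anyNA(ped_idx)) stop("matched call sample missing from pedigree")
  has_match <- function(i, parent_id) {
    pc <- parent_calls[parent_calls$sample == parent_id &
                         parent_calls$chrom == matched$chrom[i] &
                         cn_class(parent_calls$copy_number) ==
                           matched$class[i], , drop = FALSE]
    if (nrow(pc) == 0L) return(FALSE)
    ov <- pmin(pc$end, matched$end[i]) - pmax(pc$start, matched$start[i]) + 1
    wc <- matched$end[i] - matched$start[i] + 1
    wp <- pc$end - pc$start + 1
    any(ov > 0 & ov / wc >= min_ro & ov / wp >= min_ro)
  }
  for (i in seq_len(n)) {
    mat <- has_match(i, pedigree$mother[ped_idx[i]])
    pat <- has_match(i, pedigree$father[ped_idx[i]])
    if (mat && pat) {
      matched$status[i] <- "ambiguous"; matched$origin[i] <- "unresolved"
    } else if (mat) {
      matched$status[i] <- "inherited_maternal"; matched$origin[i] <- "maternal"
    } else if (pat) {
      matched$status[i] <- "inherited_paternal"; matched$origin[i] <- "paternal"
    } else {
      matched$status[i] <- "de_novo"; matched$origin[i] <- "unresolved"
    }
  }
  matched
}

#' Estimate the mosaic cell fraction of a copy-number gain
#'
#' In a mosaic gain present in a fraction `f` of cells, the heterozygous
#' BAF bands sit at `1/(2+f)` and `(1+f)/(2+f)`. The estimator folds BAF
#' about 0.5, takes a robust (10% trimmed) mean of the folded values of
#' heterozygous-band markers as the lower band centre `b`, and inverts the
#' mixture: `f = 1/b - 2`, clipped to \[0, 1\]. `f = 1` is a
#' constitutional duplication; `f = 0` means no gain.
#'
#' The folded window defaults to just below the theoretical heterozygous
#' band range `[1/3, 0.5)`: gains where the extra copy differs from a
#' homozygous base genotype emit a second band at `f/(2+f)`, which enters
#' `(0.2, 0.5)` for large `f` and would otherwise bias the estimate.
#'
#' @param call A single duplication call (one row of a call data.frame).
#' @param signals The `signal_set`.
#' @param min_het Minimal number of heterozygous-band markers (default 10).
#' @param band_window Folded-BAF window treated as the heterozygous band.
#' @param mosaic_below Report the event as mosaic when the estimate is
#'   below this (default 0.9) and above 0.
#' @return list `fraction` (estimate, or `NA` if too few heterozygous
#'   markers) and `mosaic` (logical flag).
#' @export
detect_mosaic <- function(call, signals, min_het = 10,
                          band_window = c(1 / 3 - 0.025, 0.5),
                          mosaic_below = 0.9) {
  if (call$copy_number < 2) stop("mosaic estimation applies to gains")
  idx <- which(signals$map$chrom == call$chrom &
                 signals$map$position >= call$start &
                 signals$map$position <= call$end)
  baf <- signals$baf[idx, call$sample]
  fold <- pmin(baf, 1 - baf)
  het <- fold > band_window[1] & fold <= band_window[2]
  if (sum(het) < min_het)
    return(list(fraction = NA_real_, mosaic = FALSE))
  b <- mean(fold[het], trim = 0.1)
  f <- min(max(1 / b - 2, 0), 1)
  list(fraction = f, mosaic = f > 0 && f < mosaic_below)
}
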