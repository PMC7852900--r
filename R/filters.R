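#' Reciprocal-overlap clustering of CNV calls
#'
#' Groups calls of the same class (deletion vs duplication) that overlap
#' reciprocally by at least `min_ro` (each call covers >= `min_ro` of the
#' other's span) into clusters via connected components, the conventional
#' way of equating a recurrent variant across samples.
#'
#' @param calls CNV call data.frame.
#' @param min_ro Minimal reciprocal overlap fraction (default 0.5).
#' @return Integer vector of cluster ids, one per call.
#' @export
cluster_calls <- function(calls, min_ro = 0.5) {
  n <- nrow(calls)
  if (n == 0L) return(integer(0))
  gr <- as_granges_calls(calls)
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  keep <- cn_class(calls$copy_number[q]) == cn_class(calls$copy_number[s])
  q <- q[keep]; s <- s[keep]
  ov <- pmin(calls$end[q], calls$end[s]) - pmax(calls$start[q], calls$start[s]) + 1
  wq <- calls$end[q] - calls$start[q] + 1
  ws <- calls$end[s] - calls$start[s] + 1
  keep <- ov / wq >= min_ro & ov / ws >= min_ro
  q <- q[keep]; s <- s[keep]
  # union-find over the reciprocal-overlap graph
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_along(q)) {
    a <- find(q[k]); b <- find(s[k])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Remove CNVs common in the parental set
#'
#' Calls are clustered by >= 50% reciprocal overlap and class
#' ([cluster_calls()]); a cluster's frequency is the number of distinct
#' parental carriers divided by the number of parents (unrelated
#' individuals). Clusters exceeding `max_freq` are removed cohort-wide,
#' children's calls included. Offspring-only variants have frequency 0 and
#' are always retained.
#'
#' @param calls CNV call data.frame (whole cohort).
#' @param parent_ids Character vector of all parental sample ids.
#' @param max_freq Maximal parental frequency (default 0.01, i.e. 1%).
#' @param min_ro Reciprocal-overlap threshold for clustering.
#' @return The retained calls.
#' @export
parental_frequency_filter <- function(calls, parent_ids, max_freq = 0.01,
                                      min_ro = 0.5) {
  if (length(parent_ids) == 0L) stop("empty parental set")
  if (nrow(calls) == 0L) return(calls)
  cl <- cluster_calls(calls, min_ro)
  carrier_n <- vapply(split(calls$sample, cl), function(ss)
    length(unique(intersect(ss, parent_ids))), integer(1))
  freq <- carrier_n[as.character(cl)] / length(parent_ids)
  calls[freq <= max_freq, , drop = FALSE]
}

#' Remove calls overlapping blacklist intervals
#'
#' Any overlap of at least 1 bp with a blacklist interval (centromeric or
#' telomeric regions, known copy-number-susceptible loci) removes the call.
#'
#' @param calls CNV call data.frame.
#' @param blacklist Interval data.frame (`chrom`, `start`, `end`, 1-based
#'   inclusive), e.g. [default_blacklist()].
#' @return The retained calls.
#' @export
exclude_blacklist <- function(calls, blacklist = default_blacklist()) {
  if (nrow(calls) == 0L || nrow(blacklist) == 0L) return(calls)
  if (any(blacklist$start > blacklist$end)) stop("malformed blacklist interval")
  hits <- GenomicRanges::findOverlaps(as_granges_calls(calls),
                                      as_granges_calls(blacklist))
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop)) calls[-drop, , drop = FALSE] else calls
}

#' Retain calls of sufficient size and marker support
#'
#' Keeps calls spanning at least `min_bp` base pairs (inclusive span
#' `end - start + 1`) and at least `min_markers` markers.
#'
#' @param calls CNV call data.frame.
#' @param min_bp Minimal span (default 100 kb).
#' @param min_markers Minimal marker count (default 10).
#' @return The retained calls.
#' @export
size_marker_filter <- function(calls, min_bp = 1e5, min_markers = 10) {
  if (nrow(calls) == 0L) return(calls)
  keep <- (calls$end - calls$start + 1) >= min_bp &
    calls$n_markers >= min_markers
  calls[keep, , drop = FALSE]
}

#' Match calls to reference NDD regions
#'
#' A call matches a region when it covers at least `min_frac` of the
#' region's span (`overlap / region_length >= min_frac`); the call's class
#' is deletion for copy number < 2, duplication otherwise. A call can
#' match several regions only if it covers each of them sufficiently.
#'
#' @param calls CNV call data.frame.
#' @param regions Region table ([ndd_regions()]).
#' @param min_frac Minimal covered fraction of the region (default 0.5).
#' @return data.frame of matched records: the call columns plus `region`,
#'   `class` and `region_overlap` (the covered fraction).
#' @export
match_ndd_regions <- function(calls, regions = ndd_regions(),
                              min_frac = 0.5) {
  empty <- cbind(empty_calls(),
                 data.frame(region = character(0), class = character(0),
                            region_overlap = numeric(0)))
  if (nrow(calls) == 0L) return(empty)
  hits <- GenomicRanges::findOverlaps(as_granges_calls(calls),
                                      as_granges_calls(regions))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- pmin(calls$end[q], regions$end[s]) -
    pmax(calls$start[q], regions$start[s]) + 1
  frac <- ov / (regions$end[s] - regions$start[s] + 1)
  keep <- frac >= min_frac
  if (!any(keep)) return(empty)
  out <- calls[q[keep], , drop = FALSE]
  out$region <- regions$region[s[keep]]
  out$class <- cn_class(out$copy_number)
  out$region_overlap <- frac[keep]
  rownames(out) <- NULL
  out
}
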