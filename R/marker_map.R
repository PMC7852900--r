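#' Build a synthetic SNP marker map
#'
#' Places markers along one or more chromosomes, optionally concentrating
#' density inside a set of regions (emulating the exon/region enrichment of
#' genotyping arrays around clinically relevant loci). Positions are drawn
#' from a piecewise-uniform density in which each region's density is
#' `region_boost` times the background, then sorted and de-duplicated.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param n_markers Total number of markers across all chromosomes.
#' @param regions Optional data.frame (`chrom`, `start`, `end`) of intervals
#'   receiving boosted density; an optional `boost` column overrides
#'   `region_boost` per interval (where intervals overlap, the larger
#'   boost wins).
#' @param region_boost Default density multiplier (>= 1) inside `regions`.
#' @param min_region_markers If positive, regions ending up with fewer
#'   markers are topped up to this count with uniformly placed markers.
#' @param pfb_range Range from which per-marker population B-allele
#'   frequencies are drawn uniformly.
#' @param seed Optional integer seed; the map is deterministic given
#'   (arguments, seed).
#' @return Marker map data.frame: `name`, `chrom`, `position` (1-based,
#'   strictly increasing within chromosome), `pfb`.
#' @export
build_marker_map <- function(chrom_lengths, n_markers, regions = NULL,
                             region_boost = 1, min_region_markers = 0,
                             pfb_range = c(0.05, 0.95), seed = NULL) {
  if (n_markers < 1L) stop("n_markers must be >= 1")
  if (any(chrom_lengths <= 0)) stop("zero-length chromosome")
  if (region_boost < 1) stop("region_boost must be >= 1")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- as.character(seq_along(chrom_lengths))
  with_seed(seed, {
    if (!is.null(regions) && is.null(regions$boost))
      regions$boost <- region_boost
    # effective (density-weighted) length per chromosome
    eff <- vapply(names(chrom_lengths), function(cc) {
      L <- chrom_lengths[[cc]]
      r <- if (is.null(regions)) NULL else
        regions[regions$chrom == cc, , drop = FALSE]
      segs <- boost_segments(L, r)
      sum((segs$end - segs$start + 1) * segs$w)
    }, numeric(1))
    n_per <- as.vector(stats::rmultinom(1, n_markers, eff / sum(eff)))
    names(n_per) <- names(chrom_lengths)

    out <- lapply(names(chrom_lengths), function(cc) {
      n <- n_per[[cc]]
      if (n == 0L) return(NULL)
      L <- chrom_lengths[[cc]]
      r <- if (is.null(regions)) NULL else
        regions[regions$chrom == cc, , drop = FALSE]
      pos <- sample_piecewise(n, L, r)
      if (min_region_markers > 0 && !is.null(r) && nrow(r) > 0) {
        rb <- r[r$boost == max(r$boost), , drop = FALSE]  # primary regions
        for (i in seq_len(nrow(rb))) {
          inside <- sum(pos >= rb$start[i] & pos <= rb$end[i])
          if (inside < min_region_markers) {
            extra <- floor(runif(min_region_markers - inside,
                                 rb$start[i], rb$end[i] + 1))
            pos <- c(pos, extra)
          }
        }
      }
      pos <- sort(unique(pos))
      data.frame(chrom = cc, position = pos, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    out$name <- sprintf("SNP_%s_%06d", out$chrom,
                        as.integer(stats::ave(out$position, out$chrom,
                                              FUN = seq_along)))
    out$pfb <- runif(nrow(out), pfb_range[1], pfb_range[2])
    rownames(out) <- NULL
    out[c("name", "chrom", "position", "pfb")]
  })
}

# partition [1, L] into segments with a density weight per segment
# (the largest boost wins where intervals overlap; background weight 1)
boost_segments <- function(L, regions) {
  if (is.null(regions) || nrow(regions) == 0L)
    return(data.frame(start = 1, end = L, w = 1))
  cuts <- sort(unique(c(1, pmax(1, pmin(regions$start, L)),
                        pmin(L + 1, regions$end + 1), L + 1)))
  start <- cuts[-length(cuts)]
  end <- cuts[-1] - 1
  w <- vapply(seq_along(start), function(i) {
    hit <- regions$start <= start[i] & regions$end >= end[i]
    if (any(hit)) max(regions$boost[hit]) else 1
  }, numeric(1))
  data.frame(start = start, end = end, w = w)
}

# draw n integer positions in [1, L] from the piecewise-uniform density
sample_piecewise <- function(n, L, regions) {
  segs <- boost_segments(L, regions)
  if (nrow(segs) == 1L) return(floor(runif(n, 1, L + 1)))
  wlen <- (segs$end - segs$start + 1) * segs$w
  seg_idx <- sample.int(nrow(segs), n, replace = TRUE, prob = wlen)
  floor(runif(n, segs$start[seg_idx], segs$end[seg_idx] + 1))
}
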