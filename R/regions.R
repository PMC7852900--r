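#' Recurrent NDD regions (GRCh37)
#'
#' The 13 low-copy-repeat-flanked genomic regions recurrently deleted or
#' duplicated in neurodevelopmental disorders, with GRCh37 coordinates.
#' Coordinates are stored as a BED file in `inst/extdata` and converted to
#' the package's internal 1-based inclusive convention on load.
#'
#' @return A data.frame with columns `region`, `chrom`, `start`, `end`
#'   (1-based inclusive) and `length_mb` (`(end - start) / 1e6`, the
#'   conventional span between the flanking breakpoints).
#' @export
#' @examples
#' r <- ndd_regions()
#' r[r$region == "1q21.1", "length_mb"]   # 0.817732
ndd_regions <- function() {
  path <- system.file("extdata", "ndd_regions_grch37.bed",
                      package = "triocnv", mustWork = TRUE)
  read_regions_bed(path)
}

#' Read genomic regions from a BED file
#'
#' Converts 0-based half-open BED intervals to the internal 1-based
#' inclusive representation (`start = BED start + 1`, `end = BED end`).
#'
#' @param path Path to a BED file with at least 3 columns; an optional 4th
#'   column provides region names.
#' @return data.frame with `region`, `chrom`, `start`, `end`, `length_mb`.
#' @export
read_regions_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("BED file must have at least 3 columns")
  if (any(bed[[2]] < 0 | bed[[3]] < 0)) stop("negative coordinate in BED file")
  if (any(bed[[2]] >= bed[[3]])) stop("BED interval with start >= end")
  name <- if (ncol(bed) >= 4L) as.character(bed[[4]]) else
    paste0(bed[[1]], ":", bed[[2]] + 1L, "-", bed[[3]])
  out <- data.frame(
    region = name,
    chrom = as.character(bed[[1]]),
    start = as.numeric(bed[[2]]) + 1,
    end = as.numeric(bed[[3]]),
    stringsAsFactors = FALSE
  )
  out$length_mb <- (out$end - out$start) / 1e6
  out
}

#' Write regions to a BED file (inverse of [read_regions_bed()])
#' @param regions data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `region`.
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(
    chrom = regions$chrom,
    start = format(regions$start - 1, scientific = FALSE, trim = TRUE),
    end = format(regions$end, scientific = FALSE, trim = TRUE),
    name = regions$region %||% ".",
    stringsAsFactors = FALSE
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Packaged blacklist of CNV-call exclusion intervals
#'
#' A synthetic blacklist for the simulated genome covering
#' centromeric/telomeric windows (and the acrocentric p-arms of
#' chromosomes 15 and 22) of the seven autosomes that harbour the NDD
#' regions. Calls overlapping these intervals by at least 1 bp are removed
#' by [exclude_blacklist()].
#'
#' @return data.frame in the same shape as [ndd_regions()].
#' @export
default_blacklist <- function() {
  path <- system.file("extdata", "blacklist_synthetic.bed",
                      package = "triocnv", mustWork = TRUE)
  read_regions_bed(path)
}

#' GRCh37 lengths of the chromosomes carrying NDD regions
#'
#' @return Named numeric vector of chromosome lengths (bp) for
#'   chromosomes 1, 3, 7, 15, 16, 17 and 22.
#' @export
grch37_chrom_lengths <- function() {
  c(`1` = 249250621, `3` = 198022430, `7` = 159138663,
    `15` = 102531392, `16` = 90354753, `17` = 81195210,
    `22` = 51304566)
}
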