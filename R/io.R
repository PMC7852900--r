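#' Read a PennCNV-dialect signal intensity file
#'
#' Expects tab-delimited columns `Name`, `Chr`, `Position` and, per sample,
#' `<sample>.Log R Ratio` and `<sample>.B Allele Freq`. Markers are sorted
#' by (chrom, position) with a warning if the file is unsorted.
#'
#' @param path Path to the signal file.
#' @param map Optional marker map carrying `pfb` (population B-allele
#'   frequency) for the same marker names; merged into the returned map.
#' @return A `signal_set`: list with `map` (data.frame `name`, `chrom`,
#'   `position`, and `pfb` if supplied), `samples`, and numeric matrices
#'   `lrr`, `baf` (markers x samples).
#' @export
read_signal_file <- function(path, map = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          check.names = FALSE)
  need <- c("Name", "Chr", "Position")
  if (!all(need %in% names(dt)))
    stop("signal file missing column(s): ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  if (anyDuplicated(dt$Name)) stop("duplicate marker name in signal file")
  lrr_cols <- grep("\\.Log R Ratio$", names(dt), value = TRUE)
  baf_cols <- grep("\\.B Allele Freq$", names(dt), value = TRUE)
  samples_l <- sub("\\.Log R Ratio$", "", lrr_cols)
  samples_b <- sub("\\.B Allele Freq$", "", baf_cols)
  if (length(samples_l) == 0L) stop("signal file missing column: Log R Ratio")
  missing_baf <- setdiff(samples_l, samples_b)
  if (length(missing_baf) > 0L)
    stop("signal file missing column: ", missing_baf[1], ".B Allele Freq")
  samples <- samples_l
  ord <- order(dt$Chr, dt$Position)
  if (is.unsorted(ord)) {
    warning("markers not sorted by (chrom, position); sorting")
    dt <- dt[ord, , drop = FALSE]
  }
  smap <- data.frame(name = dt$Name, chrom = as.character(dt$Chr),
                     position = as.numeric(dt$Position),
                     stringsAsFactors = FALSE)
  if (!is.null(map)) {
    idx <- match(smap$name, map$name)
    if (anyNA(idx)) stop("marker(s) in signal file absent from map")
    smap$pfb <- map$pfb[idx]
  }
  lrr <- as.matrix(dt[paste0(samples, ".Log R Ratio")])
  baf <- as.matrix(dt[paste0(samples, ".B Allele Freq")])
  colnames(lrr) <- colnames(baf) <- samples
  rownames(lrr) <- rownames(baf) <- smap$name
  signal_set(smap, lrr, baf)
}

#' Write a `signal_set` to a PennCNV-dialect signal file
#' @param signals A `signal_set` (see [read_signal_file()]).
#' @param path Output path.
#' @export
write_signal_file <- function(signals, path) {
  df <- data.frame(Name = signals$map$name, Chr = signals$map$chrom,
                   Position = signals$map$position,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (s in signals$samples) {
    df[[paste0(s, ".Log R Ratio")]] <- signals$lrr[, s]
    df[[paste0(s, ".B Allele Freq")]] <- signals$baf[, s]
  }
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Construct a signal set
#' @param map Marker map data.frame (`name`, `chrom`, `position`, optional
#'   `pfb`).
#' @param lrr,baf Numeric matrices, markers x samples, with sample column
#'   names.
#' @return Object of class `signal_set`.
#' @export
signal_set <- function(map, lrr, baf) {
  stopifnot(nrow(map) == nrow(lrr), nrow(map) == nrow(baf),
            identical(dim(lrr), dim(baf)))
  structure(list(map = map, samples = colnames(lrr), lrr = lrr, baf = baf),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat("signal_set:", nrow(x$map), "markers x", length(x$samples), "samples;",
      length(unique(x$map$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Read / write a marker map with population B-allele frequencies
#'
#' Tab-delimited with columns `Name`, `Chr`, `Position`, `PFB` (the PennCNV
#' `.pfb` dialect).
#' @param path File path.
#' @return data.frame `name`, `chrom`, `position`, `pfb`.
#' @export
read_marker_map <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  data.frame(name = dt$Name, chrom = as.character(dt$Chr),
             position = as.numeric(dt$Position), pfb = as.numeric(dt$PFB),
             stringsAsFactors = FALSE)
}

#' @rdname read_marker_map
#' @param map Marker map data.frame.
#' @export
write_marker_map <- function(map, path) {
  data.table::fwrite(
    data.frame(Name = map$name, Chr = map$chrom, Position = map$position,
               PFB = map$pfb),
    path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write a trio pedigree
#'
#' Whitespace-delimited `family child father mother` (a PED-like subset).
#' @param path File path.
#' @return data.frame with columns `family`, `child`, `father`, `mother`.
#' @export
read_pedigree <- function(path) {
  ped <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(ped) < 4L) stop("pedigree needs 4 columns: family child father mother")
  setNames(ped[1:4], c("family", "child", "father", "mother"))
}

#' @rdname read_pedigree
#' @param pedigree data.frame with `family`, `child`, `father`, `mother`.
#' @export
write_pedigree <- function(pedigree, path) {
  write.table(pedigree[c("family", "child", "father", "mother")], path,
              sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write CNV calls as TSV and BED
#'
#' The TSV keeps the internal 1-based inclusive coordinates; the BED export
#' converts to 0-based half-open at the boundary only.
#' @param calls CNV call data.frame (`sample`, `chrom`, `start`, `end`,
#'   `copy_number`, `n_markers`, `mean_lrr`).
#' @param path Output path.
#' @export
write_calls_tsv <- function(calls, path) {
  data.table::fwrite(calls, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
write_calls_bed <- function(calls, path) {
  bed <- data.frame(
    chrom = calls$chrom,
    start = format(calls$start - 1, scientific = FALSE, trim = TRUE),
    end = format(calls$end, scientific = FALSE, trim = TRUE),
    name = paste0(calls$sample, "_CN", calls$copy_number),
    stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path) {
  out <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  if ("chrom" %in% names(out)) out$chrom <- as.character(out$chrom)
  out
}

#' Serialize / restore a pipeline configuration
#'
#' Configurations are plain nested lists (see [cohort_config()],
#' [hmm_params()], [qc_thresholds()]); YAML round-trips them losslessly up
#' to numeric formatting.
#' @param config A configuration list.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) yaml::read_yaml(path)
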