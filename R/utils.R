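# internal helpers shared across modules

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL runs in the ambient state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# empty CNV call table with canonical column types
empty_calls <- function() {
  data.frame(
    sample = character(), chrom = character(),
    start = numeric(), end = numeric(),
    copy_number = integer(), n_markers = integer(),
    mean_lrr = numeric(), stringsAsFactors = FALSE
  )
}

# classify copy number into deletion/duplication
cn_class <- function(cn) ifelse(cn < 2, "deletion", "duplication")

as_granges_calls <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start, end = df$end)
  )
}
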