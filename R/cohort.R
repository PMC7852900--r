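#' Per-region event-rate table calibrated to the reference cohort
#'
#' Default simulation rates for each (region, deletion/duplication) pair,
#' derived from the packaged reference-cohort count tables (a population
#' cohort of 12,252 newborn trios): de novo child rates are the observed
#' de novo counts divided by the cohort size; parental carrier rates are
#' the inherited-child counts divided by the cohort size and by the
#' cohort's global transmission rate for that parent (24/43 maternal,
#' 15/44 paternal), so expected parental carrier totals match the observed
#' 43 maternal / 44 paternal events.
#'
#' @return data.frame: `region`, `class`, `denovo_rate`,
#'   `denovo_maternal_frac`, `maternal_carrier_rate`,
#'   `paternal_carrier_rate`.
#' @export
default_region_rates <- function() {
  rc <- reference_region_counts()
  tot <- reference_cohort_totals()
  n <- tot[["n_trios"]]
  tau_m <- tot[["transmitted_maternal"]] / tot[["mother_events"]]
  tau_p <- tot[["transmitted_paternal"]] / tot[["father_events"]]
  dn_origin_n <- rc$denovo_maternal + rc$denovo_paternal
  data.frame(
    region = rc$region, class = rc$class,
    denovo_rate = rc$n_denovo / n,
    denovo_maternal_frac = ifelse(dn_origin_n > 0,
                                  (rc$denovo_maternal +
                                     0.5 * rc$denovo_unresolved) /
                                    (dn_origin_n + rc$denovo_unresolved),
                                  0.5),
    maternal_carrier_rate = rc$inherited_maternal / n / tau_m,
    paternal_carrier_rate = rc$inherited_paternal / n / tau_p,
    stringsAsFactors = FALSE
  )
}

#' Packaged reference-cohort count tables
#'
#' Counts of recurrent NDD CNVs observed in a reference population cohort
#' of 12,252 newborn trios, per region and class (de novo with parental
#' origin, inherited maternal/paternal, mosaic) plus cohort-level totals
#' (parental event counts and transmitted counts).
#'
#' @return `reference_region_counts()`: data.frame of per-region counts;
#'   `reference_cohort_totals()`: named numeric vector.
#' @export
reference_region_counts <- function() {
  read.delim(system.file("extdata", "reference_cohort_region_counts.tsv",
                         package = "triocnv", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

#' @rdname reference_region_counts
#' @export
reference_cohort_totals <- function() {
  x <- read.delim(system.file("extdata", "reference_cohort_totals.tsv",
                              package = "triocnv", mustWork = TRUE))
  setNames(as.numeric(x$value), x$key)
}

#' Configuration for synthetic trio-cohort generation
#'
#' @param n_trios Number of trios.
#' @param regions NDD region table ([ndd_regions()] by default).
#' @param region_rates Rate table as in [default_region_rates()]; rates are
#'   per trio per (region, class).
#' @param transmission_maternal,transmission_paternal Probability that a
#'   carrier parent transmits the CNV to the child (defaults: the reference
#'   cohort's 24/43 and 15/44).
#' @param mosaic_rate Probability that a de novo duplication is mosaic.
#' @param mosaic_fraction_range Range of mosaic cell fractions (uniform).
#' @param breakpoint_jitter Maximal random extension (bp) of each event
#'   breakpoint beyond the reference region boundary, emulating breakpoint
#'   spread within the flanking low-copy repeats.
#' @param noise A [noise_model()].
#' @param n_markers,region_boost,min_region_markers Marker-map parameters
#'   (see [build_marker_map()]).
#' @param flank_bp,flank_boost Width and density multiplier of
#'   moderately-dense windows flanking each region, so that called
#'   breakpoints meet marker resistance outside the region instead of
#'   jumping across sparse background.
#' @param chrom_lengths Chromosome lengths ([grch37_chrom_lengths()]).
#' @param dup_from_transmitted_only Restrict duplication extra copies to
#'   the transmitted homolog (see [implant_cnv()]).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_trios = 500,
                          regions = ndd_regions(),
                          region_rates = default_region_rates(),
                          transmission_maternal = 24 / 43,
                          transmission_paternal = 15 / 44,
                          mosaic_rate = 1 / 7,
                          mosaic_fraction_range = c(0.4, 0.8),
                          breakpoint_jitter = 4e4,
                          noise = noise_model(),
                          n_markers = 4000,
                          region_boost = 60,
                          min_region_markers = 20,
                          flank_bp = 1.5e6,
                          flank_boost = 8,
                          chrom_lengths = grch37_chrom_lengths(),
                          dup_from_transmitted_only = FALSE) {
  rates <- unlist(region_rates[c("denovo_rate", "maternal_carrier_rate",
                                 "paternal_carrier_rate")])
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (n_trios < 1) stop("n_trios must be >= 1")
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic trio cohort with known truth
#'
#' Builds a marker map, simulates Mendelian trio genotypes, draws CNV
#' events per (region, class) from the configured rates (parental carriers
#' with Bernoulli transmission; de novo events with configured parental
#' origin; optional mosaic de novo gains), implants them, and renders
#' LRR/BAF signals.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the cohort is reproducible given
#'   (config, seed).
#' @param dir If non-NULL, the cohort is also written to this directory as
#'   a PennCNV-dialect signal file, marker map, pedigree and truth TSV.
#' @return A `trio_cohort`: list with `map`, `pedigree`, `genotypes`,
#'   `allele_counts`, `signals`, `truth`, `config`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL,
                            dir = NULL) {
  with_seed(seed, {
    reg <- config$regions
    map_regions <- rbind(
      data.frame(chrom = reg$chrom, start = reg$start, end = reg$end,
                 boost = config$region_boost),
      data.frame(chrom = reg$chrom,
                 start = pmax(1, reg$start - config$flank_bp),
                 end = reg$end + config$flank_bp,
                 boost = config$flank_boost))
    map <- build_marker_map(config$chrom_lengths, config$n_markers,
                            regions = map_regions,
                            min_region_markers = config$min_region_markers)
    geno <- simulate_trio_genotypes(map, config$n_trios)
    events <- draw_cohort_events(config, geno$trios)
    ac <- implant_cnv(geno, events,
                      dup_from_transmitted_only = config$dup_from_transmitted_only)
    signals <- render_signals(ac, config$noise)
    cohort <- structure(list(map = map, pedigree = geno$trios,
                             genotypes = geno, allele_counts = ac,
                             signals = signals, truth = attr(ac, "truth"),
                             config = config),
                        class = "trio_cohort")
    if (!is.null(dir)) write_cohort(cohort, dir)
    cohort
  })
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat("trio_cohort:", nrow(x$pedigree), "trios,", nrow(x$map), "markers,",
      nrow(x$truth), "implanted events\n")
  invisible(x)
}

#' Write a cohort's external files
#' @param cohort A `trio_cohort`.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_signal_file(cohort$signals, file.path(dir, "signals.tsv"))
  write_marker_map(cohort$map, file.path(dir, "markers.pfb"))
  write_pedigree(cohort$pedigree, file.path(dir, "pedigree.ped"))
  data.table::fwrite(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t")
  invisible(dir)
}

# draw the event table for a cohort; truth rows are child events
# (de_novo / inherited) plus parent-only carriers (untransmitted)
draw_cohort_events <- function(config, trios) {
  n <- nrow(trios)
  rr <- config$region_rates
  regions <- config$regions
  out <- vector("list", nrow(rr))
  for (i in seq_len(nrow(rr))) {
    reg <- regions[regions$region == rr$region[i], ]
    if (nrow(reg) != 1L) stop("rate table region not found: ", rr$region[i])
    cn <- if (rr$class[i] == "deletion") 1L else 3L
    rows <- list()
    # parental carriers and transmission
    for (side in c("maternal", "paternal")) {
      q <- if (side == "maternal") rr$maternal_carrier_rate[i] else
        rr$paternal_carrier_rate[i]
      tau <- if (side == "maternal") config$transmission_maternal else
        config$transmission_paternal
      carrier <- which(runif(n) < q)
      if (length(carrier) == 0L) next
      transmits <- runif(length(carrier)) < tau
      parent_ids <- if (side == "maternal") trios$mother[carrier] else
        trios$father[carrier]
      rows[[side]] <- data.frame(
        region = reg$region, chrom = reg$chrom,
        start = reg$start, end = reg$end,
        carrier = ifelse(transmits, trios$child[carrier], parent_ids),
        copy_number = cn, origin_parent = side,
        mode = ifelse(transmits, "inherited", "untransmitted"),
        mosaic_fraction = 1, stringsAsFactors = FALSE)
    }
    # de novo child events
    dn <- which(runif(n) < rr$denovo_rate[i])
    if (length(dn) > 0L) {
      origin <- ifelse(runif(length(dn)) < rr$denovo_maternal_frac[i],
                       "maternal", "paternal")
      mf <- rep(1, length(dn))
      if (cn == 3L && config$mosaic_rate > 0) {
        mos <- runif(length(dn)) < config$mosaic_rate
        mf[mos] <- runif(sum(mos), config$mosaic_fraction_range[1],
                         config$mosaic_fraction_range[2])
      }
      rows$de_novo <- data.frame(
        region = reg$region, chrom = reg$chrom,
        start = reg$start, end = reg$end,
        carrier = trios$child[dn], copy_number = cn,
        origin_parent = origin, mode = "de_novo",
        mosaic_fraction = mf, stringsAsFactors = FALSE)
    }
    out[[i]] <- do.call(rbind, rows)
  }
  ev <- do.call(rbind, out)
  if (is.null(ev)) {
    return(data.frame(region = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      carrier = character(), copy_number = integer(),
                      origin_parent = character(), mode = character(),
                      mosaic_fraction = numeric(), stringsAsFactors = FALSE))
  }
  rownames(ev) <- NULL
  # at most one event per (individual, region): an inherited event also
  # occupies the origin parent, so later draws touching the same person at
  # the same locus (e.g. a deletion and a duplication of one region in one
  # parent) are dropped, keeping the first
  fam <- sub("_[cmf]$", "", ev$carrier)
  parent_of <- ifelse(ev$mode == "inherited",
                      paste0(fam, ifelse(ev$origin_parent == "maternal",
                                         "_m", "_f")),
                      NA_character_)
  seen <- character(0)
  keep <- logical(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    keys <- paste(c(ev$carrier[i], parent_of[i]), ev$region[i])
    keys <- keys[!is.na(c(ev$carrier[i], parent_of[i]))]
    if (!any(keys %in% seen)) {
      keep[i] <- TRUE
      seen <- c(seen, keys)
    }
  }
  ev <- ev[keep, , drop = FALSE]
  # breakpoint jitter within the flanking repeats
  j <- config$breakpoint_jitter
  if (j > 0) {
    ev$start <- pmax(1, ev$start - floor(runif(nrow(ev), 0, j + 1)))
    lim <- config$chrom_lengths[ev$chrom]
    ev$end <- pmin(lim, ev$end + floor(runif(nrow(ev), 0, j + 1)))
  }
  ev
}
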