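#' Run the full trio CNV analysis pipeline on a cohort
#'
#' Chains every analysis stage on a (typically simulated) trio cohort:
#' per-sample HMM segmentation, fragment merging, QC metrics with the
#' trio gate, parental-frequency / blacklist / size filtering, NDD-region
#' matching, inheritance classification, parent-of-origin resolution for
#' de novo calls, mosaic-fraction estimation for duplications, and the
#' summary tables.
#'
#' @param cohort A `trio_cohort` ([generate_cohort()]) or a list with
#'   `signals` (`signal_set` whose map has `pfb`) and `pedigree`.
#' @param hmm [hmm_params()].
#' @param thresholds [qc_thresholds()].
#' @param regions Region table ([ndd_regions()]).
#' @param blacklist Blacklist intervals ([default_blacklist()]); `NULL`
#'   skips the blacklist filter.
#' @param max_parental_freq,min_bp,min_markers,region_min_frac Filter
#'   parameters (defaults: 1%, 100 kb, 10 markers, 50%).
#' @param refine_margin Log-odds margin for breakpoint refinement (`Inf`
#'   disables refinement).
#' @param gap_fraction Fragment-merge gap fraction.
#' @return list: `qc`, `gate`, `n_trios_pass`, `calls` (post-merge),
#'   `calls_filtered`, `matched`, `parental_matched`, `classified`,
#'   `tables`.
#' @export
run_pipeline <- function(cohort, hmm = hmm_params(),
                         thresholds = qc_thresholds(),
                         regions = ndd_regions(),
                         blacklist = default_blacklist(),
                         max_parental_freq = 0.01, min_bp = 1e5,
                         min_markers = 10, region_min_frac = 0.5,
                         refine_margin = 2, gap_fraction = 0.2) {
  signals <- cohort$signals
  pedigree <- cohort$pedigree

  calls <- viterbi_segment(signals, hmm)
  calls <- merge_adjacent(calls, gap_fraction, map = signals$map)

  qc <- compute_qc_metrics(signals, calls)
  gate <- apply_trio_gate(qc, pedigree, thresholds)
  ped_pass <- pedigree[gate$pass, , drop = FALSE]
  keep_samples <- c(ped_pass$mother, ped_pass$father, ped_pass$child)
  calls_pass <- calls[calls$sample %in% keep_samples, , drop = FALSE]

  parents <- c(ped_pass$mother, ped_pass$father)
  filtered <- parental_frequency_filter(calls_pass, parents,
                                        max_freq = max_parental_freq)
  if (!is.null(blacklist)) filtered <- exclude_blacklist(filtered, blacklist)
  filtered <- size_marker_filter(filtered, min_bp, min_markers)
  if (is.finite(refine_margin))
    filtered <- refine_breakpoints(filtered, signals, hmm, refine_margin)

  child_calls <- filtered[filtered$sample %in% ped_pass$child, , drop = FALSE]
  parent_calls <- filtered[filtered$sample %in% parents, , drop = FALSE]
  matched <- match_ndd_regions(child_calls, regions, region_min_frac)
  parental_matched <- match_ndd_regions(parent_calls, regions,
                                        region_min_frac)

  classified <- classify_inheritance(matched, parent_calls, ped_pass)
  classified <- resolve_parent_origin(classified, signals, ped_pass)
  classified$mosaic <- rep(FALSE, nrow(classified))
  classified$mosaic_fraction <- rep(NA_real_, nrow(classified))
  for (i in which(classified$copy_number > 2)) {
    mos <- detect_mosaic(classified[i, ], signals)
    classified$mosaic[i] <- mos$mosaic
    classified$mosaic_fraction[i] <- mos$fraction
  }

  tables <- build_summary_tables(classified, parental_matched, ped_pass,
                                 regions, n_trios = nrow(ped_pass))
  list(qc = qc, gate = gate, n_trios_pass = nrow(ped_pass),
       calls = calls, calls_filtered = filtered, matched = matched,
       parental_matched = parental_matched, classified = classified,
       tables = tables)
}

#' Compare pipeline results with simulation truth
#'
#' Matches classified offspring calls against the cohort's truth table by
#' (sample, region) and tallies recovery and classification agreement.
#'
#' @param classified Classified calls from [run_pipeline()].
#' @param truth Truth table of a `trio_cohort` (child events only are
#'   considered, i.e. `mode` of `de_novo` or `inherited`).
#' @param samples Optional sample ids to restrict the truth to (e.g. the
#'   children of QC-passing trios; events in excluded trios cannot be
#'   called and should not count as misses).
#' @return list: `n_truth`, `n_called`, `n_recovered`, `status_correct`
#'   (of recovered events), `false_calls` (called but not in truth).
#' @export
compare_with_truth <- function(classified, truth, samples = NULL) {
  child_truth <- truth[truth$mode %in% c("de_novo", "inherited"), ,
                       drop = FALSE]
  if (!is.null(samples))
    child_truth <- child_truth[child_truth$carrier %in% samples, ,
                               drop = FALSE]
  truth_key <- paste(child_truth$carrier, child_truth$region)
  call_key <- paste(classified$sample, classified$region)
  recovered <- truth_key %in% call_key
  idx <- match(truth_key[recovered], call_key)
  expect_status <- ifelse(child_truth$mode[recovered] == "de_novo", "de_novo",
                          paste0("inherited_", child_truth$origin_parent[recovered]))
  status_ok <- classified$status[idx] == expect_status
  list(n_truth = nrow(child_truth),
       n_called = nrow(classified),
       n_recovered = sum(recovered),
       status_correct = sum(status_ok),
       false_calls = sum(!(call_key %in% truth_key)))
}
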