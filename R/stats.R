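#' Wilson score confidence interval for a binomial proportion
#'
#' The Wilson interval is well behaved at small counts: its lower bound is
#' exactly 0 when `x = 0` and the upper bound 1 when `x = n`, and it
#' always contains the point estimate `x/n`.
#'
#' @param x Number of successes (events).
#' @param n Number of trials (e.g. trios).
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)` on the proportion scale.
#' @export
#' @examples
#' wilson_ci(59, 12252) * 1e4   # 37.35, 62.06 per 10,000
wilson_ci <- function(x, n, conf = 0.95) {
  if (n < 1) stop("n must be >= 1")
  if (x < 0 || x > n) stop("x must lie in [0, n]")
  if (conf <= 0 || conf >= 1) stop("conf must lie in (0, 1)")
  z <- qnorm((1 + conf) / 2)
  centre <- (x + z^2 / 2) / (n + z^2)
  half <- z * sqrt(x * (n - x) / n + z^2 / 4) / (n + z^2)
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Two-proportion Z-test
#'
#' Pooled two-proportion Z statistic with two-sided normal p-value, used
#' to compare deletion and duplication counts over the same cohort.
#'
#' @param x1,n1 Events and trials in group 1.
#' @param x2,n2 Events and trials in group 2.
#' @return list `z`, `p`.
#' @export
#' @examples
#' two_prop_z(25, 12252, 34, 12252)  # z = -1.17, p = 0.24
two_prop_z <- function(x1, n1, x2, n2) {
  stopifnot(x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2, n1 >= 1, n2 >= 1)
  pbar <- (x1 + x2) / (n1 + n2)
  if (pbar <= 0 || pbar >= 1)
    stop("pooled proportion is degenerate (0 or 1); Z undefined")
  z <- (x1 / n1 - x2 / n2) / sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Transmission disequilibrium test
#'
#' Compares transmitted vs untransmitted parental CNVs with the classic
#' one-degree-of-freedom chi-square `(T - NT)^2 / (T + NT)`, where `T` is
#' the number of parental CNVs transmitted to the child and
#' `NT = n - T` the untransmitted remainder. An exact binomial test
#' (`T ~ Binom(n, 1/2)`) is available as an alternative.
#'
#' @param transmitted Number of transmitted parental CNVs (`T`).
#' @param parental_total Total parental CNVs (`n`).
#' @param exact Use the exact binomial p-value instead of chi-square.
#' @return list `transmitted`, `untransmitted`, `n`, `rate` (`T/n`),
#'   `chi2`, `p`.
#' @export
#' @examples
#' tdt(15, 44)  # rate 34.1%, p = 0.03
tdt <- function(transmitted, parental_total, exact = FALSE) {
  if (parental_total < 1) stop("parental_total must be >= 1")
  if (transmitted < 0 || transmitted > parental_total)
    stop("transmitted must lie in [0, parental_total]")
  nt <- parental_total - transmitted
  chi2 <- (transmitted - nt)^2 / parental_total
  p <- if (exact) binom.test(transmitted, parental_total, 0.5)$p.value
  else pchisq(chi2, df = 1, lower.tail = FALSE)
  list(transmitted = transmitted, untransmitted = nt, n = parental_total,
       rate = transmitted / parental_total, chi2 = chi2, p = p)
}

prev_block <- function(x, n, conf, prefix) {
  ci <- wilson_ci(x, n, conf)
  out <- list(x, 1e4 * x / n, 1e4 * ci[["lower"]], 1e4 * ci[["upper"]])
  names(out) <- paste0(prefix, c("_n", "_prev", "_ci_low", "_ci_high"))
  out
}

#' Build cohort summary tables from per-region counts
#'
#' Computes the three publication-style summaries from count data alone:
#' cumulative prevalence rows (all / inherited / de novo, split by
#' deletion/duplication, with Wilson intervals per 10,000 and a
#' deletion-vs-duplication two-proportion Z-test), per-region prevalence
#' rows, and parental transmission rows (prevalence, transmission rate,
#' TDT). This "counts mode" makes published count tables first-class
#' inputs, with no CNV calling involved.
#'
#' @param region_counts data.frame in the shape of
#'   [reference_region_counts()].
#' @param totals Named vector in the shape of
#'   [reference_cohort_totals()] (`n_trios`, `mother_events`,
#'   `father_events`, `transmitted_maternal`, `transmitted_paternal`).
#' @param conf Confidence level.
#' @return list of data.frames `cumulative`, `per_region`, `transmission`.
#' @export
summarize_counts <- function(region_counts, totals, conf = 0.95) {
  n <- totals[["n_trios"]]
  rc <- region_counts
  rc$n_inherited <- rc$inherited_maternal + rc$inherited_paternal
  rc$n_total <- rc$n_denovo + rc$n_inherited
  del <- rc$class == "deletion"

  cum_row <- function(label, x_del, x_dup) {
    zt <- if (x_del + x_dup > 0) two_prop_z(x_del, n, x_dup, n)
    else list(z = NA_real_, p = NA_real_)
    c(list(subset = label),
      prev_block(x_del, n, conf, "del"),
      prev_block(x_dup, n, conf, "dup"),
      prev_block(x_del + x_dup, n, conf, "total"),
      list(z = zt$z, p = zt$p))
  }
  cumulative <- rbind(
    as.data.frame(cum_row("all", sum(rc$n_total[del]), sum(rc$n_total[!del]))),
    as.data.frame(cum_row("inherited", sum(rc$n_inherited[del]),
                          sum(rc$n_inherited[!del]))),
    as.data.frame(cum_row("de_novo", sum(rc$n_denovo[del]),
                          sum(rc$n_denovo[!del]))))

  per_region <- do.call(rbind, lapply(seq_len(nrow(rc)), function(i) {
    as.data.frame(c(list(region = rc$region[i], class = rc$class[i]),
                    prev_block(rc$n_denovo[i], n, conf, "denovo"),
                    prev_block(rc$inherited_maternal[i], n, conf, "inh_mat"),
                    prev_block(rc$inherited_paternal[i], n, conf, "inh_pat"),
                    prev_block(rc$n_total[i], n, conf, "total")))
  }))

  trans_row <- function(label, n_parent, n_trans) {
    t <- if (n_parent > 0) tdt(n_trans, n_parent)
    else list(rate = NA_real_, chi2 = NA_real_, p = NA_real_)
    ci <- wilson_ci(n_parent, n, conf)
    data.frame(side = label, parent_events = n_parent,
               transmitted = n_trans, rate_pct = 100 * t$rate,
               chi2 = t$chi2, p = t$p,
               parent_prev = 1e4 * n_parent / n,
               parent_ci_low = 1e4 * ci[["lower"]],
               parent_ci_high = 1e4 * ci[["upper"]])
  }
  transmission <- rbind(
    trans_row("maternal", totals[["mother_events"]],
              totals[["transmitted_maternal"]]),
    trans_row("paternal", totals[["father_events"]],
              totals[["transmitted_paternal"]]),
    trans_row("combined",
              totals[["mother_events"]] + totals[["father_events"]],
              totals[["transmitted_maternal"]] +
                totals[["transmitted_paternal"]]))

  list(cumulative = cumulative, per_region = per_region,
       transmission = transmission)
}

#' Build summary tables from classified calls
#'
#' Tallies classified offspring calls and region-matched parental calls
#' into the count structures of [summarize_counts()] and computes the
#' summary tables. Ambiguous (both-parent) calls are reported in the
#' returned counts but excluded from per-parent tallies.
#'
#' @param classified Classified offspring calls
#'   ([classify_inheritance()] + [resolve_parent_origin()]).
#' @param parental_matched Region-matched parental calls
#'   ([match_ndd_regions()] on the parents' post-filter calls).
#' @param pedigree Trio pedigree (defines mother/father roles).
#' @param regions Region table; rows are emitted for every (region, class)
#'   even when empty.
#' @param n_trios Number of QC-passing trios (the prevalence denominator).
#' @param conf Confidence level.
#' @return As [summarize_counts()], plus `region_counts` and `totals`.
#' @export
build_summary_tables <- function(classified, parental_matched, pedigree,
                                 regions = ndd_regions(), n_trios,
                                 conf = 0.95) {
  grid <- expand.grid(region = regions$region,
                      class = c("deletion", "duplication"),
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$region, regions$region)), ]
  tally <- function(pred) {
    vapply(seq_len(nrow(grid)), function(i)
      sum(pred & classified$region == grid$region[i] &
            classified$class == grid$class[i]), numeric(1))
  }
  region_counts <- data.frame(
    region = grid$region, class = grid$class,
    n_denovo = tally(classified$status == "de_novo"),
    denovo_maternal = tally(classified$status == "de_novo" &
                              classified$origin == "maternal"),
    denovo_paternal = tally(classified$status == "de_novo" &
                              classified$origin == "paternal"),
    denovo_unresolved = tally(classified$status == "de_novo" &
                                classified$origin == "unresolved"),
    inherited_maternal = tally(classified$status == "inherited_maternal"),
    inherited_paternal = tally(classified$status == "inherited_paternal"),
    n_mosaic = tally(isTRUE_vec(classified$mosaic)),
    n_ambiguous = tally(classified$status == "ambiguous"),
    stringsAsFactors = FALSE)

  is_mother <- parental_matched$sample %in% pedigree$mother
  is_father <- parental_matched$sample %in% pedigree$father
  totals <- c(
    n_trios = n_trios,
    mother_events = sum(is_mother),
    father_events = sum(is_father),
    transmitted_maternal = sum(classified$status == "inherited_maternal"),
    transmitted_paternal = sum(classified$status == "inherited_paternal"))

  out <- summarize_counts(region_counts, totals, conf)
  out$region_counts <- region_counts
  out$totals <- totals
  out
}

isTRUE_vec <- function(x) {
  if (is.null(x)) return(FALSE)
  !is.na(x) & x
}
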