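test_that("Wilson intervals reproduce the published cohort values", {
  # 59 carriers of 12,252 trios: (37.35, 62.06) per 10,000
  ci <- wilson_ci(59, 12252) * 1e4
  expect_equal(round(unname(ci), 2), c(37.35, 62.06))
  # zero events: lower bound exactly 0, upper ~0.0003 as a proportion
  ci0 <- wilson_ci(0, 12252)
  expect_equal(unname(ci0[1]), 0)
  expect_equal(signif(unname(ci0[2]), 1), 3e-4)
  # all events: upper bound exactly 1 (mirror of the zero case)
  expect_equal(unname(wilson_ci(100, 100)[2]), 1)
})

test_that("Wilson intervals agree with the score test inversion in stats", {
  for (x in c(0, 1, 5, 20, 59)) {
    for (n in c(100, 12252)) {
      ours <- unname(wilson_ci(x, n))
      ref <- as.vector(prop.test(x, n, correct = FALSE)$conf.int)
      expect_equal(ours, ref, tolerance = 1e-9)
    }
  }
})

test_that("Wilson interval properties: contains p-hat, narrows with n", {
  set.seed(3)
  for (i in 1:50) {
    n <- sample(10:5000, 1); x <- sample(0:n, 1)
    ci <- wilson_ci(x, n)
    expect_lte(ci[["lower"]], x / n + 1e-12)
    expect_gte(ci[["upper"]], x / n - 1e-12)
  }
  w1 <- diff(wilson_ci(10, 100))
  w2 <- diff(wilson_ci(100, 1000))
  expect_lt(w2, w1)  # same proportion, larger n
  expect_error(wilson_ci(5, 0), "n")
  expect_error(wilson_ci(7, 5), "x")
})

test_that("two-proportion Z-test reproduces the published comparisons", {
  # all deletions vs duplications: 25 vs 34 in 12,252
  zt <- two_prop_z(25, 12252, 34, 12252)
  expect_equal(round(zt$z, 2), -1.17)
  expect_equal(round(zt$p, 2), 0.24)
  # inherited: 12 vs 27
  zt2 <- two_prop_z(12, 12252, 27, 12252)
  expect_equal(round(zt2$z, 1), -2.4)
  expect_equal(round(zt2$p, 3), 0.016)
  # de novo: 13 vs 7
  zt3 <- two_prop_z(13, 12252, 7, 12252)
  expect_equal(round(zt3$z, 2), 1.34)
  expect_equal(round(zt3$p, 2), 0.18)
})

test_that("Z-test is antisymmetric and matches the chi-square relation", {
  a <- two_prop_z(13, 500, 29, 700)
  b <- two_prop_z(29, 700, 13, 500)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  # identity case
  eq <- two_prop_z(5, 100, 5, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  # Z^2 equals the uncorrected chi-square test statistic
  pt <- prop.test(c(13, 29), c(500, 700), correct = FALSE)
  expect_equal(a$z^2, unname(pt$statistic), tolerance = 1e-9)
  expect_error(two_prop_z(0, 10, 0, 10), "degenerate")
})

test_that("the TDT reproduces the published transmission statistics", {
  # paternal: 15 of 44 transmitted
  t1 <- tdt(15, 44)
  expect_equal(round(100 * t1$rate, 2), 34.09)
  expect_equal(round(t1$p, 2), 0.03)
  expect_equal(t1$chi2, (15 - 29)^2 / 44)
  # combined: 39 of 87
  t2 <- tdt(39, 87)
  expect_equal(round(t2$p, 2), 0.33)
  expect_equal(round(100 * t2$rate), 45)
  # maternal: 24 of 43 -> 55.81%
  expect_equal(round(100 * tdt(24, 43)$rate, 2), 55.81)
  # balanced transmission
  t0 <- tdt(22, 44)
  expect_equal(t0$chi2, 0)
  expect_equal(t0$p, 1)
})

test_that("TDT symmetry and the exact binomial option", {
  a <- tdt(10, 40); b <- tdt(30, 40)
  expect_equal(a$chi2, b$chi2)
  expect_equal(a$p, b$p)
  ex <- tdt(10, 40, exact = TRUE)
  expect_equal(ex$p, binom.test(10, 40, 0.5)$p.value)
  expect_error(tdt(5, 0), "parental_total")
  expect_error(tdt(9, 5), "transmitted")
})

test_that("counts-mode summary tables reproduce the published cohort", {
  tabs <- summarize_counts(reference_region_counts(),
                           reference_cohort_totals())
  cum <- tabs$cumulative
  all_row <- cum[cum$subset == "all", ]
  expect_equal(c(all_row$del_n, all_row$dup_n, all_row$total_n),
               c(25, 34, 59))
  expect_equal(round(c(all_row$del_prev, all_row$dup_prev, all_row$total_prev),
                     2), c(20.40, 27.75, 48.16))
  expect_equal(round(c(all_row$total_ci_low, all_row$total_ci_high), 2),
               c(37.35, 62.06))
  expect_equal(round(all_row$z, 2), -1.17)

  inh <- cum[cum$subset == "inherited", ]
  expect_equal(c(inh$del_n, inh$dup_n, inh$total_n), c(12, 27, 39))
  expect_equal(round(c(inh$total_ci_low, inh$total_ci_high), 2),
               c(23.30, 43.48))
  expect_equal(round(inh$z, 1), -2.4)

  dn <- cum[cum$subset == "de_novo", ]
  expect_equal(c(dn$del_n, dn$dup_n, dn$total_n), c(13, 7, 20))
  expect_equal(round(c(dn$total_ci_low, dn$total_ci_high), 2),
               c(10.57, 25.20))

  pr <- tabs$per_region
  q <- pr[pr$region == "1q21.1" & pr$class == "deletion", ]
  expect_equal(q$total_n, 6)
  expect_equal(round(c(q$total_prev, q$total_ci_low, q$total_ci_high), 2),
               c(4.90, 2.24, 10.68))
  expect_equal(q$denovo_n, 2)
  expect_equal(round(c(q$denovo_ci_low, q$denovo_ci_high), 2), c(0.45, 5.95))

  tr <- tabs$transmission
  expect_equal(round(tr$rate_pct[tr$side == "maternal"], 2), 55.81)
  expect_equal(round(tr$rate_pct[tr$side == "paternal"], 2), 34.09)
  expect_equal(round(tr$p[tr$side == "paternal"], 2), 0.03)
  expect_equal(round(tr$p[tr$side == "combined"], 2), 0.33)
  # parental prevalence: 43 mothers -> 0.35% (0.26, 0.47)
  mat <- tr[tr$side == "maternal", ]
  expect_equal(round(c(mat$parent_prev, mat$parent_ci_low,
                       mat$parent_ci_high) / 1e4 * 100, 2),
               c(0.35, 0.26, 0.47))
})

test_that("summary tables reconcile counts across groupings", {
  tabs <- summarize_counts(reference_region_counts(),
                           reference_cohort_totals())
  cum <- tabs$cumulative
  pr <- tabs$per_region
  expect_equal(cum$total_n[cum$subset == "all"],
               cum$total_n[cum$subset == "inherited"] +
                 cum$total_n[cum$subset == "de_novo"])
  expect_equal(sum(pr$total_n), cum$total_n[cum$subset == "all"])
  expect_equal(sum(pr$denovo_n), cum$total_n[cum$subset == "de_novo"])
  expect_equal(sum(pr$inh_mat_n) + sum(pr$inh_pat_n),
               cum$total_n[cum$subset == "inherited"])
})

test_that("an empty cohort yields all-zero tables with upper bounds only", {
  rc <- reference_region_counts()
  rc[3:9] <- 0
  totals <- c(n_trios = 1000, mother_events = 0, father_events = 0,
              transmitted_maternal = 0, transmitted_paternal = 0)
  tabs <- summarize_counts(rc, totals)
  expect_true(all(tabs$cumulative$total_n == 0))
  expect_true(all(tabs$cumulative$total_ci_low == 0))
  expect_true(all(tabs$cumulative$total_ci_high > 0))
  expect_true(all(is.na(tabs$cumulative$z)))
  expect_true(all(is.na(tabs$transmission$p)))
})
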