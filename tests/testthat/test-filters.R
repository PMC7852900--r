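test_that("packaged region lengths match the published table to 6 decimals", {
  r <- ndd_regions()
  printed <- c(`1q21.1` = 0.817732, `3q29` = 1.586626, `7q11.23` = 1.399605,
               `15q11.2-13.1` = 5.815783, `15q13.3` = 1.371062,
               `16p11.2_distal` = 0.223645, `16p11.2_proximal` = 0.544304,
               `17p13.3` = 1.341075, `17p11.2` = 3.405089, `17q12` = 1.3991,
               `17q21.31` = 0.459037, `22q11.2` = 2.444275,
               `22q11.2_distal` = 1.731716)
  expect_equal(setNames(r$length_mb, r$region), printed, tolerance = 1e-9)
})

test_that("the parental frequency filter removes >1% clusters cohort-wide", {
  parents <- paste0("p", 1:200)
  # shared variant in 3 of 200 parents (1.5%) plus a child carrier
  common <- do.call(rbind, lapply(c("p1", "p2", "p3", "kid1"), function(s)
    call_row(s, 1e6, 1.2e6, 1)))
  # variant in 1 of 200 parents (0.5%)
  rare <- rbind(call_row("p9", 5e6, 5.3e6, 3), call_row("kid2", 5e6, 5.3e6, 3))
  out <- parental_frequency_filter(rbind(common, rare), parents)
  expect_equal(sort(out$sample), c("kid2", "p9"))
  expect_error(parental_frequency_filter(common, character(0)), "empty")
})

test_that("offspring-only variants never contribute to the frequency", {
  parents <- paste0("p", 1:100)
  kids_only <- do.call(rbind, lapply(paste0("kid", 1:30), function(s)
    call_row(s, 2e6, 2.4e6, 1)))
  out <- parental_frequency_filter(kids_only, parents)
  expect_equal(nrow(out), 30)
})

test_that("frequency clustering requires 50% reciprocal overlap", {
  # 40% reciprocal overlap -> distinct clusters
  a <- call_row("p1", 1, 100000, 1)
  b <- call_row("p2", 60001, 160000, 1)
  expect_equal(length(unique(cluster_calls(rbind(a, b)))), 2)
  # 60% -> one cluster; opposite classes always distinct
  c2 <- call_row("p2", 40001, 140000, 1)
  expect_equal(length(unique(cluster_calls(rbind(a, c2)))), 1)
  d <- call_row("p2", 1, 100000, 3)
  expect_equal(length(unique(cluster_calls(rbind(a, d)))), 2)
})

test_that("blacklist exclusion is 1-bp-overlap semantics", {
  bl <- data.frame(region = "bad", chrom = "1", start = 2e6, end = 3e6)
  inside <- call_row("s1", 2.2e6, 2.4e6, 1)
  spanning <- call_row("s1", 1.9e6, 2.0001e6, 1)
  abutting <- call_row("s1", 1e6, 2e6 - 1, 1)
  expect_equal(nrow(exclude_blacklist(inside, bl)), 0)
  expect_equal(nrow(exclude_blacklist(spanning, bl)), 0)
  expect_equal(nrow(exclude_blacklist(abutting, bl)), 1)
  expect_identical(exclude_blacklist(abutting, bl[0, ]), abutting)
})

test_that("size and marker-count thresholds are inclusive at-least rules", {
  too_short <- call_row("s1", 1, 99999, 1, n_markers = 15)
  too_sparse <- call_row("s1", 1, 150000, 1, n_markers = 9)
  ok <- call_row("s1", 1, 150000, 1, n_markers = 12)
  exactly <- call_row("s1", 1, 100000, 1, n_markers = 10)
  kept <- size_marker_filter(rbind(too_short, too_sparse, ok, exactly))
  expect_equal(nrow(kept), 2)
  expect_true(all(kept$end %in% c(150000, 100000) & kept$n_markers >= 10))
})

test_that("region matching requires covering half of the region", {
  r <- ndd_regions()
  q <- r[r$region == "1q21.1", ]
  sixty <- call_row("s1", q$start, q$start + 0.5e6, 1, chrom = q$chrom)
  thirty <- call_row("s1", q$start, q$start + 0.3e6, 1, chrom = q$chrom)
  full <- call_row("s1", q$start - 1e5, q$end + 1e5, 3, chrom = q$chrom)
  m <- match_ndd_regions(rbind(sixty, thirty, full), r)
  expect_equal(nrow(m), 2)
  expect_equal(m$class, c("deletion", "duplication"))
  expect_true(all(m$region == "1q21.1"))
  expect_gte(m$region_overlap[2], 1)
})

test_that("size and blacklist filters commute", {
  set.seed(41)
  calls <- do.call(rbind, lapply(1:60, function(i) {
    st <- runif(1, 1, 5e7)
    call_row(paste0("s", i), st, st + runif(1, 5e4, 5e5), sample(c(1, 3), 1),
             n_markers = sample(5:30, 1))
  }))
  bl <- data.frame(region = "b", chrom = "1",
                   start = c(5e6, 3e7), end = c(6e6, 3.2e7))
  ab <- exclude_blacklist(size_marker_filter(calls), bl)
  ba <- size_marker_filter(exclude_blacklist(calls, bl))
  expect_equal(ab[order(ab$sample), ], ba[order(ba$sample), ],
               ignore_attr = TRUE)
})
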