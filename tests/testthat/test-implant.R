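# worked single-trio fixtures: 6 markers, event spans markers 2..5

imp_map <- function() even_map(6, len = 6e6, pfb = rep(0.5, 6))
span <- c(1.5e6, 4.4e6)  # covers markers 2..5 of even_map(6, 6e6)

test_that("de novo deletion retains exactly the other parent's allele", {
  map <- imp_map()
  geno <- toy_geno(map, mother_h1 = c(1, 1, 1, 1, 1, 1), mother_h2 = rep(1, 6),
                   father_h1 = c(0, 0, 0, 1, 0, 0), father_h2 = rep(0, 6))
  ac <- implant_cnv(geno, event_row("T1_c", span[1], span[2], 1,
                                    origin = "maternal"))
  tot <- unname(ac$A[, "T1_c"] + ac$B[, "T1_c"])
  expect_equal(tot, c(2, 1, 1, 1, 1, 2))
  # retained allele is the paternal transmitted one at every span marker
  expect_equal(unname(ac$B[2:5, "T1_c"]), as.numeric(geno$child_pat[2:5, 1]))
})

test_that("de novo duplication adds an origin-parent allele (worked case)", {
  map <- imp_map()
  # mother BB, father AA -> child base AB; paternal CN3 adds an A
  geno <- toy_geno(map, mother_h1 = rep(1, 6), mother_h2 = rep(1, 6),
                   father_h1 = rep(0, 6), father_h2 = rep(0, 6))
  ac <- implant_cnv(geno, event_row("T1_c", span[1], span[2], 3,
                                    origin = "paternal"))
  expect_equal(unname(ac$A[3, "T1_c"]), 2)  # A:2, B:1
  expect_equal(unname(ac$B[3, "T1_c"]), 1)
  sig <- render_signals(ac, zero_noise())
  expect_equal(unname(sig$baf[3, "T1_c"]), 1 / 3)
})

test_that("mosaic gain renders the shifted heterozygous BAF bands", {
  f <- 0.4
  map <- imp_map()
  # child het A(pat)/B(mat); maternal gain duplicates the transmitted B
  geno <- toy_geno(map, mother_h1 = rep(1, 6), mother_h2 = rep(1, 6),
                   father_h1 = rep(0, 6), father_h2 = rep(0, 6))
  ac <- implant_cnv(geno, event_row("T1_c", span[1], span[2], 3,
                                    origin = "maternal", mosaic = f),
                    dup_from_transmitted_only = TRUE)
  sig <- render_signals(ac, zero_noise())
  expect_equal(unname(sig$baf[3, "T1_c"]), (1 + f) / (2 + f), tolerance = 1e-12)
  # the mirrored lower band for a duplicated A allele
  ac2 <- implant_cnv(geno, event_row("T1_c", span[1], span[2], 3,
                                     origin = "paternal", mosaic = f),
                     dup_from_transmitted_only = TRUE)
  sig2 <- render_signals(ac2, zero_noise())
  expect_equal(unname(sig2$baf[3, "T1_c"]), 1 / (2 + f), tolerance = 1e-12)
})

test_that("inherited events implant in the parent and transmit", {
  map <- imp_map()
  geno <- simulate_trio_genotypes(map, 1, seed = 4)
  ids <- geno$trios
  ac <- implant_cnv(geno, event_row(ids$child, span[1], span[2], 1,
                                    origin = "maternal", mode = "inherited"))
  expect_equal(unname(ac$A[2:5, ids$mother] + ac$B[2:5, ids$mother]), rep(1, 4))
  expect_equal(unname(ac$A[2:5, ids$child] + ac$B[2:5, ids$child]), rep(1, 4))
  # father untouched
  expect_equal(unname(ac$A[, ids$father] + ac$B[, ids$father]), rep(2, 6))
})

test_that("untransmitted parental carriers leave the child diploid", {
  map <- imp_map()
  geno <- simulate_trio_genotypes(map, 1, seed = 6)
  ids <- geno$trios
  ac <- implant_cnv(geno, event_row(ids$father, span[1], span[2], 3,
                                    origin = "paternal",
                                    mode = "untransmitted"))
  expect_equal(unname(ac$A[3, ids$father] + ac$B[3, ids$father]), 3)
  expect_true(all(ac$A[, ids$child] + ac$B[, ids$child] == 2))
})

test_that("CN0 and CN4 events and overlap rejection behave", {
  map <- imp_map()
  geno <- simulate_trio_genotypes(map, 1, seed = 8)
  ids <- geno$trios
  ac0 <- implant_cnv(geno, event_row(ids$child, span[1], span[2], 0))
  expect_true(all(ac0$A[2:5, ids$child] + ac0$B[2:5, ids$child] == 0))
  ac4 <- implant_cnv(geno, event_row(ids$child, span[1], span[2], 4))
  expect_true(all(ac4$A[2:5, ids$child] + ac4$B[2:5, ids$child] == 4))
  two <- rbind(event_row(ids$child, span[1], span[2], 1),
               event_row(ids$child, span[1] + 1e6, span[2] + 1e6, 3))
  expect_error(implant_cnv(geno, two), "overlapping events")
})

test_that("every truth event is recoverable from the allele counts", {
  cfg <- quick_config(n_trios = 60)
  coh <- generate_cohort(cfg, seed = 31)
  truth <- coh$truth
  constitutional <- truth[truth$mosaic_fraction == 1, , drop = FALSE]
  expect_gt(nrow(constitutional), 0)
  for (i in seq_len(nrow(constitutional))) {
    ev <- constitutional[i, ]
    idx <- which(coh$map$chrom == ev$chrom & coh$map$position >= ev$start &
                   coh$map$position <= ev$end)
    tot <- coh$allele_counts$A[idx, ev$carrier] +
      coh$allele_counts$B[idx, ev$carrier]
    expect_true(all(tot == ev$copy_number))
  }
})
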