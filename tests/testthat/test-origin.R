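# genotype encoding: B-allele copy counts (child of 1 or 3, parents of 2)

test_that("deletion origin follows Mendelian forcing of the retained allele", {
  # retained B, mother AA, father AB: mother cannot supply B, so the
  # retained allele is paternal and the deleted homolog maternal
  out <- infer_deletion_origin(rep(1L, 5), rep(0L, 5), rep(1L, 5))
  expect_equal(out$origin, "maternal")
  expect_true(all(out$verdicts == "maternal"))

  # retained A with both parents AA: uninformative everywhere -> unresolved
  out2 <- infer_deletion_origin(rep(0L, 5), rep(0L, 5), rep(0L, 5))
  expect_equal(out2$origin, "unresolved")
  expect_equal(unname(out2$counts[["uninformative"]]), 5)

  # retained B with neither parent carrying B: inconsistent
  v <- triocnv:::deletion_verdicts(1L, 0L, 0L)
  expect_equal(v, "inconsistent")

  expect_error(infer_deletion_origin(2L, 1L, 1L), "copy number 1")
})

test_that("duplication origin enumeration reproduces the worked cases", {
  # child A:2,B:1; mother BB, father AA -> paternal
  expect_equal(triocnv:::duplication_verdicts(1L, 2L, 0L), "paternal")
  # child A:1,B:2; mother AB, father AA -> maternal
  expect_equal(triocnv:::duplication_verdicts(2L, 1L, 0L), "maternal")
  # child A:2,B:1; mother AB, father AA -> both hypotheses fit
  expect_equal(triocnv:::duplication_verdicts(1L, 1L, 0L), "uninformative")
  # impossible allele combination -> inconsistent
  expect_equal(triocnv:::duplication_verdicts(3L, 0L, 0L), "inconsistent")
})

test_that("verdicts are symmetric under parent swap with allele relabeling", {
  set.seed(55)
  flip <- c(maternal = "paternal", paternal = "maternal",
            uninformative = "uninformative", inconsistent = "inconsistent")
  for (i in 1:200) {
    mb <- sample(0:2, 1); fb <- sample(0:2, 1)
    cb1 <- sample(0:1, 1)
    v <- triocnv:::deletion_verdicts(cb1, mb, fb)
    # swap parents and relabel A<->B
    v_sym <- triocnv:::deletion_verdicts(1L - cb1, 2L - fb, 2L - mb)
    expect_identical(unname(flip[v]), v_sym)
    cb3 <- sample(0:3, 1)
    d <- triocnv:::duplication_verdicts(cb3, mb, fb)
    d_sym <- triocnv:::duplication_verdicts(3L - cb3, 2L - fb, 2L - mb)
    expect_identical(unname(flip[d]), d_sym)
  }
})

test_that("strict same-allele mode tightens the duplication hypothesis", {
  # child A:1,B:2; mother AB, father BB
  # NAHR mode: maternal pair {A,B} + paternal B fits, and so does
  # paternal {B,B} + maternal A -> uninformative
  expect_equal(triocnv:::duplication_verdicts(2L, 1L, 2L, nahr = TRUE),
               "uninformative")
  # strict mode: the maternal pair must be a doubled allele {A,A} or {B,B},
  # neither of which yields A:1,B:2 with a paternal B -> paternal
  expect_equal(triocnv:::duplication_verdicts(2L, 1L, 2L, nahr = FALSE),
               "paternal")
})

test_that("aggregation demands enough informative, concordant markers", {
  # 2 informative markers < 3 -> unresolved
  out <- infer_deletion_origin(c(1L, 1L), c(0L, 0L), c(1L, 1L))
  expect_equal(out$origin, "unresolved")
  # 6 maternal vs 4 paternal verdicts: 60% concordance < 80% -> unresolved
  child <- rep(1L, 10)
  mother <- c(rep(0L, 6), rep(2L, 4))
  father <- c(rep(1L, 6), rep(0L, 4))
  out2 <- infer_deletion_origin(child, mother, father)
  expect_equal(unname(out2$counts[["maternal"]]), 6)
  expect_equal(unname(out2$counts[["paternal"]]), 4)
  expect_equal(out2$origin, "unresolved")
  # 9 vs 1 passes the 80% concordance bar
  mother3 <- c(rep(0L, 9), 2L)
  father3 <- c(rep(1L, 9), 0L)
  expect_equal(infer_deletion_origin(child, mother3, father3)$origin,
               "maternal")
})

test_that("a high inconsistent-marker rate triggers an integrity warning", {
  child <- rep(1L, 10)
  mother <- rep(0L, 10)
  father <- c(rep(1L, 6), rep(0L, 4))  # 4 markers impossible
  expect_warning(infer_deletion_origin(child, mother, father),
                 "inconsistent")
})

test_that("BAF band assignment discards out-of-tolerance markers", {
  b <- baf_to_b_count(c(0, 0.33, 0.52, 0.45, 1), 3)
  expect_equal(b, c(0L, 1L, NA_integer_, NA_integer_, 3L))
  b2 <- baf_to_b_count(c(0.02, 0.5, 0.97), 2)
  expect_equal(b2, c(0L, 1L, 2L))
})

test_that("origin inference is near-perfect on simulated de novo events", {
  set.seed(91)
  n_rep <- 60
  correct <- 0; resolved <- 0
  for (i in 1:n_rep) {
    map <- even_map(120, len = 3e6, seed = i)
    geno <- simulate_trio_genotypes(map, 1, seed = 1000 + i)
    ids <- geno$trios
    cn <- if (i %% 2 == 0) 1L else 3L
    origin <- if (i %% 4 < 2) "maternal" else "paternal"
    ac <- implant_cnv(geno, event_row(ids$child, 1, 3e6, cn, origin = origin),
                      seed = 2000 + i)
    child_b <- ac$B[, ids$child]
    mother_b <- ac$B[, ids$mother]
    father_b <- ac$B[, ids$father]
    res <- if (cn == 1L)
      infer_deletion_origin(child_b, mother_b, father_b)
    else infer_duplication_origin(child_b, mother_b, father_b)
    expect_equal(unname(res$counts[["inconsistent"]]), 0)
    if (res$origin != "unresolved") {
      resolved <- resolved + 1
      if (res$origin == origin) correct <- correct + 1
    }
  }
  expect_gt(resolved, 0.9 * n_rep)
  expect_equal(correct, resolved)  # never wrong on exact genotypes
})

test_that("CN4 calls are left unresolved with a warning", {
  map <- even_map(60, len = 2e6, pfb = rep(0.5, 60))
  geno <- simulate_trio_genotypes(map, 1, seed = 3)
  ids <- geno$trios
  ac <- implant_cnv(geno, event_row(ids$child, 1, 2e6, 4))
  sig <- render_signals(ac, zero_noise())
  cl <- call_row(ids$child, 1, 2e6, 4)
  cl$region <- "R"; cl$class <- "duplication"; cl$region_overlap <- 1
  cl$status <- "de_novo"; cl$origin <- "unresolved"
  expect_warning(out <- resolve_parent_origin(cl, sig, geno$trios), "CN4")
  expect_equal(out$origin, "unresolved")
})
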