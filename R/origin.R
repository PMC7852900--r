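#' Assign allele copy counts from a BAF value
#'
#' At total copy number `cn`, the canonical BAF bands lie at `k / cn` for
#' `k` copies of the B allele. The observed BAF is assigned to the nearest
#' band within `tol`; markers outside tolerance are discarded (`NA`),
#' which guards the Mendelian enumeration against noisy markers.
#'
#' @param baf Numeric vector of BAF values.
#' @param cn Total copy number (> 0).
#' @param tol Band assignment tolerance (default 0.08).
#' @return Integer vector of B-allele copy counts (`NA` where
#'   unassignable).
#' @export
baf_to_b_count <- function(baf, cn, tol = 0.08) {
  stopifnot(cn >= 1)
  bands <- (0:cn) / cn
  k <- vapply(baf, function(x) {
    d <- abs(x - bands)
    i <- which.min(d)
    if (d[i] <= tol) i - 1L else NA_integer_
  }, integer(1))
  k
}

# per-marker Mendelian verdict for a hemizygous (CN1) child marker:
# retained allele is tested against each parent; the parent that could NOT
# have transmitted it is the origin of the DELETED homolog
deletion_verdicts <- function(child_b, mother_b, father_b) {
  retained_is_b <- child_b == 1L
  mother_can <- ifelse(retained_is_b, mother_b >= 1L, mother_b <= 1L)
  father_can <- ifelse(retained_is_b, father_b >= 1L, father_b <= 1L)
  verdict <- rep("uninformative", length(child_b))
  verdict[!mother_can & father_can] <- "paternal_retained" # deleted maternal
  verdict[mother_can & !father_can] <- "maternal_retained" # deleted paternal
  verdict[!mother_can & !father_can] <- "inconsistent"
  verdict[is.na(child_b) | is.na(mother_b) | is.na(father_b)] <- "uninformative"
  ifelse(verdict == "paternal_retained", "maternal",
         ifelse(verdict == "maternal_retained", "paternal", verdict))
}

# can a parent with b_parent B alleles (of 2) supply a pair with k B
# alleles? nahr = TRUE allows the pair to combine both homologs
pair_feasible <- function(k, b_parent, nahr) {
  a_parent <- 2L - b_parent
  if (nahr) {
    (k == 0L & a_parent >= 1L) | (k == 1L & a_parent >= 1L & b_parent >= 1L) |
      (k == 2L & b_parent >= 1L)
  } else {
    (k == 0L & a_parent >= 1L) | (k == 2L & b_parent >= 1L)
  }
}

single_feasible <- function(j, b_parent) {
  a_parent <- 2L - b_parent
  (j == 0L & a_parent >= 1L) | (j == 1L & b_parent >= 1L)
}

# per-marker verdict for a CN3 child marker: which parent could have
# supplied the duplicated pair (the other supplying one allele)?
duplication_verdicts <- function(child_b, mother_b, father_b, nahr = TRUE) {
  n <- length(child_b)
  verdict <- character(n)
  for (i in seq_len(n)) {
    cb <- child_b[i]; mb <- mother_b[i]; fb <- father_b[i]
    if (is.na(cb) || is.na(mb) || is.na(fb)) {
      verdict[i] <- "uninformative"; next
    }
    h_mat <- h_pat <- FALSE
    for (k in 0:2) {            # B alleles in the duplicated pair
      j <- cb - k               # B alleles in the single transmitted allele
      if (j < 0L || j > 1L) next
      if (pair_feasible(k, mb, nahr) && single_feasible(j, fb)) h_mat <- TRUE
      if (pair_feasible(k, fb, nahr) && single_feasible(j, mb)) h_pat <- TRUE
    }
    verdict[i] <- if (h_mat && h_pat) "uninformative"
    else if (h_mat) "maternal"
    else if (h_pat) "paternal"
    else "inconsistent"
  }
  verdict
}

aggregate_verdicts <- function(verdict, min_informative, min_concordance,
                               warn_inconsistent = 0.1) {
  counts <- c(maternal = sum(verdict == "maternal"),
              paternal = sum(verdict == "paternal"),
              uninformative = sum(verdict == "uninformative"),
              inconsistent = sum(verdict == "inconsistent"))
  assessed <- sum(counts) - counts[["uninformative"]]
  if (assessed > 0 && counts[["inconsistent"]] / assessed > warn_inconsistent)
    warning("inconsistent-marker rate exceeds ", warn_inconsistent,
            "; possible genotyping error or wrong copy-number model")
  informative <- counts[["maternal"]] + counts[["paternal"]]
  origin <- "unresolved"
  if (informative >= min_informative) {
    top <- max(counts[["maternal"]], counts[["paternal"]])
    if (top / informative >= min_concordance)
      origin <- if (counts[["maternal"]] >= counts[["paternal"]])
        "maternal" else "paternal"
  }
  list(origin = origin, counts = counts)
}

#' Infer the parental origin of a deletion from trio genotypes
#'
#' For each marker in a hemizygous (CN1) span, the single retained allele
#' is tested against both parental genotypes; when one parent could not
#' have transmitted it, the retained allele is from the other parent and
#' the deleted homolog originates from the first. Per-marker verdicts are
#' aggregated by majority, requiring at least `min_informative`
#' informative markers and `min_concordance` concordance.
#'
#' @param child_b,mother_b,father_b Integer vectors of B-allele copy
#'   counts per marker (child: of 1; parents: of 2). `NA` markers are
#'   uninformative.
#' @param min_informative,min_concordance Aggregation thresholds
#'   (defaults: 3 markers, 80%).
#' @return list with `origin` (`maternal`, `paternal`, `unresolved`) and
#'   per-verdict `counts`.
#' @export
infer_deletion_origin <- function(child_b, mother_b, father_b,
                                  min_informative = 3,
                                  min_concordance = 0.8) {
  if (any(child_b > 1L, na.rm = TRUE))
    stop("deletion origin inference requires child copy number 1")
  v <- deletion_verdicts(child_b, mother_b, father_b)
  out <- aggregate_verdicts(v, min_informative, min_concordance)
  out$verdicts <- v
  out
}

#' Infer the parental origin of a duplication from trio genotypes
#'
#' At each CN3 marker the child's three-allele count vector is tested
#' against two hypotheses: the duplicated pair comes from the mother plus
#' one paternal allele (maternal origin), or vice versa. By default the
#' duplicated pair may combine both homologs of the origin parent
#' (interchromosomal NAHR); `nahr = FALSE` restricts it to a doubled
#' single allele. A marker compatible with only one hypothesis is
#' informative; both = uninformative; neither = inconsistent.
#'
#' @param child_b Integer vector of B-allele counts of 3 per marker.
#' @param mother_b,father_b Parental B-allele counts of 2.
#' @param nahr Allow the duplicated pair to span both homologs.
#' @inheritParams infer_deletion_origin
#' @return As [infer_deletion_origin()].
#' @export
infer_duplication_origin <- function(child_b, mother_b, father_b,
                                     nahr = TRUE, min_informative = 3,
                                     min_concordance = 0.8) {
  v <- duplication_verdicts(child_b, mother_b, father_b, nahr)
  out <- aggregate_verdicts(v, min_informative, min_concordance)
  out$verdicts <- v
  out
}

#' Resolve parent-of-origin of de novo calls from array signals
#'
#' For each de novo call, per-marker allele counts are derived from BAF
#' band assignment ([baf_to_b_count()]): the child at its called copy
#' number, the parents as diploid. Deletions (CN1) use the retained-allele
#' test, duplications (CN3) the three-allele enumeration; CN0 and CN4
#' calls are left unresolved (with a warning for CN4).
#'
#' @param classified Classified calls from [classify_inheritance()].
#' @param signals The cohort `signal_set`.
#' @param pedigree Trio pedigree.
#' @param tol BAF band-assignment tolerance.
#' @param nahr,min_informative,min_concordance Passed to the inference
#'   functions.
#' @return `classified` with the `origin` of de novo rows filled in.
#' @export
resolve_parent_origin <- function(classified, signals, pedigree, tol = 0.08,
                                  nahr = TRUE, min_informative = 3,
                                  min_concordance = 0.8) {
  dn <- which(classified$status == "de_novo")
  ped_idx <- match(classified$sample, pedigree$child)
  for (i in dn) {
    cn <- classified$copy_number[i]
    if (cn == 4L) {
      warning("CN4 call left unresolved (origin enumeration covers CN3)")
      next
    }
    if (cn != 1L && cn != 3L) next
    idx <- which(signals$map$chrom == classified$chrom[i] &
                   signals$map$position >= classified$start[i] &
                   signals$map$position <= classified$end[i])
    child_b <- baf_to_b_count(signals$baf[idx, classified$sample[i]], cn, tol)
    mother_b <- baf_to_b_count(
      signals$baf[idx, pedigree$mother[ped_idx[i]]], 2L, tol)
    father_b <- baf_to_b_count(
      signals$baf[idx, pedigree$father[ped_idx[i]]], 2L, tol)
    res <- if (cn == 1L)
      infer_deletion_origin(child_b, mother_b, father_b,
                            min_informative, min_concordance)
    else
      infer_duplication_origin(child_b, mother_b, father_b, nahr,
                               min_informative, min_concordance)
    classified$origin[i] <- res$origin
  }
  classified
}
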