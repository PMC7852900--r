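#' Simulate Mendelian trio genotypes
#'
#' Parental haplotypes are drawn per marker from Hardy-Weinberg proportions
#' at the map's population B-allele frequency (`pfb`); each child allele
#' pair is one transmitted maternal plus one transmitted paternal allele,
#' with the transmitted homolog recorded (transmission is drawn
#' independently per marker, i.e. free recombination in the background).
#'
#' @param map Marker map from [build_marker_map()].
#' @param n_trios Number of mother-father-child trios.
#' @param seed Optional integer seed (bit-for-bit reproducible cohort).
#' @param family_prefix Prefix for family/sample identifiers.
#' @return A `trio_genotypes` object: list with `map`, `trios` (data.frame
#'   `family`, `child`, `father`, `mother`) and integer 0/1 matrices
#'   (markers x trios; 1 = B allele) `mother_h1`, `mother_h2`, `father_h1`,
#'   `father_h2`, `child_mat`, `child_pat` (transmitted alleles) plus
#'   `child_mat_hom`, `child_pat_hom` (1/2: which parental homolog was
#'   transmitted).
#' @export
simulate_trio_genotypes <- function(map, n_trios, seed = NULL,
                                    family_prefix = "F") {
  stopifnot(n_trios >= 1)
  if (any(map$pfb <= 0 | map$pfb >= 1)) stop("pfb must lie in (0, 1)")
  n <- nrow(map)
  with_seed(seed, {
    draw <- function() matrix((runif(n * n_trios) < map$pfb) * 1L,
                              nrow = n, ncol = n_trios)
    mother_h1 <- draw(); mother_h2 <- draw()
    father_h1 <- draw(); father_h2 <- draw()
    pick_hom <- function() matrix((runif(n * n_trios) < 0.5) + 1L, n, n_trios)
    child_mat_hom <- pick_hom()
    child_pat_hom <- pick_hom()
    child_mat <- mother_h2; sel <- child_mat_hom == 1L
    child_mat[sel] <- mother_h1[sel]
    child_pat <- father_h2; sel <- child_pat_hom == 1L
    child_pat[sel] <- father_h1[sel]
    fam <- sprintf("%s%04d", family_prefix, seq_len(n_trios))
    trios <- data.frame(family = fam,
                        child = paste0(fam, "_c"),
                        father = paste0(fam, "_f"),
                        mother = paste0(fam, "_m"),
                        stringsAsFactors = FALSE)
    structure(list(map = map, trios = trios,
                   mother_h1 = mother_h1, mother_h2 = mother_h2,
                   father_h1 = father_h1, father_h2 = father_h2,
                   child_mat = child_mat, child_pat = child_pat,
                   child_mat_hom = child_mat_hom, child_pat_hom = child_pat_hom),
              class = "trio_genotypes")
  })
}

#' @export
print.trio_genotypes <- function(x, ...) {
  cat("trio_genotypes:", nrow(x$map), "markers x", nrow(x$trios), "trios\n")
  invisible(x)
}

#' Convert trio genotypes to per-sample allele copy counts
#'
#' @param geno A `trio_genotypes` object.
#' @return An `allele_counts` object: list with `map`, `samples` (all
#'   mothers, fathers, children) and numeric matrices `A`, `B`
#'   (markers x samples) of per-marker allele copy numbers. Counts are
#'   numeric so that mosaic events can contribute fractional copies.
#' @export
allele_counts <- function(geno) {
  stopifnot(inherits(geno, "trio_genotypes"))
  # alleles are 0/1, so B = h1 + h2 and A = 2 - B
  cnt <- function(h1, h2) { b <- h1 + h2; list(A = 2 - b, B = b) }
  m <- cnt(geno$mother_h1, geno$mother_h2)
  f <- cnt(geno$father_h1, geno$father_h2)
  c_ <- cnt(geno$child_mat, geno$child_pat)
  samples <- c(geno$trios$mother, geno$trios$father, geno$trios$child)
  A <- cbind(m$A, f$A, c_$A); B <- cbind(m$B, f$B, c_$B)
  colnames(A) <- colnames(B) <- samples
  structure(list(map = geno$map, samples = samples,
                 A = A * 1.0, B = B * 1.0,
                 trios = geno$trios),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat("allele_counts:", nrow(x$map), "markers x", length(x$samples),
      "samples\n")
  invisible(x)
}

#' Implant CNV events into trio allele counts
#'
#' Modifies per-marker allele copy counts to reflect a set of ground-truth
#' CNV events. Deletions drop the transmitted allele of the origin parent
#' (both alleles for CN0); duplications add one (CN3) or two (CN4) copies
#' drawn from the origin parent's homologs. Inherited events are implanted
#' in the carrier parent first and then transmitted, so the parent is a
#' carrier too; `mode = "untransmitted"` implants in the parent only.
#' Mosaic gains (`mosaic_fraction < 1`) add fractional copies, which
#' renders as the shifted BAF bands `1/(2+f)` and `(1+f)/(2+f)`.
#'
#' @param geno A `trio_genotypes` object.
#' @param events data.frame of truth events with columns `region`, `chrom`,
#'   `start`, `end`, `carrier` (child sample id; parent id for
#'   `untransmitted`), `copy_number` (0, 1, 3, 4), `origin_parent`
#'   (`"maternal"`/`"paternal"`), `mode` (`"de_novo"`, `"inherited"`,
#'   `"untransmitted"`), `mosaic_fraction` (1 = constitutional).
#' @param dup_from_transmitted_only If `TRUE`, the extra copy of a
#'   duplication always duplicates the transmitted homolog
#'   (intrachromosomal); the default also allows the other homolog,
#'   modelling interchromosomal NAHR.
#' @param seed Optional seed for the homolog choices.
#' @return An `allele_counts` object with a `truth` attribute: the events
#'   table with an added `event_id` column.
#' @export
implant_cnv <- function(geno, events, dup_from_transmitted_only = FALSE,
                        seed = NULL) {
  ac <- allele_counts(geno)
  if (nrow(events) == 0L) {
    attr(ac, "truth") <- cbind(event_id = character(0), events)
    return(ac)
  }
  events$mosaic_fraction <- events$mosaic_fraction %||% 1
  events$event_id <- sprintf("ev%04d", seq_len(nrow(events)))

  # reject overlapping events touching the same individual (an inherited
  # event also modifies the origin parent)
  trio_of <- function(id) {
    r <- match(id, ac$trios$child)
    r[is.na(r)] <- match(id[is.na(r)], ac$trios$mother)
    r[is.na(r)] <- match(id[is.na(r)], ac$trios$father)
    r
  }
  tr_i <- trio_of(events$carrier)
  if (anyNA(tr_i)) stop("unknown carrier: ", events$carrier[is.na(tr_i)][1])
  extra <- ifelse(events$mode == "inherited",
                  ifelse(events$origin_parent == "maternal",
                         ac$trios$mother[tr_i], ac$trios$father[tr_i]),
                  NA_character_)
  touched <- rbind(data.frame(i = seq_len(nrow(events)), id = events$carrier),
                   data.frame(i = which(!is.na(extra)),
                              id = extra[!is.na(extra)]))
  for (s in unique(touched$id)) {
    ev <- events[touched$i[touched$id == s], , drop = FALSE]
    if (nrow(ev) > 1L) {
      gr <- as_granges_calls(ev)
      if (length(GenomicRanges::findOverlaps(gr, drop.self = TRUE)) > 0L)
        stop("overlapping events for carrier ", s)
    }
  }

  n <- nrow(ac$map)
  with_seed(seed, {
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      idx <- which(ac$map$chrom == ev$chrom &
                     ac$map$position >= ev$start & ac$map$position <= ev$end)
      if (length(idx) == 0L) next
      trio_row <- which(ac$trios$child == ev$carrier |
                          ac$trios$mother == ev$carrier |
                          ac$trios$father == ev$carrier)
      if (length(trio_row) != 1L) stop("unknown carrier: ", ev$carrier)
      tr <- ac$trios[trio_row, ]
      maternal <- identical(ev$origin_parent, "maternal")
      parent_id <- if (maternal) tr$mother else tr$father
      h1 <- if (maternal) geno$mother_h1 else geno$father_h1
      h2 <- if (maternal) geno$mother_h2 else geno$father_h2
      trans <- if (maternal) geno$child_mat else geno$child_pat
      hom <- if (maternal) geno$child_mat_hom else geno$child_pat_hom
      f <- ev$mosaic_fraction
      stopifnot(f > 0, f <= 1)

      add <- function(sample, allele, amount) {
        sel <- allele == 0L
        ac$A[idx[sel], sample] <<- ac$A[idx[sel], sample] + amount
        ac$B[idx[!sel], sample] <<- ac$B[idx[!sel], sample] + amount
      }
      pick_extra <- function() {
        # allele(s) of the parental homolog supplying the extra copy
        if (dup_from_transmitted_only) trans[idx, trio_row]
        else if (sample(1:2, 1) == 1L) h1[idx, trio_row]
        else h2[idx, trio_row]
      }

      if (ev$mode == "untransmitted") {
        if (ev$carrier != parent_id)
          stop("untransmitted event carrier must be the origin parent")
        if (ev$copy_number == 1) {
          # delete the non-transmitted parental homolog
          non_trans <- ifelse(hom[idx, trio_row] == 1L,
                              h2[idx, trio_row], h1[idx, trio_row])
          add(parent_id, non_trans, -f)
        } else if (ev$copy_number == 3) {
          add(parent_id, pick_extra(), f)
        } else stop("untransmitted events support CN1 and CN3 only")
      } else if (ev$mode == "de_novo") {
        child <- tr$child
        if (ev$copy_number == 0) {
          add(child, geno$child_mat[idx, trio_row], -f)
          add(child, geno$child_pat[idx, trio_row], -f)
        } else if (ev$copy_number == 1) {
          add(child, trans[idx, trio_row], -f)
        } else if (ev$copy_number == 3) {
          add(child, pick_extra(), f)
        } else if (ev$copy_number == 4) {
          add(child, h1[idx, trio_row], f)
          add(child, h2[idx, trio_row], f)
        } else stop("unsupported copy number: ", ev$copy_number)
      } else if (ev$mode == "inherited") {
        child <- tr$child
        if (ev$copy_number == 1) {
          # child loses the transmitted allele; the parent carries the
          # deletion on the homolog that was transmitted
          add(child, trans[idx, trio_row], -f)
          add(parent_id, trans[idx, trio_row], -f)
        } else if (ev$copy_number == 3) {
          extra <- pick_extra()
          add(parent_id, extra, f)
          add(child, extra, f)
        } else stop("inherited events support CN1 and CN3 only")
      } else stop("unknown event mode: ", ev$mode)
    }
    if (any(ac$A < -1e-9) || any(ac$B < -1e-9))
      stop("event combination produced negative allele counts")
    attr(ac, "truth") <- events
    ac
  })
}
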