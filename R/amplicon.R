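# Amplicon haplotype analysis: read filtering, polymorphic-site and
# haplotype enumeration, tetraploid haplotype-dosage assignment, pairwise
# marker-combination distinguishability, and concordance with reference
# dosage calls.

#' Filter an amplicon read table by depth and haplotype frequency
#'
#' Removes genotypes with fewer than \code{minReads} total reads (strict:
#' 99 reads is removed at the default of 100) and zeroes, per genotype, the
#' haplotypes holding strictly less than \code{minFraction} of the
#' genotype's total reads (exactly 10\% is retained). Haplotypes with no
#' reads left anywhere are dropped from the table with their sequences.
#' The two rules are re-applied until stable, so the output is a fixpoint:
#' filtering a filtered table changes nothing.
#'
#' @param x a \code{\link{HaplotypeTable}}.
#' @param minReads minimum reads per genotype (default 100).
#' @param minFraction minimum per-genotype haplotype read fraction
#'   (default 0.10).
#' @return the filtered \code{\link{HaplotypeTable}}.
#' @export
filterReadTable <- function(x, minReads = 100L, minFraction = 0.10) {
  stopifnot(is(x, "HaplotypeTable"))
  cm <- readCounts(x)
  repeat {
    tot <- rowSums(cm)
    keepG <- tot >= minReads
    cm2 <- cm[keepG, , drop = FALSE]
    tot <- tot[keepG]
    if (nrow(cm2)) {
      small <- sweep(cm2, 1L, minFraction * tot, "<")
      cm2[small] <- 0L
    }
    keepH <- colSums(cm2) > 0
    cm2 <- cm2[, keepH, drop = FALSE]
    if (identical(dim(cm2), dim(cm)) && all(cm2 == cm)) break
    cm <- cm2
  }
  HaplotypeTable(markerId(x), haplotypeSequences(x)[colnames(cm)], cm,
                 x@ampliconLength)
}

#' Assign haplotype dosages to one genotype's read counts
#'
#' Distributes the ploidy (4 for tetraploids) over the genotype's retained
#' (non-zero) haplotypes by largest-remainder rounding of
#' \code{ploidy * read fraction}, with every retained haplotype guaranteed a
#' dosage of at least 1 and the dosages summing exactly to the ploidy. Ties
#' are broken toward the higher-count haplotype, then by haplotype id.
#' A genotype with more retained haplotypes than the ploidy cannot be
#' dosed; \code{NULL} is returned and the caller flags the genotype.
#'
#' @param counts named non-negative numeric vector of reads per haplotype.
#' @param ploidy integer ploidy (default 4).
#' @return named integer vector of dosages over the retained haplotypes
#'   summing to \code{ploidy}, or \code{NULL} when the genotype carries more
#'   retained haplotypes than the ploidy.
#' @examples
#' haplotypeDosages(c(H1 = 750, H2 = 250))   # 3, 1
#' haplotypeDosages(c(H1 = 500, H2 = 500))   # 2, 2
#' @export
haplotypeDosages <- function(counts, ploidy = 4L) {
  if (is.null(names(counts)))
    names(counts) <- paste0("H", seq_along(counts))
  counts <- counts[counts > 0]
  if (!length(counts))
    .validationError("genotype has no retained haplotype")
  if (length(counts) > ploidy) return(NULL)
  ord <- order(-counts, names(counts))        # tie-break order
  counts <- counts[ord]
  q <- ploidy * counts / sum(counts)
  d <- pmax(floor(q), 1)                       # every retained gets >= 1
  # remainders relative to the current allocation, so a haplotype already
  # forced up to the minimum does not compete with its pre-floor remainder
  rem <- q - d
  excess <- sum(d) - ploidy
  if (excess > 0) {
    # forced minimums overshot: take back where allocation most exceeds q
    for (i in seq_len(excess)) {
      cand <- which(d > 1)
      j <- cand[which.min(rem[cand])]
      d[j] <- d[j] - 1
      rem[j] <- rem[j] + 1
    }
  } else if (excess < 0) {
    # distribute remaining copies by largest remainder (already in
    # higher-count-first order, so ties resolve toward higher counts)
    give <- order(-rem)[seq_len(-excess)]
    d[give] <- d[give] + 1
  }
  out <- as.integer(d)
  names(out) <- names(counts)
  out[order(names(out))]
}

.dosageMultisets <- function(x, ploidy = 4L) {
  cm <- readCounts(x)
  labels <- vapply(rownames(cm), function(g) {
    d <- haplotypeDosages(setNames(as.vector(cm[g, ]), colnames(cm)), ploidy)
    if (is.null(d)) NA_character_
    else paste(names(d), d, sep = ":", collapse = ";")
  }, character(1))
  labels
}

#' Summarize an amplicon marker's discrimination statistics
#'
#' Over a filtered table: the number of genotypes retained, the number of
#' polymorphic alignment columns (a column is polymorphic when it carries
#' more than one distinct symbol; the gap "-" counts as a symbol, so a 2-bp
#' indel contributes 2 polymorphic sites), the number of distinct retained
#' haplotypes, and the number of distinguishable genotypes, i.e. distinct
#' haplotype-dosage multisets under the assumed ploidy. Genotypes with more
#' retained haplotypes than the ploidy cannot be dosed and are excluded
#' from the multiset count (and reported).
#'
#' @param x a filtered \code{\link{HaplotypeTable}}.
#' @param ploidy assumed ploidy (default 4).
#' @return list with \code{marker_id, n_genotypes_retained,
#'   n_polymorphic_sites, n_haplotypes, n_distinguishable_genotypes,
#'   flagged_genotypes}.
#' @export
summarizeAmplicon <- function(x, ploidy = 4L) {
  stopifnot(is(x, "HaplotypeTable"))
  cm <- readCounts(x)
  if (!nrow(cm) || !ncol(cm))
    .validationError("empty haplotype table")
  seqs <- as.character(haplotypeSequences(x))
  chars <- do.call(rbind, strsplit(seqs, ""))
  nPoly <- sum(apply(chars, 2L, function(col) length(unique(col)) > 1L))
  labels <- .dosageMultisets(x, ploidy)
  flagged <- names(labels)[is.na(labels)]
  list(marker_id = markerId(x),
       n_genotypes_retained = nrow(cm),
       n_polymorphic_sites = nPoly,
       n_haplotypes = length(unique(seqs)),
       n_distinguishable_genotypes = length(unique(labels[!is.na(labels)])),
       flagged_genotypes = flagged)
}

#' Pairwise marker-combination distinguishability table
#'
#' Symmetric markers x markers table: the diagonal holds each marker's
#' number of distinguishable genotypes (distinct haplotype-dosage
#' multisets); the off-diagonal (i, j) entry holds the number of distinct
#' joint (multiset_i, multiset_j) profiles over the genotypes retained and
#' dosable in both markers.
#'
#' @param tables named list of >= 2 filtered \code{\link{HaplotypeTable}}s.
#' @param ploidy assumed ploidy (default 4).
#' @return integer matrix with marker ids as dimnames.
#' @export
pairwiseCombinationTable <- function(tables, ploidy = 4L) {
  if (length(tables) < 2L)
    .usageError("need at least two markers to combine")
  labels <- lapply(tables, .dosageMultisets, ploidy = ploidy)
  ids <- vapply(tables, markerId, character(1))
  n <- length(tables)
  out <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    li <- labels[[i]][!is.na(labels[[i]])]
    out[i, i] <- length(unique(li))
    for (j in seq_len(n)[-seq_len(i)]) {
      lj <- labels[[j]][!is.na(labels[[j]])]
      shared <- intersect(names(li), names(lj))
      out[i, j] <- out[j, i] <-
        length(unique(paste(li[shared], lj[shared], sep = "|")))
    }
  }
  out
}

#' Concordance between amplicon-derived and reference dosage calls
#'
#' Per marker over the shared accessions: the number of cells scored
#' identically in both sources, scored differently, unscored in total
#' (in either source) and unscored per source, plus the overall agreement
#' fraction over cells scored in both.
#'
#' @param ampliconDosages,referenceDosages \code{\link{ScoreMatrix}} objects
#'   sharing accession and marker indices.
#' @return list with \code{perMarker} (data.frame) and \code{agreement}
#'   (overall fraction over mutually scored cells).
#' @export
concordanceWithReference <- function(ampliconDosages, referenceDosages) {
  .checkSharedIndices(ampliconDosages, referenceDosages)
  al <- .alignTo(referenceDosages, ampliconDosages)
  a <- scores(ampliconDosages)
  r <- al$scores
  rows <- lapply(colnames(a), function(mk) {
    av <- a[, mk]; rv <- r[, mk]
    both <- !is.na(av) & !is.na(rv)
    data.frame(marker_id = mk,
               n_identical = sum(both & av == rv, na.rm = TRUE),
               n_differing = sum(both & av != rv, na.rm = TRUE),
               n_unscored_total = sum(is.na(av) | is.na(rv)),
               n_unscored_reference = sum(is.na(rv)),
               n_unscored_amplicon = sum(is.na(av)))
  })
  perMarker <- do.call(rbind, rows)
  nBoth <- sum(perMarker$n_identical) + sum(perMarker$n_differing)
  list(perMarker = perMarker,
       agreement = if (nBoth) sum(perMarker$n_identical) / nBoth
                   else NA_real_)
}
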