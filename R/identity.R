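# Identity analysis over dosage profiles: Chebyshev distances, duplicate-pair
# classification, identical-profile clustering, and the combinatorics of how
# many markers a panel needs.

#' Chebyshev (maximum) distance matrix over dosage profiles
#'
#' d(a, b) is the maximum absolute dosage difference over the markers scored
#' in both accessions. Pairs with no mutually scored marker are flagged with
#' \code{NA} rather than silently set to 0 or infinity.
#'
#' @param x a \code{\link{ScoreMatrix}}.
#' @return symmetric numeric matrix with zero diagonal; entries in 0..4 or
#'   \code{NA} for no-overlap pairs.
#' @examples
#' m <- ScoreMatrix(matrix(c(0L, 4L, 1L, 1L, 4L, 0L), 2, 3,
#'      dimnames = list(c("a", "b"), c("m1", "m2", "m3"))))
#' maxDistanceMatrix(m)["a", "b"]  # 4
#' @export
maxDistanceMatrix <- function(x) {
  stopifnot(is(x, "ScoreMatrix"))
  sc <- scores(x)
  n <- nrow(sc)
  D <- matrix(0, n, n, dimnames = list(rownames(sc), rownames(sc)))
  overlap <- matrix(0L, n, n)
  for (k in seq_len(ncol(sc))) {
    v <- sc[, k]
    ok <- !is.na(v)
    d <- abs(outer(v, v, "-"))
    d[!ok, ] <- NA; d[, !ok] <- NA
    D <- pmax(D, d, na.rm = TRUE)
    overlap <- overlap + outer(ok, ok, "&")
  }
  D[overlap == 0L] <- NA
  diag(D) <- 0
  D
}

#' Classify an assumed duplicate pair by its dosage profiles
#'
#' Applies the pair-exclusion rule first: a marker counts as missing for the
#' pair when it is unscored in either member, and a pair with more than
#' \code{maxMissing} missing markers is inconclusive regardless of its
#' differences. Otherwise differences are counted over the mutually scored
#' markers and the pair is categorized as \code{identical} (0 differences),
#' \code{diff_1_3} (1-3) or \code{diff_gt3} (> 3).
#'
#' @param profileA,profileB integer dosage vectors over the same marker
#'   panel (NA = unscored). If named, they are matched by name.
#' @param maxMissing maximum tolerated pair-missing markers (default 4;
#'   "more than four" unscored markers makes the pair inconclusive).
#' @return one-row data.frame: \code{n_compared, n_missing_markers,
#'   n_differences, category}.
#' @examples
#' classifyPair(c(0, 1, 2), c(0, 1, 2))$category       # identical
#' classifyPair(c(0, 1, 2), c(0, 3, 2))$category       # diff_1_3
#' @export
classifyPair <- function(profileA, profileB, maxMissing = 4L) {
  if (!is.null(names(profileA)) && !is.null(names(profileB))) {
    if (!setequal(names(profileA), names(profileB)))
      .usageError("profiles must be indexed by the same panel")
    profileB <- profileB[names(profileA)]
  }
  if (length(profileA) != length(profileB))
    .usageError("profiles must cover the same panel")
  missing <- is.na(profileA) | is.na(profileB)
  nMissing <- sum(missing)
  nDiff <- sum(profileA[!missing] != profileB[!missing])
  category <- if (nMissing > maxMissing) "inconclusive"
    else if (nDiff == 0L) "identical"
    else if (nDiff <= 3L) "diff_1_3"
    else "diff_gt3"
  data.frame(n_compared = sum(!missing), n_missing_markers = nMissing,
             n_differences = if (nMissing > maxMissing) NA_integer_
                             else as.integer(nDiff),
             category = category, stringsAsFactors = FALSE)
}

#' Classify a set of assumed duplicate pairs
#'
#' Convenience wrapper applying \code{\link{classifyPair}} to each row of a
#' pair table against a score matrix.
#'
#' @param x a \code{\link{ScoreMatrix}}.
#' @param pairs data.frame with columns \code{accession_a, accession_b}.
#' @param maxMissing see \code{\link{classifyPair}}.
#' @return data.frame with the pair ids and the verdict columns.
#' @export
classifyPairs <- function(x, pairs, maxMissing = 4L) {
  sc <- scores(x)
  absent <- setdiff(c(pairs$accession_a, pairs$accession_b), rownames(sc))
  if (length(absent))
    .usageError("accession(s) not in matrix: %s",
                paste(absent, collapse = ", "))
  verdicts <- lapply(seq_len(nrow(pairs)), function(i) {
    classifyPair(sc[pairs$accession_a[i], ], sc[pairs$accession_b[i], ],
                 maxMissing)
  })
  cbind(pairs, do.call(rbind, verdicts))
}

#' Cluster accessions with identical dosage profiles
#'
#' Over a complete (no missing cell) score matrix — typically restricted to
#' the \code{\link{robustSubset}} — groups accessions sharing an exact
#' profile. Groups of size >= 2 are reported as clusters; the rest are
#' unique.
#'
#' @param x a complete \code{\link{ScoreMatrix}}.
#' @return list with \code{clusters} (list of lists with \code{members} and
#'   \code{profile}) and \code{unique} (character vector of accessions with
#'   a unique profile).
#' @export
findIdenticalClusters <- function(x) {
  stopifnot(is(x, "ScoreMatrix"))
  sc <- scores(x)
  if (anyNA(sc))
    .validationError("matrix must be complete (no missing calls)")
  key <- apply(sc, 1L, paste, collapse = ",")
  groups <- split(rownames(sc), key)
  big <- groups[lengths(groups) >= 2L]
  clusters <- lapply(names(big), function(k) {
    list(members = big[[k]],
         profile = as.integer(strsplit(k, ",", fixed = TRUE)[[1]]))
  })
  list(clusters = clusters[order(-vapply(clusters,
                                         function(cl) length(cl$members),
                                         integer(1)))],
       unique = unlist(groups[lengths(groups) == 1L], use.names = FALSE))
}

#' Minimum number of markers to distinguish a collection
#'
#' Smallest m with \code{nClasses^m >= nGenotypes}: with 5 possible dosage
#' configurations per biallelic marker in a tetraploid, 4,187 genotypes need
#' 6 markers under ideal assumptions.
#'
#' @param nGenotypes number of genotypes to distinguish (>= 1).
#' @param nClasses dosage configurations per marker (default 5).
#' @return integer marker count.
#' @examples
#' minMarkersRequired(4187)  # 6
#' @export
minMarkersRequired <- function(nGenotypes, nClasses = 5L) {
  if (nGenotypes < 1L) .usageError("nGenotypes must be >= 1")
  if (nClasses < 2L) .usageError("nClasses must be >= 2")
  m <- 0L
  cap <- 1
  while (cap < nGenotypes) {
    m <- m + 1L
    cap <- cap * nClasses
  }
  m
}

#' Theoretical discrimination capacity of a marker panel
#'
#' \code{nClasses^nMarkers} distinct profiles, computed exactly (integer-
#' valued double; exact up to 2^53, far beyond the 5^18 of an 18-marker
#' tetraploid panel).
#'
#' @param nMarkers number of markers (>= 0).
#' @param nClasses dosage configurations per marker (default 5).
#' @return numeric (integer-valued) capacity.
#' @examples
#' theoreticalCapacity(6)   # 15625
#' @export
theoreticalCapacity <- function(nMarkers, nClasses = 5L) {
  if (nMarkers < 0L) .usageError("nMarkers must be >= 0")
  prod(rep(as.numeric(nClasses), nMarkers))
}

#' Count distinct dosage profiles over a marker subset
#'
#' The panel's realized discriminatory power: the number of distinct profile
#' tuples the accessions show over the chosen markers.
#'
#' @param x a \code{\link{ScoreMatrix}}.
#' @param markerSubset character vector of marker ids (non-empty); the
#'   restricted matrix must be complete.
#' @return integer count of distinct profiles.
#' @export
countDistinguishableProfiles <- function(x,
                                         markerSubset = colnames(scores(x))) {
  stopifnot(is(x, "ScoreMatrix"))
  if (!length(markerSubset)) .usageError("marker subset must be non-empty")
  absent <- setdiff(markerSubset, colnames(scores(x)))
  if (length(absent))
    .usageError("marker(s) not in matrix: %s", paste(absent, collapse = ", "))
  sub <- scores(x)[, markerSubset, drop = FALSE]
  if (anyNA(sub))
    .validationError("restricted matrix must be complete")
  length(unique(apply(sub, 1L, paste, collapse = ",")))
}
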