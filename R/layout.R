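# Dual plate-layout robustness: dosages are called once with the whole
# analysis plate as the modelling unit ("original" layout) and once within
# the 95-genotype source-plate groups ("single" layout); the two score
# matrices are compared marker by marker, combined to raise the call rate,
# and markers whose scores disagree too often are dropped from the panel.

#' Split analysis-plate records back into source-plate groups
#'
#' Partitions the signal records of one analysis plate by their source DNA
#' plate (the 95-genotype groups in which samples were originally arranged).
#' Negative controls stay with their source plate. The groups are disjoint
#' and jointly cover all records.
#'
#' @param records signal-record \code{data.frame}.
#' @return named list of record \code{data.frame}s, one per source plate.
#' @export
splitBySourcePlate <- function(records) {
  sp <- records$source_plate_id
  if (is.null(sp) || any(is.na(sp) | sp == ""))
    .validationError("every record needs a non-empty source_plate_id")
  split(records, records$source_plate_id)
}

.checkSharedIndices <- function(a, b) {
  if (!identical(sort(rownames(scores(a))), sort(rownames(scores(b)))) ||
      !identical(sort(colnames(scores(a))), sort(colnames(scores(b)))))
    .usageError("score matrices must share accession and marker index sets")
}

.alignTo <- function(x, template) {
  sc <- scores(x)[rownames(scores(template)), colnames(scores(template)),
                  drop = FALSE]
  po <- posteriors(x)
  if (length(po))
    po <- po[rownames(scores(template)), colnames(scores(template)),
             drop = FALSE]
  list(scores = sc, posteriors = po)
}

#' Compare dosage calls between two plate layouts
#'
#' For each marker, counts the cells called in both layouts, the fraction of
#' those that disagree, and the breakdown of disagreements by absolute
#' dosage difference (1-4 dosage groups). Call rates per layout and after
#' combination are reported alongside. Markers with no cell called in both
#' layouts get an \code{NA} (undefined) disagreement fraction.
#'
#' @param single,original \code{\link{ScoreMatrix}} objects over the same
#'   accessions and markers.
#' @return data.frame with one row per marker: \code{marker_id},
#'   \code{n_both_called}, \code{n_disagree}, \code{disagreement_fraction},
#'   \code{diff_1}..\code{diff_4}, \code{call_rate_single},
#'   \code{call_rate_original}, \code{call_rate_combined}.
#' @export
compareLayoutCalls <- function(single, original) {
  .checkSharedIndices(single, original)
  al <- .alignTo(original, single)
  s <- scores(single)
  o <- al$scores
  comb <- scores(combineLayoutCalls(single, original)$combined)
  rows <- lapply(colnames(s), function(mk) {
    both <- !is.na(s[, mk]) & !is.na(o[, mk])
    dd <- abs(s[both, mk] - o[both, mk])
    nDis <- sum(dd > 0)
    brk <- tabulate(dd[dd > 0], nbins = 4L)
    data.frame(marker_id = mk, n_both_called = sum(both), n_disagree = nDis,
               disagreement_fraction = if (sum(both)) nDis / sum(both)
                                       else NA_real_,
               diff_1 = brk[1], diff_2 = brk[2], diff_3 = brk[3],
               diff_4 = brk[4],
               call_rate_single = mean(!is.na(s[, mk])),
               call_rate_original = mean(!is.na(o[, mk])),
               call_rate_combined = mean(!is.na(comb[, mk])))
  })
  do.call(rbind, rows)
}

#' Combine dosage calls from two plate layouts
#'
#' Cell-wise combination rule: a cell called in exactly one layout takes
#' that call; called identically in both, the shared call; called
#' differently in both, the call with the higher assigned-class posterior
#' wins (ties and absent posteriors fall back to the single-plate layout)
#' and the cell is recorded in the conflict set; called in neither, missing.
#' A conflicted cell counts as called, so the combined call rate is >= each
#' input's rate for every marker.
#'
#' @param single,original \code{\link{ScoreMatrix}} objects over the same
#'   accessions and markers.
#' @return a list with \code{combined} (a \code{ScoreMatrix} tagged
#'   \code{"combined"}) and \code{conflicts}, a data.frame of cells where
#'   the layouts disagreed (\code{accession, marker_id, call_single,
#'   call_original, chosen}).
#' @export
combineLayoutCalls <- function(single, original) {
  .checkSharedIndices(single, original)
  al <- .alignTo(original, single)
  s <- scores(single); o <- al$scores
  ps <- posteriors(single); po <- al$posteriors
  havePost <- length(ps) > 0 && length(po) > 0

  comb <- s
  useO <- is.na(s) & !is.na(o)
  comb[useO] <- o[useO]
  conflict <- which(!is.na(s) & !is.na(o) & s != o)
  chosen <- s[conflict]
  if (length(conflict) && havePost) {
    oWins <- !is.na(po[conflict]) & !is.na(ps[conflict]) &
      po[conflict] > ps[conflict]
    chosen[oWins] <- o[conflict][oWins]
  }
  comb[conflict] <- chosen

  pComb <- matrix(numeric(), 0, 0)
  if (havePost) {
    pComb <- pmax(ifelse(is.na(s), -Inf, ps), ifelse(is.na(o), -Inf, po))
    pComb[is.infinite(pComb)] <- NA_real_
    dimnames(pComb) <- dimnames(s)
  }

  idx <- arrayInd(conflict, dim(s))
  conflicts <- data.frame(
    accession = rownames(s)[idx[, 1]],
    marker_id = colnames(s)[idx[, 2]],
    call_single = s[conflict], call_original = o[conflict],
    chosen = chosen, stringsAsFactors = FALSE
  )
  list(combined = ScoreMatrix(comb, layout = "combined", posteriors = pComb),
       conflicts = conflicts)
}

#' Filter markers by cross-layout disagreement
#'
#' Markers whose disagreement fraction strictly exceeds \code{threshold}
#' are excluded from the panel; a marker at exactly the threshold is
#' retained, as is a marker whose disagreement is undefined (no shared
#' calls).
#'
#' @param comparisons data.frame from \code{\link{compareLayoutCalls}}.
#' @param threshold disagreement-fraction cutoff (default 0.10).
#' @return list with character vectors \code{retained} and \code{excluded}.
#' @export
markerRobustnessFilter <- function(comparisons, threshold = 0.10) {
  if (!nrow(comparisons)) .validationError("no layout comparisons supplied")
  bad <- !is.na(comparisons$disagreement_fraction) &
    comparisons$disagreement_fraction > threshold
  list(retained = comparisons$marker_id[!bad],
       excluded = comparisons$marker_id[bad])
}

#' Accessions robustly called across both layouts
#'
#' Returns the accessions with (a) no missing call in either layout over
#' the panel markers and (b) identical calls in both layouts for every
#' panel marker — the subset on which identical-profile clustering is
#' well defined.
#'
#' @param single,original \code{\link{ScoreMatrix}} objects.
#' @param panel character vector of marker ids (default: all markers).
#' @return character vector of accession ids.
#' @export
robustSubset <- function(single, original,
                         panel = colnames(scores(single))) {
  .checkSharedIndices(single, original)
  missing <- setdiff(panel, colnames(scores(single)))
  if (length(missing))
    .usageError("panel marker(s) not in matrices: %s",
                paste(missing, collapse = ", "))
  al <- .alignTo(original, single)
  s <- scores(single)[, panel, drop = FALSE]
  o <- al$scores[, panel, drop = FALSE]
  ok <- rowSums(is.na(s) | is.na(o)) == 0 & rowSums(s != o, na.rm = TRUE) == 0
  rownames(s)[ok]
}
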