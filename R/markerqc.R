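# Marker-level quality statistics: dosage-class proportions, Shannon-Wiener
# evenness, the three chip-style selection criteria, and chromosome coverage
# of the panel.

#' Shannon-Wiener evenness of dosage-class proportions
#'
#' Computes the Shannon-Wiener index H = -sum(p_i ln p_i) (with
#' 0 ln 0 := 0) over the dosage-class proportions of one marker and the
#' normalized evenness I = H / ln(S), where S is the number of dosage
#' classes (5 for a tetraploid: dosages 0-4). I is 1 when all classes are
#' equally occupied and 0 when a single class holds everything.
#'
#' @param proportions non-negative numeric vector of class proportions
#'   summing to 1 (length S >= 2).
#' @return an \code{\link{EvennessResult}}.
#' @examples
#' evenness(computeEvenness(c(0.03, 0.13, 0.16, 0.09, 0.59)))  # ~0.740
#' evenness(computeEvenness(rep(0.2, 5)))                      # 1
#' @export
computeEvenness <- function(proportions) {
  if (length(proportions) < 2L)
    .validationError("need at least two dosage classes")
  if (any(proportions < 0))
    .validationError("proportions must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-6)
    .validationError("proportions must sum to 1 (got %.6f)",
                     sum(proportions))
  p <- proportions
  H <- -sum(ifelse(p > 0, p * log(p), 0))
  new("EvennessResult", p = p, S = length(p), H = H, I = H / log(length(p)))
}

#' Dosage-class proportions of one marker's calls
#'
#' Proportions of called (non-missing) samples in each dosage class 0..
#' \code{nClasses - 1}. Missing calls are excluded from the denominator.
#'
#' @param dosages integer vector of dosages (NA = missing), controls already
#'   excluded.
#' @param nClasses number of dosage classes (default 5).
#' @return numeric vector of \code{nClasses} proportions summing to 1.
#' @examples
#' dosageProportions(c(0, 0, 1, 2, 4))
#' @export
dosageProportions <- function(dosages, nClasses = 5L) {
  d <- dosages[!is.na(dosages)]
  if (!length(d))
    .validationError("no called samples: proportions undefined")
  if (any(d < 0 | d >= nClasses))
    .validationError("dosages must lie in 0..%d", nClasses - 1L)
  tabulate(d + 1L, nbins = nClasses) / length(d)
}

#' Chip-style marker selection filter
#'
#' Applies the three selection criteria used to pick markers from array
#' posterior data: (1) every dosage cluster (by each sample's
#' maximum-posterior class) holds at least \code{minClassProportion} of the
#' samples; (2) at least \code{minAssignedFraction} of samples are assigned
#' with posterior >= \code{assignmentProbability}; (3) the mean per-sample
#' maximum posterior is at least \code{meanMaxPosterior}. A marker passes
#' only if all three hold.
#'
#' @param posteriorTable numeric matrix, samples x dosage classes, rows
#'   summing to 1.
#' @param minClassProportion,assignmentProbability,minAssignedFraction,
#'   meanMaxPosterior the criterion constants (defaults 0.10, 0.99, 0.90,
#'   0.99).
#' @return a list with \code{pass} (logical) and \code{criteria}, a
#'   data.frame of per-criterion observed value, threshold and pass flag.
#' @export
chipFilter <- function(posteriorTable, minClassProportion = 0.10,
                       assignmentProbability = 0.99,
                       minAssignedFraction = 0.90,
                       meanMaxPosterior = 0.99) {
  if (is.null(dim(posteriorTable)) || nrow(posteriorTable) == 0L)
    .validationError("posterior table is empty")
  if (any(abs(rowSums(posteriorTable) - 1) > 1e-6))
    .validationError("posterior rows must sum to 1")
  maxp <- apply(posteriorTable, 1L, max)
  cls <- apply(posteriorTable, 1L, which.max)
  occ <- tabulate(cls, nbins = ncol(posteriorTable)) / nrow(posteriorTable)
  observed <- c(min(occ), mean(maxp >= assignmentProbability), mean(maxp))
  threshold <- c(minClassProportion, minAssignedFraction, meanMaxPosterior)
  criteria <- data.frame(
    criterion = c("min_class_proportion", "assigned_fraction",
                  "mean_max_posterior"),
    observed = observed, threshold = threshold,
    pass = observed >= threshold
  )
  list(pass = all(criteria$pass), criteria = criteria)
}

#' Check chromosome coverage of a marker panel
#'
#' A panel passes when every chromosome 1..\code{nChromosomes} carries at
#' least \code{minPerChromosome} markers.
#'
#' @param panel data.frame with columns \code{marker_id} and
#'   \code{chromosome} (integers in 1..\code{nChromosomes}).
#' @param nChromosomes number of chromosomes (default 7).
#' @param minPerChromosome minimum markers per chromosome (default 2).
#' @return a list with \code{pass}, per-chromosome \code{counts}, and the
#'   \code{failing} chromosome numbers.
#' @export
checkChromosomeCoverage <- function(panel, nChromosomes = 7L,
                                    minPerChromosome = 2L) {
  if (nrow(panel)) {
    .stopifnotCols(panel, c("marker_id", "chromosome"), "panel definition")
    if (any(!panel$chromosome %in% seq_len(nChromosomes)))
      .validationError("chromosomes must lie in 1..%d", nChromosomes)
  }
  counts <- tabulate(if (nrow(panel)) panel$chromosome else integer(),
                     nbins = nChromosomes)
  names(counts) <- seq_len(nChromosomes)
  failing <- which(counts < minPerChromosome)
  list(pass = length(failing) == 0L, counts = counts,
       failing = as.integer(failing))
}

#' Per-marker QC report over a score matrix
#'
#' Combines call rate, dosage-class proportions and evenness into one table,
#' one row per marker (proportions over called samples only).
#'
#' @param x a \code{\link{ScoreMatrix}}.
#' @param nClasses number of dosage classes (default 5).
#' @return data.frame with columns \code{marker_id}, \code{call_rate},
#'   \code{P0}..\code{P4} and \code{evenness}.
#' @export
markerQCReport <- function(x, nClasses = 5L) {
  stopifnot(is(x, "ScoreMatrix"))
  sc <- scores(x)
  rows <- lapply(colnames(sc), function(mk) {
    d <- sc[, mk]
    p <- dosageProportions(d, nClasses)
    cbind(data.frame(marker_id = mk, call_rate = mean(!is.na(d))),
          as.data.frame(as.list(setNames(round(p, 2),
                                         paste0("P", seq_len(nClasses) - 1)))),
          data.frame(evenness = round(evenness(computeEvenness(p)), 3)))
  })
  do.call(rbind, rows)
}
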