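#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet width
#' @importFrom stats dnorm mad quantile rbinom rgamma rlnorm rmultinom rnorm runif setNames
#' @importFrom utils read.csv read.delim write.csv write.table
NULL

## ---------------------------------------------------------------------------
## Generics
## ---------------------------------------------------------------------------

#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @export
setGeneric("layoutTag", function(x) standardGeneric("layoutTag"))
#' @export
setGeneric("posteriors", function(x) standardGeneric("posteriors"))
#' @export
setGeneric("markerId", function(x) standardGeneric("markerId"))
#' @export
setGeneric("unitId", function(x) standardGeneric("unitId"))
#' @export
setGeneric("haplotypeSequences", function(x) standardGeneric("haplotypeSequences"))
#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))
#' @export
setGeneric("evenness", function(x) standardGeneric("evenness"))
#' @export
setGeneric("shannonIndex", function(x) standardGeneric("shannonIndex"))
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))
#' @export
setGeneric("duplicatePairs", function(x) standardGeneric("duplicatePairs"))
#' @export
setGeneric("mislabelPairs", function(x) standardGeneric("mislabelPairs"))

## ---------------------------------------------------------------------------
## CallerConfig
## ---------------------------------------------------------------------------

#' Configuration for the allele-dosage caller
#'
#' Holds the tuning parameters of the mixture-model dosage caller. The
#' defaults reproduce the calling contract used for tetraploid material:
#' five dosage classes (0-4) and a posterior-probability threshold of 0.95
#' below which a sample is left uncalled. \code{dipFilter} is accepted for
#' interface completeness but is a no-op: the pipeline runs with it disabled.
#'
#' @slot ploidy integer; ploidy of the material (default 4).
#' @slot nClasses integer; number of dosage classes, always \code{ploidy + 1}.
#' @slot posteriorThreshold numeric in (0.5, 1); minimum posterior class
#'   probability required to assign a dosage.
#' @slot dipFilter logical; accepted but inert (no unimodality pre-filter).
#' @slot maxIterations integer; EM iteration cap.
#' @slot convergenceTol numeric; relative log-likelihood change declaring
#'   convergence.
#' @slot seed integer; retained for interface stability (the fit itself is
#'   deterministic through its quantile initialisation).
#' @export
setClass("CallerConfig",
  slots = c(
    ploidy = "integer", nClasses = "integer",
    posteriorThreshold = "numeric", dipFilter = "logical",
    maxIterations = "integer", convergenceTol = "numeric", seed = "integer"
  )
)

setValidity("CallerConfig", function(object) {
  msg <- character()
  if (object@ploidy < 1L) msg <- c(msg, "ploidy must be >= 1")
  if (object@nClasses != object@ploidy + 1L)
    msg <- c(msg, "nClasses must equal ploidy + 1")
  if (object@posteriorThreshold <= 0.5 || object@posteriorThreshold >= 1)
    msg <- c(msg, "posteriorThreshold must lie in (0.5, 1)")
  if (object@maxIterations < 1L) msg <- c(msg, "maxIterations must be >= 1")
  if (object@convergenceTol <= 0) msg <- c(msg, "convergenceTol must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param ploidy,posteriorThreshold,dipFilter,maxIterations,convergenceTol,seed
#'   see slot documentation.
#' @return \code{CallerConfig} returns a validated \code{CallerConfig} object.
#' @rdname CallerConfig-class
#' @examples
#' CallerConfig()
#' CallerConfig(posteriorThreshold = 0.99)
#' @export
CallerConfig <- function(ploidy = 4L, posteriorThreshold = 0.95,
                         dipFilter = FALSE, maxIterations = 500L,
                         convergenceTol = 1e-8, seed = 1L) {
  new("CallerConfig",
      ploidy = as.integer(ploidy), nClasses = as.integer(ploidy) + 1L,
      posteriorThreshold = posteriorThreshold, dipFilter = dipFilter,
      maxIterations = as.integer(maxIterations),
      convergenceTol = convergenceTol, seed = as.integer(seed))
}

setMethod("show", "CallerConfig", function(object) {
  cat("CallerConfig: ploidy", object@ploidy,
      "(", object@nClasses, "dosage classes ),",
      "posterior threshold", object@posteriorThreshold, "\n")
})

## ---------------------------------------------------------------------------
## DosageMixtureFit
## ---------------------------------------------------------------------------

#' Fitted dosage mixture for one marker in one analysis unit
#'
#' The result of fitting an order-constrained Gaussian mixture with one
#' component per dosage class to the transformed signal ratios of all usable
#' samples of one marker within one analysis unit. Component locations are
#' strictly increasing along the ratio axis, so component k corresponds to
#' dosage k - 1.
#'
#' @slot markerId,unitId character; provenance of the fit.
#' @slot locations numeric; strictly increasing component means on [0, 1].
#' @slot scales numeric; positive component standard deviations.
#' @slot weights numeric; mixing proportions summing to 1.
#' @slot logLik numeric; final log-likelihood.
#' @slot converged logical.
#' @slot nSamples integer; number of samples used in the fit.
#' @export
setClass("DosageMixtureFit",
  slots = c(
    markerId = "character", unitId = "character",
    locations = "numeric", scales = "numeric", weights = "numeric",
    logLik = "numeric", converged = "logical", nSamples = "integer"
  )
)

setValidity("DosageMixtureFit", function(object) {
  msg <- character()
  k <- length(object@locations)
  if (length(object@scales) != k || length(object@weights) != k)
    msg <- c(msg, "locations, scales and weights must have equal length")
  if (any(diff(object@locations) <= 0))
    msg <- c(msg, "locations must be strictly increasing")
  if (any(object@scales <= 0)) msg <- c(msg, "scales must be positive")
  if (abs(sum(object@weights) - 1) > 1e-9)
    msg <- c(msg, "weights must sum to 1")
  if (length(msg)) msg else TRUE
})

#' @rdname DosageMixtureFit-class
#' @param x a \code{DosageMixtureFit}.
#' @export
setMethod("markerId", "DosageMixtureFit", function(x) x@markerId)
#' @rdname DosageMixtureFit-class
#' @export
setMethod("unitId", "DosageMixtureFit", function(x) x@unitId)

setMethod("show", "DosageMixtureFit", function(object) {
  cat("DosageMixtureFit for marker", object@markerId,
      "in unit", object@unitId, "\n")
  cat("  n =", object@nSamples, ifelse(object@converged,
      "(converged)", "(NOT converged)"), "\n")
  cat("  locations:", paste(signif(object@locations, 3), collapse = " "), "\n")
  cat("  weights:  ", paste(signif(object@weights, 3), collapse = " "), "\n")
})

## ---------------------------------------------------------------------------
## ScoreMatrix
## ---------------------------------------------------------------------------

#' Accessions-by-markers allele dosage matrix
#'
#' Container for called allele dosages: an integer matrix with one row per
#' accession and one column per marker, cells in 0..ploidy or \code{NA} for
#' uncalled, tagged with the plate-layout scheme (\code{layout}) that produced
#' the calls. Optionally carries the matrix of assigned-class posterior
#' probabilities, which the layout-combination step uses to resolve
#' conflicting calls.
#'
#' @slot scores integer matrix, values 0..4 or NA, with dimnames.
#' @slot layout character(1); analysis-unit scheme tag (e.g. "original",
#'   "single", "combined").
#' @slot posteriors numeric matrix of the same shape as \code{scores}, or a
#'   0 x 0 matrix when posteriors are not tracked.
#' @export
setClass("ScoreMatrix",
  slots = c(scores = "matrix", layout = "character", posteriors = "matrix")
)

setValidity("ScoreMatrix", function(object) {
  msg <- character()
  s <- object@scores
  if (nrow(s) > 0 && is.null(rownames(s)))
    msg <- c(msg, "scores must have accession rownames")
  if (ncol(s) > 0 && is.null(colnames(s)))
    msg <- c(msg, "scores must have marker colnames")
  v <- s[!is.na(s)]
  if (length(v) && (any(v != round(v)) || any(v < 0) || any(v > 4)))
    msg <- c(msg, "scores must be integers in 0..4 or NA")
  if (length(object@layout) != 1L)
    msg <- c(msg, "layout must be a single string")
  p <- object@posteriors
  if (!(nrow(p) == 0 && ncol(p) == 0) && !identical(dim(p), dim(s)))
    msg <- c(msg, "posteriors must be empty or match the scores' shape")
  if (length(msg)) msg else TRUE
})

#' @param scores,layout,posteriors see slot documentation.
#' @return \code{ScoreMatrix} returns a validated \code{ScoreMatrix}.
#' @rdname ScoreMatrix-class
#' @examples
#' m <- matrix(c(0L, 4L, 2L, NA), 2, 2,
#'             dimnames = list(c("a1", "a2"), c("mk1", "mk2")))
#' ScoreMatrix(m, layout = "single")
#' @export
ScoreMatrix <- function(scores, layout = "unspecified",
                        posteriors = matrix(numeric(), 0, 0)) {
  storage.mode(scores) <- "integer"
  new("ScoreMatrix", scores = scores, layout = layout, posteriors = posteriors)
}

#' @rdname ScoreMatrix-class
#' @param x a \code{ScoreMatrix}.
#' @export
setMethod("scores", "ScoreMatrix", function(x) x@scores)
#' @rdname ScoreMatrix-class
#' @export
setMethod("layoutTag", "ScoreMatrix", function(x) x@layout)
#' @rdname ScoreMatrix-class
#' @export
setMethod("posteriors", "ScoreMatrix", function(x) x@posteriors)
#' @rdname ScoreMatrix-class
#' @export
setMethod("dim", "ScoreMatrix", function(x) dim(x@scores))

setMethod("show", "ScoreMatrix", function(object) {
  cat("ScoreMatrix:", nrow(object@scores), "accessions x",
      ncol(object@scores), "markers, layout =", object@layout, "\n")
  n <- length(object@scores)
  if (n > 0)
    cat("  missing:", sum(is.na(object@scores)), "of", n, "cells\n")
})

## ---------------------------------------------------------------------------
## EvennessResult
## ---------------------------------------------------------------------------

#' Shannon-Wiener evenness of dosage-class proportions
#'
#' Holds the class proportions p_i, the number of dosage classes S, the
#' Shannon-Wiener index H (in nats) and the normalized evenness
#' I = H / ln(S) in [0, 1], where 1 means all dosage classes are equally
#' occupied.
#'
#' @slot p numeric; class proportions summing to 1.
#' @slot S integer; number of dosage classes (5 for tetraploids).
#' @slot H numeric; Shannon-Wiener index, nats.
#' @slot I numeric; evenness in [0, 1].
#' @export
setClass("EvennessResult",
  slots = c(p = "numeric", S = "integer", H = "numeric", I = "numeric")
)

setValidity("EvennessResult", function(object) {
  msg <- character()
  if (abs(sum(object@p) - 1) > 1e-6) msg <- c(msg, "p must sum to 1")
  if (object@I < -1e-12 || object@I > 1 + 1e-12)
    msg <- c(msg, "evenness must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname EvennessResult-class
#' @param x an \code{EvennessResult}.
#' @export
setMethod("evenness", "EvennessResult", function(x) x@I)
#' @rdname EvennessResult-class
#' @export
setMethod("shannonIndex", "EvennessResult", function(x) x@H)

setMethod("show", "EvennessResult", function(object) {
  cat("EvennessResult: S =", object@S,
      "classes, H =", round(object@H, 4),
      "nats, evenness I =", round(object@I, 3), "\n")
})

## ---------------------------------------------------------------------------
## HaplotypeTable
## ---------------------------------------------------------------------------

#' Amplicon haplotype read counts with aligned sequences
#'
#' Per-genotype read counts over the gap-aligned haplotypes of one amplicon
#' marker. Sequences are stored as a \code{DNAStringSet} of equal aligned
#' width (gaps as "-"); the count matrix has one row per genotype and one
#' column per haplotype, with column names matching the sequence names.
#'
#' @slot markerId character(1).
#' @slot sequences \code{DNAStringSet}; gap-aligned haplotype sequences.
#' @slot counts integer matrix, genotypes x haplotypes, non-negative.
#' @slot ampliconLength integer; ungapped reference amplicon length in bp.
#' @export
setClass("HaplotypeTable",
  slots = c(markerId = "character", sequences = "DNAStringSet",
            counts = "matrix", ampliconLength = "integer")
)

setValidity("HaplotypeTable", function(object) {
  msg <- character()
  w <- Biostrings::width(object@sequences)
  if (length(w) && length(unique(w)) != 1L)
    msg <- c(msg, "aligned sequences must all have equal length")
  if (!identical(as.character(colnames(object@counts)),
                 as.character(names(object@sequences))))
    msg <- c(msg, "count columns must match sequence names (same order)")
  if (nrow(object@counts) > 0 && is.null(rownames(object@counts)))
    msg <- c(msg, "counts must have genotype rownames")
  v <- object@counts
  if (length(v) && (any(v < 0) || any(v != round(v))))
    msg <- c(msg, "read counts must be non-negative integers")
  if (length(msg)) msg else TRUE
})

#' @param markerId,sequences,counts,ampliconLength see slot documentation.
#' @return \code{HaplotypeTable} returns a validated \code{HaplotypeTable}.
#' @rdname HaplotypeTable-class
#' @export
HaplotypeTable <- function(markerId, sequences, counts,
                           ampliconLength = NA_integer_) {
  storage.mode(counts) <- "integer"
  if (is.na(ampliconLength) && length(sequences))
    ampliconLength <- max(nchar(gsub("-", "", as.character(sequences))))
  new("HaplotypeTable", markerId = markerId, sequences = sequences,
      counts = counts, ampliconLength = as.integer(ampliconLength))
}

#' @rdname HaplotypeTable-class
#' @param x a \code{HaplotypeTable}.
#' @export
setMethod("markerId", "HaplotypeTable", function(x) x@markerId)
#' @rdname HaplotypeTable-class
#' @export
setMethod("haplotypeSequences", "HaplotypeTable", function(x) x@sequences)
#' @rdname HaplotypeTable-class
#' @export
setMethod("readCounts", "HaplotypeTable", function(x) x@counts)

setMethod("show", "HaplotypeTable", function(object) {
  cat("HaplotypeTable for marker", object@markerId, "\n")
  cat(" ", nrow(object@counts), "genotypes x", ncol(object@counts),
      "haplotypes, aligned width",
      if (length(object@sequences)) Biostrings::width(object@sequences)[1]
      else 0, "\n")
})

## ---------------------------------------------------------------------------
## SimulationTruth
## ---------------------------------------------------------------------------

#' Ground truth of a simulated fingerprinting panel
#'
#' The complete generating state of one synthetic study: accession and marker
#' identities, per-marker dosage-class frequencies, the true dosage matrix,
#' injected duplicate pairs and mislabel swaps, and the fluorescence cluster
#' model (per-dosage mean ratio locations, a common scale, and a dropout
#' probability).
#'
#' @slot seed integer; master seed all substreams derive from.
#' @slot accessions character; accession ids.
#' @slot markers data.frame with columns \code{marker_id}, \code{chromosome}.
#' @slot frequencies numeric matrix, markers x dosage classes, rows sum to 1.
#' @slot dosages integer matrix, accessions x markers, values 0..4.
#' @slot duplicates data.frame with columns \code{accession_a},
#'   \code{accession_b}: injected duplicate pairs (b copies a's profile).
#' @slot mislabels data.frame with columns \code{accession_a},
#'   \code{accession_b}: ids whose underlying dosage profiles were swapped.
#' @slot clusterLocations numeric; strictly increasing per-dosage mean
#'   transformed ratios on [0, 1].
#' @slot clusterScale numeric; common cluster standard deviation.
#' @slot dropoutRate numeric in [0, 1]; per-well missing-signal probability.
#' @export
setClass("SimulationTruth",
  slots = c(seed = "integer", accessions = "character", markers = "data.frame",
            frequencies = "matrix", dosages = "matrix",
            duplicates = "data.frame", mislabels = "data.frame",
            clusterLocations = "numeric", clusterScale = "numeric",
            dropoutRate = "numeric")
)

setValidity("SimulationTruth", function(object) {
  msg <- character()
  if (any(diff(object@clusterLocations) <= 0))
    msg <- c(msg, "clusterLocations must be strictly increasing")
  if (nrow(object@frequencies) &&
      any(abs(rowSums(object@frequencies) - 1) > 1e-6))
    msg <- c(msg, "per-marker frequency vectors must sum to 1")
  if (object@dropoutRate < 0 || object@dropoutRate > 1)
    msg <- c(msg, "dropoutRate must lie in [0, 1]")
  if (!identical(dim(object@dosages),
                 c(length(object@accessions), nrow(object@markers))))
    msg <- c(msg, "dosage matrix shape must match accessions x markers")
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationTruth-class
#' @param x a \code{SimulationTruth}.
#' @export
setMethod("dosageMatrix", "SimulationTruth", function(x) x@dosages)
#' @rdname SimulationTruth-class
#' @export
setMethod("duplicatePairs", "SimulationTruth", function(x) x@duplicates)
#' @rdname SimulationTruth-class
#' @export
setMethod("mislabelPairs", "SimulationTruth", function(x) x@mislabels)

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth:", length(object@accessions), "accessions x",
      nrow(object@markers), "markers (seed", object@seed, ")\n")
  cat("  cluster scale", object@clusterScale,
      ", dropout", object@dropoutRate, "\n")
  cat("  injected:", nrow(object@duplicates), "duplicate pair(s),",
      nrow(object@mislabels), "mislabel swap(s)\n")
})
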