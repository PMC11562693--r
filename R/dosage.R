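# Allele-dosage calling: an order-constrained Gaussian mixture on the
# transformed two-channel signal ratio, one component per dosage class.
# This is the role a tetraploid genotype caller plays in a plate-based
# fingerprinting pipeline: samples of one marker within one
# analysis unit are modelled together, and a sample receives the dosage of
# its maximum-posterior component only when that posterior clears the
# configured threshold.

.SCALE_FLOOR <- 1e-4
.WEIGHT_FLOOR <- 1e-6

#' Transform two-channel fluorescence into an allele-B signal fraction
#'
#' Maps allele-specific fluorescence (a, b) to b / (a + b) in [0, 1], the
#' axis on which dosage clusters are modelled: 0 means pure allele A
#' (dosage 0), 1 pure allele B (dosage 4 in a tetraploid). Wells with zero
#' total signal are unprocessable and yield \code{NA} rather than an error,
#' so they propagate to a missing call.
#'
#' @param signalA,signalB non-negative numeric vectors.
#' @return numeric vector of ratios in [0, 1], \code{NA} where both signals
#'   are zero.
#' @examples
#' transformSignal(c(1000, 0, 500), c(0, 1000, 500))
#' @export
transformSignal <- function(signalA, signalB) {
  if (any(signalA < 0, na.rm = TRUE) || any(signalB < 0, na.rm = TRUE))
    .validationError("signals must be non-negative")
  tot <- signalA + signalB
  ifelse(tot > 0, signalB / tot, NA_real_)
}

#' Fit the dosage mixture for one marker in one analysis unit
#'
#' Fits an EM Gaussian mixture with \code{nClasses} components to the
#' transformed signal ratios of all usable (non-control, positive-signal)
#' records. Component locations are kept in increasing order by relabeling
#' after each M-step, so component k always represents dosage k - 1.
#' Initialisation is deterministic: locations at the canonical evenly
#' spaced anchor positions (2d + 1) / (2 nClasses) on the ratio axis
#' (0.1, 0.3, 0.5, 0.7, 0.9 for tetraploids), uniform weights, and a pooled
#' MAD for every scale. A weak anchor prior (\code{anchorStrength} pseudo-
#' observations per component) pulls each location toward its anchor in the
#' M-step: with tens of samples in a class the data dominate entirely,
#' while a dosage class that is empty in the unit keeps its slot at the
#' anchor with its weight floored instead of invading a neighbouring
#' cluster — the behaviour that keeps calls consistent between small
#' (95-sample) and large (380-sample) analysis units. Scales are floored
#' at 1e-4 and weights at 1e-6 (then renormalized).
#'
#' @param records signal-record \code{data.frame} for a single marker and
#'   analysis unit (see \code{\link{readFluorescence}}).
#' @param config a \code{\link{CallerConfig}}.
#' @param anchorStrength weight (in pseudo-observations) of the anchor
#'   prior on component locations (default 2).
#' @return a \code{\link{DosageMixtureFit}}.
#' @examples
#' tr <- generateTruthPanel(nAccessions = 190, nMarkers = 1, seed = 7)
#' rec <- simulateFluorescence(tr)
#' fit <- fitDosageMixture(rec[rec$marker_id == "MK01", ], CallerConfig())
#' fit
#' @export
fitDosageMixture <- function(records, config = CallerConfig(),
                             anchorStrength = 2) {
  stopifnot(is(config, "CallerConfig"))
  if (length(unique(records$marker_id)) != 1L)
    .usageError("records must belong to a single marker")
  usable <- !records$is_negative_control &
    (records$signal_a + records$signal_b) > 0
  r <- transformSignal(records$signal_a[usable], records$signal_b[usable])
  k <- config@nClasses
  if (length(r) < k)
    .fitError("only %d usable record(s) for %d dosage classes",
              length(r), k)

  anchors <- (2 * seq_len(k) - 1) / (2 * k)  # 0.1, 0.3, ... for k = 5
  mu <- anchors
  sg <- rep(max(mad(r), .SCALE_FLOOR), k)
  w <- rep(1 / k, k)

  ll <- -Inf
  converged <- FALSE
  for (it in seq_len(config@maxIterations)) {
    logd <- vapply(seq_len(k),
                   function(j) dnorm(r, mu[j], sg[j], log = TRUE) + log(w[j]),
                   numeric(length(r)))
    m <- apply(logd, 1L, max)
    lse <- m + log(rowSums(exp(logd - m)))
    resp <- exp(logd - lse)
    newll <- sum(lse)

    nk <- colSums(resp)
    w <- pmax(nk / length(r), .WEIGHT_FLOOR)
    w <- w / sum(w)
    mu <- (colSums(resp * r) + anchorStrength * anchors) /
      (nk + anchorStrength)
    sg <- sqrt(colSums(resp * (outer(r, mu, "-")^2)) / pmax(nk, 1e-12))
    sg <- pmax(sg, .SCALE_FLOOR)

    ord <- order(mu)                          # keep dosage order
    mu <- mu[ord]; sg <- sg[ord]; w <- w[ord]
    if (any(diff(mu) <= 0))                   # degenerate coincident means
      mu <- mu + seq(0, k - 1) * 1e-12

    if (is.finite(ll) && abs(newll - ll) < config@convergenceTol *
        (abs(ll) + 1e-3)) {
      converged <- TRUE
      ll <- newll
      break
    }
    ll <- newll
  }

  new("DosageMixtureFit",
      markerId = records$marker_id[1],
      unitId = if (!is.null(records$unit_id)) records$unit_id[1]
               else records$analysis_plate_id[1],
      locations = mu, scales = sg, weights = w,
      logLik = ll, converged = converged, nSamples = length(r))
}

#' Posterior dosage-class probabilities under a fitted mixture
#'
#' Bayes rule on the fitted mixture: for each ratio, component weights times
#' normal densities, normalized to sum to 1 across the dosage classes.
#'
#' @param fit a \code{\link{DosageMixtureFit}}.
#' @param ratios numeric vector of transformed signal ratios.
#' @return numeric matrix, \code{length(ratios)} rows by \code{nClasses}
#'   columns; each row sums to 1. Rows for \code{NA} ratios are \code{NA}.
#' @export
classPosteriors <- function(fit, ratios) {
  stopifnot(is(fit, "DosageMixtureFit"))
  k <- length(fit@locations)
  out <- matrix(NA_real_, length(ratios), k)
  ok <- !is.na(ratios)
  if (any(ok)) {
    logd <- vapply(seq_len(k), function(j) {
      dnorm(ratios[ok], fit@locations[j], fit@scales[j], log = TRUE) +
        log(fit@weights[j])
    }, numeric(sum(ok)))
    logd <- matrix(logd, ncol = k)
    m <- apply(logd, 1L, max)
    out[ok, ] <- exp(logd - (m + log(rowSums(exp(logd - m)))))
  }
  out
}

#' Call allele dosages from a fitted mixture
#'
#' Assigns each record the dosage of its maximum-posterior component when
#' that posterior reaches \code{posteriorThreshold}; otherwise the call is
#' missing and the maximum posterior is still reported. Records with zero
#' total signal are unprocessable (missing call, \code{NA} posterior).
#' Negative controls are carried through flagged so that downstream rates
#' can exclude them.
#'
#' @param fit a \code{\link{DosageMixtureFit}} for the records' marker/unit.
#' @param records signal-record \code{data.frame}.
#' @param config a \code{\link{CallerConfig}}.
#' @return a \code{data.frame} of dosage calls with columns
#'   \code{sample_id, marker_id, unit_id, source_plate_id, well,
#'   is_negative_control, dosage, posterior}.
#' @export
callDosages <- function(fit, records, config = CallerConfig()) {
  stopifnot(is(fit, "DosageMixtureFit"), is(config, "CallerConfig"))
  if (any(records$marker_id != markerId(fit)))
    .usageError("records belong to marker(s) other than the fit's (%s)",
                markerId(fit))
  ratios <- transformSignal(records$signal_a, records$signal_b)
  post <- classPosteriors(fit, ratios)
  maxp <- apply(post, 1L, function(x) if (all(is.na(x))) NA_real_ else max(x))
  cls <- apply(post, 1L, function(x) if (all(is.na(x))) NA_integer_
               else which.max(x) - 1L)
  dosage <- ifelse(!is.na(maxp) & maxp >= config@posteriorThreshold,
                   cls, NA_integer_)
  data.frame(
    sample_id = records$sample_id,
    marker_id = records$marker_id,
    unit_id = unitId(fit),
    source_plate_id = records$source_plate_id,
    well = records$well,
    is_negative_control = records$is_negative_control,
    dosage = as.integer(dosage),
    posterior = maxp,
    stringsAsFactors = FALSE
  )
}

#' Call rate of a collection of dosage calls
#'
#' Fraction of non-control samples that received a dosage.
#'
#' @param calls a dosage-call \code{data.frame} from \code{\link{callDosages}}.
#' @return a fraction in [0, 1].
#' @export
callRate <- function(calls) {
  keep <- !calls$is_negative_control
  if (!any(keep))
    .validationError("no non-control calls: call rate undefined")
  mean(!is.na(calls$dosage[keep]))
}

#' Flag source plates whose missing fraction exceeds a threshold
#'
#' Plates on which strictly more than \code{threshold} of the non-control
#' genotypes could not be scored are flagged for an assay repeat.
#'
#' @param calls dosage-call \code{data.frame} with source-plate provenance.
#' @param threshold missing-fraction threshold (default 0.20, strict
#'   inequality: exactly 20\% missing is not flagged).
#' @return character vector of flagged source plate ids.
#' @export
flagPlatesForRepeat <- function(calls, threshold = 0.20) {
  calls <- calls[!calls$is_negative_control, , drop = FALSE]
  missFrac <- tapply(is.na(calls$dosage), calls$source_plate_id, mean)
  names(missFrac)[missFrac > threshold]
}

#' Write a per-marker fit report as JSON
#'
#' Serializes the fitted mixtures of a calling run (locations, scales,
#' weights, log-likelihood, convergence, sample count per marker/unit)
#' together with each unit's call rate.
#'
#' @param result a list as returned by \code{\link{callDosageMatrix}}.
#' @param path output JSON path.
#' @return invisibly, \code{path}.
#' @importFrom jsonlite write_json
#' @export
writeFitReport <- function(result, path) {
  calls <- result$calls
  report <- lapply(result$fits, function(f) {
    unitCalls <- calls[calls$marker_id == markerId(f) &
                       calls$unit_id == unitId(f), , drop = FALSE]
    list(marker_id = markerId(f), unit_id = unitId(f),
         locations = f@locations, scales = f@scales, weights = f@weights,
         log_likelihood = f@logLik, converged = f@converged,
         n_samples = f@nSamples,
         call_rate = callRate(unitCalls))
  })
  jsonlite::write_json(unname(report), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Call a full signal-record set into a dosage score matrix
#'
#' Runs the mixture caller marker by marker under one of the two analysis-
#' unit schemes: \code{"original"} models all samples of an analysis plate
#' together (190-380 genotypes), \code{"single"} first splits them back into
#' their 95-genotype source-plate groups and fits each group separately.
#' Marker/unit combinations with too few usable samples yield missing calls
#' for the whole unit rather than an error.
#'
#' @param records signal-record \code{data.frame} covering any number of
#'   markers and plates.
#' @param config a \code{\link{CallerConfig}}.
#' @param layout \code{"original"} or \code{"single"}.
#' @return a list with elements \code{matrix} (a \code{\link{ScoreMatrix}}
#'   carrying assigned-class posteriors), \code{calls} (row-bound call
#'   data.frames) and \code{fits} (list of \code{DosageMixtureFit}).
#' @examples
#' tr <- generateTruthPanel(nAccessions = 190, nMarkers = 2, seed = 3)
#' rec <- simulateFluorescence(tr)
#' res <- callDosageMatrix(rec, layout = "single")
#' res$matrix
#' @export
callDosageMatrix <- function(records, config = CallerConfig(),
                             layout = c("original", "single")) {
  layout <- match.arg(layout)
  records$unit_id <- if (layout == "original") {
    records$analysis_plate_id
  } else {
    paste(records$analysis_plate_id, records$source_plate_id, sep = ":")
  }
  accessions <- sort(unique(records$sample_id[!records$is_negative_control]))
  markers <- sort(unique(records$marker_id))
  sc <- matrix(NA_integer_, length(accessions), length(markers),
               dimnames = list(accessions, markers))
  po <- matrix(NA_real_, length(accessions), length(markers),
               dimnames = list(accessions, markers))
  fits <- list()
  allCalls <- list()
  for (grp in split(records,
                    list(records$marker_id, records$unit_id), drop = TRUE)) {
    calls <- tryCatch({
      fit <- fitDosageMixture(grp, config)
      fits[[paste(markerId(fit), unitId(fit))]] <- fit
      callDosages(fit, grp, config)
    }, polyfp_fit_error = function(e) {
      data.frame(sample_id = grp$sample_id, marker_id = grp$marker_id,
                 unit_id = grp$unit_id, source_plate_id = grp$source_plate_id,
                 well = grp$well,
                 is_negative_control = grp$is_negative_control,
                 dosage = NA_integer_, posterior = NA_real_,
                 stringsAsFactors = FALSE)
    })
    allCalls[[length(allCalls) + 1L]] <- calls
    keep <- !calls$is_negative_control
    i <- match(calls$sample_id[keep], accessions)
    j <- match(calls$marker_id[keep], markers)
    sc[cbind(i, j)] <- calls$dosage[keep]
    po[cbind(i, j)] <- calls$posterior[keep]
  }
  list(matrix = ScoreMatrix(sc, layout = layout, posteriors = po),
       calls = do.call(rbind, allCalls),
       fits = fits)
}
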