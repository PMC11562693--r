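# Synthetic-data generator: plate-structured two-channel fluorescence with
# per-dosage clusters, dropout, injected duplicates and mislabels, and
# multinomial amplicon read counts. Defaults emulate a well-separated
# tetraploid assay: cluster means 0.1/0.3/0.5/0.7/0.9 on the signal-ratio
# axis with sd 0.02 and 2% dropout ("easy"); the "hard" preset widens the
# clusters to sd 0.07 so threshold-driven missingness appears.
# All randomness flows from one master seed through named substreams, so
# each operation is reproducible on its own.

.EASY_SCALE <- 0.02
.HARD_SCALE <- 0.07

#' Generate the ground truth of a synthetic fingerprinting panel
#'
#' Draws per-marker dosage-class frequencies from a symmetric Dirichlet with
#' the given concentration (larger concentration gives more even classes,
#' hence higher marker evenness), then draws each accession's true dosage
#' per marker from those frequencies. Chromosomes 1..7 are assigned
#' round-robin, so any panel of >= 14 markers passes the two-per-chromosome
#' coverage rule.
#'
#' @param nAccessions,nMarkers panel dimensions (defaults 500 x 18).
#' @param frequencyConcentration symmetric Dirichlet concentration
#'   (default 3).
#' @param seed master seed.
#' @param clusterLocations per-dosage mean transformed ratios.
#' @param clusterScale cluster standard deviation (default 0.02; use
#'   \code{presetScale("hard")} for the overlapping regime).
#' @param dropoutRate per-well probability of a failed (zero-signal) well.
#' @param ploidy ploidy (default 4; dosage classes 0..ploidy).
#' @return a \code{\link{SimulationTruth}}.
#' @examples
#' generateTruthPanel(nAccessions = 20, nMarkers = 4, seed = 1)
#' @export
generateTruthPanel <- function(nAccessions = 500L, nMarkers = 18L,
                               frequencyConcentration = 3,
                               seed = 1L,
                               clusterLocations = seq(0.1, 0.9, by = 0.2),
                               clusterScale = .EASY_SCALE,
                               dropoutRate = 0.02,
                               ploidy = 4L) {
  if (nAccessions < 1L || nMarkers < 1L)
    .validationError("panel dimensions must be >= 1")
  k <- ploidy + 1L
  accessions <- sprintf("ACC%04d", seq_len(nAccessions))
  markerIds <- sprintf("MK%02d", seq_len(nMarkers))

  set.seed(.subSeed(seed, "frequencies"))
  g <- matrix(rgamma(nMarkers * k, shape = frequencyConcentration),
              nMarkers, k)
  freqs <- g / rowSums(g)
  dimnames(freqs) <- list(markerIds, paste0("P", 0:(k - 1L)))

  set.seed(.subSeed(seed, "dosages"))
  dosages <- vapply(seq_len(nMarkers), function(j) {
    sample.int(k, nAccessions, replace = TRUE, prob = freqs[j, ]) - 1L
  }, integer(nAccessions))
  dosages <- matrix(dosages, nAccessions, nMarkers,
                    dimnames = list(accessions, markerIds))

  new("SimulationTruth",
      seed = as.integer(seed), accessions = accessions,
      markers = data.frame(marker_id = markerIds,
                           chromosome = rep_len(1:7, nMarkers),
                           stringsAsFactors = FALSE),
      frequencies = freqs, dosages = dosages,
      duplicates = data.frame(accession_a = character(),
                              accession_b = character()),
      mislabels = data.frame(accession_a = character(),
                             accession_b = character()),
      clusterLocations = clusterLocations, clusterScale = clusterScale,
      dropoutRate = dropoutRate)
}

#' Cluster scale of a named simulation preset
#'
#' @param preset \code{"easy"} (sd 0.02, well-separated clusters) or
#'   \code{"hard"} (sd 0.07, overlapping clusters with threshold-driven
#'   missing calls).
#' @return numeric cluster standard deviation.
#' @export
presetScale <- function(preset = c("easy", "hard")) {
  switch(match.arg(preset), easy = .EASY_SCALE, hard = .HARD_SCALE)
}

#' Inject duplicate accessions and mislabel swaps into a truth panel
#'
#' Duplicates copy an existing accession's true dosage vector under a new
#' id (suffix \code{"-DUP"}), emulating the same clone catalogued twice.
#' Mislabels swap the dosage vectors behind two ids while the labels stay:
#' each mislabel picks one member of an injected duplicate pair (when
#' available, so that an "assumed duplicate" pair stops matching) and swaps
#' its material with that of the most dissimilar outside accession. The
#' truth object's manifests record both sets.
#'
#' @param truth a \code{\link{SimulationTruth}}.
#' @param nDuplicates,nMislabels how many pairs/swaps to inject (each at
#'   most half the accession count).
#' @return the modified \code{\link{SimulationTruth}}.
#' @export
injectDuplicatesAndMislabels <- function(truth, nDuplicates = 0L,
                                         nMislabels = 0L) {
  stopifnot(is(truth, "SimulationTruth"))
  n <- length(truth@accessions)
  if (nDuplicates > n / 2 || nMislabels > n / 2)
    .validationError("cannot inject more pairs than half the accessions")
  if (nMislabels > 0 && nDuplicates > 0 && nMislabels > nDuplicates)
    .validationError("mislabels exceed the available duplicate pairs")

  dos <- truth@dosages
  dup <- truth@duplicates
  if (nDuplicates > 0) {
    set.seed(.subSeed(truth@seed, "duplicates"))
    src <- sample(truth@accessions, nDuplicates)
    newIds <- paste0(src, "-DUP")
    dos <- rbind(dos, dos[src, , drop = FALSE])
    rownames(dos) <- c(truth@accessions, newIds)
    truth@accessions <- rownames(dos)
    dup <- rbind(dup, data.frame(accession_a = src, accession_b = newIds,
                                 stringsAsFactors = FALSE))
  }

  mis <- truth@mislabels
  if (nMislabels > 0) {
    set.seed(.subSeed(truth@seed, "mislabels"))
    victims <- if (nrow(dup)) dup$accession_b[seq_len(nMislabels)]
      else sample(truth@accessions, nMislabels)
    pool <- setdiff(truth@accessions, c(dup$accession_a, dup$accession_b))
    for (v in victims) {
      # most dissimilar partner: maximum number of differing markers
      diffs <- rowSums(dos[pool, , drop = FALSE] !=
                       matrix(dos[v, ], length(pool), ncol(dos),
                              byrow = TRUE))
      partner <- pool[which.max(diffs)]
      tmp <- dos[v, ]
      dos[v, ] <- dos[partner, ]
      dos[partner, ] <- tmp
      pool <- setdiff(pool, partner)
      mis <- rbind(mis, data.frame(accession_a = v, accession_b = partner,
                                   stringsAsFactors = FALSE))
    }
  }

  truth@dosages <- dos
  truth@duplicates <- dup
  truth@mislabels <- mis
  validObject(truth)
  truth
}

.wellIds <- function(n, nrowPlate = 16L, ncolPlate = 24L) {
  rows <- rep(LETTERS[seq_len(nrowPlate)], each = ncolPlate)
  cols <- rep(seq_len(ncolPlate), nrowPlate)
  sprintf("%s%02d", rows, cols)[seq_len(n)]
}

#' Simulate plate-structured endpoint fluorescence for a truth panel
#'
#' Arranges the accessions into 95-genotype source plates (each with one
#' negative-control well), pools \code{platesPerAnalysis} source plates into
#' one analysis plate per marker, and emits two-channel signals per well:
#' the transformed ratio of a dosage-d sample is drawn from
#' N(location_d, scale) (clamped to (0, 1)) and back-computed into signal
#' channels, so \code{\link{transformSignal}} recovers the simulated ratio
#' exactly. Control wells emit near-zero signals; a sample drops out (both
#' signals zero, hence a missing call) with probability \code{dropoutRate}.
#'
#' @param truth a \code{\link{SimulationTruth}}.
#' @param platesPerAnalysis source plates pooled per analysis plate
#'   (default 4, i.e. 380 genotypes + 4 controls per 384-well plate).
#' @param sourcePlateSize genotypes per source plate (default 95).
#' @return a signal-record \code{data.frame}
#'   (see \code{\link{readFluorescence}}).
#' @export
simulateFluorescence <- function(truth, platesPerAnalysis = 4L,
                                 sourcePlateSize = 95L) {
  stopifnot(is(truth, "SimulationTruth"))
  acc <- truth@accessions
  nPlates <- ceiling(length(acc) / sourcePlateSize)
  sourcePlate <- sprintf("SP%03d", ceiling(seq_along(acc) / sourcePlateSize))
  markerIds <- truth@markers$marker_id

  set.seed(.subSeed(truth@seed, "fluorescence"))
  out <- vector("list", length(markerIds))
  for (m in seq_along(markerIds)) {
    mk <- markerIds[m]
    analysisPlate <- sprintf("AP%s_%03d", mk,
                             ceiling(seq_len(nPlates) / platesPerAnalysis))
    recs <- data.frame(
      sample_id = acc, marker_id = mk,
      source_plate_id = sourcePlate,
      analysis_plate_id = analysisPlate[match(sourcePlate,
                                              sprintf("SP%03d",
                                                      seq_len(nPlates)))],
      is_negative_control = FALSE, stringsAsFactors = FALSE
    )
    # one control well per source plate
    ctrl <- data.frame(
      sample_id = sprintf("NTC_%s_SP%03d", mk, seq_len(nPlates)),
      marker_id = mk,
      source_plate_id = sprintf("SP%03d", seq_len(nPlates)),
      analysis_plate_id = analysisPlate,
      is_negative_control = TRUE, stringsAsFactors = FALSE
    )
    recs <- rbind(recs, ctrl)
    recs <- recs[order(recs$analysis_plate_id, recs$source_plate_id), ]
    recs$well <- unlist(lapply(split(seq_len(nrow(recs)),
                                     recs$analysis_plate_id),
                               function(i) .wellIds(length(i))),
                        use.names = FALSE)

    d <- truth@dosages[, mk]
    ratio <- rnorm(length(acc), truth@clusterLocations[d + 1L],
                   truth@clusterScale)
    ratio <- pmin(pmax(ratio, 1e-3), 1 - 1e-3)
    total <- rlnorm(length(acc), log(2000), 0.15)
    sigA <- total * (1 - ratio)
    sigB <- total * ratio
    drop <- runif(length(acc)) < truth@dropoutRate
    sigA[drop] <- 0
    sigB[drop] <- 0
    sig <- data.frame(sample_id = acc, signal_a = sigA, signal_b = sigB,
                      stringsAsFactors = FALSE)
    ctrlSig <- data.frame(sample_id = ctrl$sample_id,
                          signal_a = runif(nrow(ctrl), 0, 20),
                          signal_b = runif(nrow(ctrl), 0, 20),
                          stringsAsFactors = FALSE)
    sig <- rbind(sig, ctrlSig)
    idx <- match(recs$sample_id, sig$sample_id)
    recs$signal_a <- sig$signal_a[idx]
    recs$signal_b <- sig$signal_b[idx]
    out[[m]] <- recs
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("sample_id", "marker_id", "source_plate_id", "analysis_plate_id",
          "well", "signal_a", "signal_b", "is_negative_control")]
}

#' Simulate multinomial amplicon reads from true haplotype dosages
#'
#' Each genotype's reads are multinomial with probabilities
#' dosage / ploidy over its haplotypes, at the given sequencing depth.
#' Synthetic gap-aligned haplotype sequences are fabricated
#' deterministically from the seed, mutually distinct at
#' \code{nVariableSites} alignment columns.
#'
#' @param dosages integer matrix, genotypes x haplotypes, rows summing to
#'   the ploidy (0 = haplotype absent), with dimnames.
#' @param depth sequencing depth per genotype (>= 1).
#' @param seed random seed.
#' @param markerId marker id for the resulting table.
#' @param ampliconLength aligned amplicon length in bp (default 240).
#' @param nVariableSites number of columns at which haplotypes differ.
#' @return a \code{\link{HaplotypeTable}}.
#' @examples
#' d <- matrix(c(3L, 1L, 2L, 2L), 2, 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("H1", "H2")))
#' simulateAmpliconReads(d, depth = 1000, seed = 1)
#' @export
simulateAmpliconReads <- function(dosages, depth = 1000L, seed = 1L,
                                  markerId = "AMP01",
                                  ampliconLength = 240L,
                                  nVariableSites = max(3L, ncol(dosages))) {
  if (depth < 1L) .validationError("depth must be >= 1")
  ploidy <- unique(rowSums(dosages))
  if (length(ploidy) != 1L)
    .validationError("every genotype's dosages must sum to the same ploidy")

  set.seed(.subSeed(seed, "haplotype_sequences"))
  backbone <- sample(c("A", "C", "G", "T"), ampliconLength, replace = TRUE)
  sites <- sort(sample.int(ampliconLength, nVariableSites))
  seqs <- vapply(seq_len(ncol(dosages)), function(h) {
    s <- backbone
    # give each haplotype a distinct symbol pattern at the variable sites,
    # including gaps so indel columns occur
    alpha <- c("A", "C", "G", "T", "-")
    s[sites] <- alpha[(h + seq_along(sites)) %% length(alpha) + 1L]
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- colnames(dosages)

  set.seed(.subSeed(seed, "amplicon_reads"))
  cm <- t(vapply(seq_len(nrow(dosages)), function(g) {
    as.integer(rmultinom(1, depth, prob = dosages[g, ] / ploidy))
  }, integer(ncol(dosages))))
  dimnames(cm) <- dimnames(dosages)
  HaplotypeTable(markerId, Biostrings::DNAStringSet(seqs), cm,
                 as.integer(ampliconLength))
}
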