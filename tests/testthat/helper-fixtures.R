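# Shared fixture builders: signal-record frames from raw ratios, toy score
# matrices, and toy haplotype tables, all constructed in code.

makeRecords <- function(ratios, marker = "M1", total = 2000,
                        sourcePlate = "SP1", analysisPlate = "AP1",
                        control = FALSE) {
  n <- length(ratios)
  data.frame(
    sample_id = sprintf("s%04d", seq_len(n)),
    marker_id = marker,
    source_plate_id = rep_len(sourcePlate, n),
    analysis_plate_id = analysisPlate,
    well = sprintf("A%02d", seq_len(n) %% 24 + 1),
    signal_a = total * (1 - ratios),
    signal_b = total * ratios,
    is_negative_control = rep_len(control, n),
    stringsAsFactors = FALSE
  )
}

clusteredRatios <- function(perClass, locations = seq(0.1, 0.9, 0.2),
                            scale = 0.02) {
  truth <- rep(seq_along(locations) - 1L, times = perClass)
  list(truth = truth,
       ratios = pmin(pmax(rnorm(length(truth), locations[truth + 1L], scale),
                          1e-3), 1 - 1e-3))
}

makeScoreMatrix <- function(values, accessions = NULL, markers = NULL,
                            layout = "test", posteriors = NULL) {
  m <- as.matrix(values)
  if (is.null(accessions)) accessions <- sprintf("acc%02d", seq_len(nrow(m)))
  if (is.null(markers)) markers <- sprintf("mk%02d", seq_len(ncol(m)))
  dimnames(m) <- list(accessions, markers)
  if (is.null(posteriors)) {
    ScoreMatrix(m, layout = layout)
  } else {
    p <- as.matrix(posteriors)
    dimnames(p) <- dimnames(m)
    ScoreMatrix(m, layout = layout, posteriors = p)
  }
}

makeHaplotypeTable <- function(counts, seqs = NULL, marker = "AMP1") {
  cm <- as.matrix(counts)
  if (is.null(rownames(cm))) rownames(cm) <- sprintf("g%02d", seq_len(nrow(cm)))
  if (is.null(colnames(cm))) colnames(cm) <- sprintf("H%d", seq_len(ncol(cm)))
  if (is.null(seqs)) {
    base <- strsplit("ACGTACGTACGT", "")[[1]]
    seqs <- vapply(seq_len(ncol(cm)), function(h) {
      s <- base
      s[h] <- c("T", "G", "C", "A", "-")[(h - 1L) %% 5L + 1L]
      paste(s, collapse = "")
    }, character(1))
  }
  names(seqs) <- colnames(cm)
  HaplotypeTable(marker, Biostrings::DNAStringSet(seqs), cm)
}
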