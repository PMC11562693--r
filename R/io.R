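# Readers and writers for the tabular formats the pipeline touches:
# fluorescence exports + plate maps, dosage score matrices, and amplicon
# haplotype data (gapped FASTA + read-count TSV). All readers validate and
# reject out-of-domain values rather than coercing them.

#' Read an endpoint-fluorescence export with its plate map
#'
#' Parses a two-channel endpoint-fluorescence export (one row per well of an
#' analysis plate, CSV with columns \code{well,sample_id,marker_id,signal_a,
#' signal_b}) together with a plate-map TSV (\code{well,sample_id,
#' source_plate_id,is_control}) assigning each sample to its source DNA plate
#' and flagging negative-control wells.
#'
#' @param path path to the fluorescence export CSV.
#' @param layoutPath path to the plate-map TSV.
#' @param analysisPlateId id of the analysis plate this export came from;
#'   defaults to the export's file name.
#' @return a \code{data.frame} of signal records with columns
#'   \code{sample_id, marker_id, source_plate_id, analysis_plate_id, well,
#'   signal_a, signal_b, is_negative_control}.
#' @examples
#' tr <- generateTruthPanel(nAccessions = 10, nMarkers = 1, seed = 1)
#' rec <- simulateFluorescence(tr)
#' d <- tempfile(); dir.create(d)
#' paths <- writeFluorescence(rec, d)
#' rec2 <- readFluorescence(paths$export, paths$plateMap,
#'                          analysisPlateId = rec$analysis_plate_id[1])
#' nrow(rec2) == nrow(rec)
#' @export
readFluorescence <- function(path, layoutPath,
                             analysisPlateId = basename(path)) {
  exp <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
  .stopifnotCols(exp, c("well", "sample_id", "marker_id",
                        "signal_a", "signal_b"), "fluorescence export")
  pm <- read.delim(layoutPath, stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE)
  .stopifnotCols(pm, c("well", "sample_id", "source_plate_id", "is_control"),
                 "plate map")

  sa <- suppressWarnings(as.numeric(exp$signal_a))
  sb <- suppressWarnings(as.numeric(exp$signal_b))
  bad <- which(is.na(sa) | is.na(sb))
  if (length(bad))
    .formatError("non-numeric signal value(s) at export row(s): %s",
                 paste(bad + 1L, collapse = ", "))  # +1: header line
  neg <- which(sa < 0 | sb < 0)
  if (length(neg))
    .integrityError("negative signal value(s) at export row(s): %s",
                    paste(neg + 1L, collapse = ", "))

  key <- paste(exp$sample_id, exp$marker_id, analysisPlateId, sep = "\r")
  if (anyDuplicated(key))
    .integrityError("duplicate (sample, marker, analysis plate) entries: %s",
                    paste(unique(exp$sample_id[duplicated(key)]),
                          collapse = ", "))

  idx <- match(exp$sample_id, pm$sample_id)
  if (anyNA(idx))
    .integrityError("sample(s) absent from plate map: %s",
                    paste(unique(exp$sample_id[is.na(idx)]), collapse = ", "))
  data.frame(
    sample_id = exp$sample_id,
    marker_id = exp$marker_id,
    source_plate_id = pm$source_plate_id[idx],
    analysis_plate_id = analysisPlateId,
    well = exp$well,
    signal_a = sa,
    signal_b = sb,
    is_negative_control = pm$is_control[idx] %in% c("TRUE", "true", "1"),
    stringsAsFactors = FALSE
  )
}

#' Write signal records as a fluorescence export plus plate map
#'
#' Inverse of \code{\link{readFluorescence}} for records of a single analysis
#' plate; used to materialise simulated data in the instrument-export dialect.
#'
#' @param records signal-record \code{data.frame} (one analysis plate).
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, a list with the paths \code{export} and \code{plateMap}.
#' @export
writeFluorescence <- function(records, dir, prefix = "plate") {
  if (length(unique(records$analysis_plate_id)) != 1L)
    .usageError("writeFluorescence expects records of a single analysis plate")
  exportPath <- file.path(dir, paste0(prefix, "_export.csv"))
  mapPath <- file.path(dir, paste0(prefix, "_platemap.tsv"))
  write.csv(records[, c("well", "sample_id", "marker_id",
                        "signal_a", "signal_b")],
            exportPath, row.names = FALSE, quote = FALSE)
  pm <- unique(records[, c("well", "sample_id", "source_plate_id",
                           "is_negative_control")])
  names(pm)[4] <- "is_control"
  write.table(pm, mapPath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(export = exportPath, plateMap = mapPath))
}

#' Read and write dosage score matrices
#'
#' A score matrix CSV has a first column \code{accession}, one column per
#' marker, cells in \code{0..4} or \code{NA}, and an optional leading comment
#' line \code{# layout=<tag>} carrying the plate-layout tag. Writing then
#' reading a matrix is an identity, including missing cells and the tag.
#'
#' @param path file path.
#' @return \code{readScoreMatrix} returns a \code{\link{ScoreMatrix}}.
#' @examples
#' m <- ScoreMatrix(matrix(c(1L, NA, 3L, 0L), 2, 2,
#'                  dimnames = list(c("a", "b"), c("m1", "m2"))), "single")
#' f <- tempfile(fileext = ".csv")
#' writeScoreMatrix(m, f)
#' identical(scores(readScoreMatrix(f)), scores(m))
#' @export
readScoreMatrix <- function(path) {
  first <- readLines(path, n = 1L)
  layout <- "unspecified"
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    m <- regmatches(first, regexec("layout=([^[:space:]]+)", first))[[1]]
    if (length(m) == 2L) layout <- m[2]
  }
  df <- read.csv(path, skip = skip, stringsAsFactors = FALSE,
                 colClasses = "character", check.names = FALSE)
  .stopifnotCols(df, "accession", "score matrix")
  markers <- setdiff(names(df), "accession")
  vals <- as.matrix(df[, markers, drop = FALSE])
  ok <- is.na(vals) | vals == "NA" | vals %in% as.character(0:4)
  if (!all(ok))
    .formatError("score matrix cell(s) outside 0..4/NA: %s",
                 paste(unique(vals[!ok]), collapse = ", "))
  num <- matrix(suppressWarnings(as.integer(vals)), nrow(vals), ncol(vals),
                dimnames = list(df$accession, markers))
  ScoreMatrix(num, layout = layout)
}

#' @param x a \code{ScoreMatrix}.
#' @rdname readScoreMatrix
#' @return \code{writeScoreMatrix} invisibly returns \code{path}.
#' @export
writeScoreMatrix <- function(x, path) {
  stopifnot(is(x, "ScoreMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# layout=%s", layoutTag(x)), con)
  sc <- scores(x)
  acc <- rownames(sc)
  if (is.null(acc)) acc <- character(nrow(sc))
  df <- data.frame(accession = acc, sc,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("accession", colnames(sc))
  write.csv(df, con, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read amplicon haplotype data (gapped FASTA plus read-count TSV)
#'
#' Loads the gap-aligned haplotype sequences of one amplicon marker and the
#' per-genotype read counts over those haplotypes. All sequences must share
#' one aligned length, and every haplotype id in the count table must exist
#' in the FASTA.
#'
#' @param fastaPath FASTA of gap-aligned haplotype sequences (gaps "-").
#' @param countsPath TSV with columns \code{genotype_id,haplotype_id,reads}.
#' @param markerId marker id for the resulting table; defaults to the FASTA
#'   file name.
#' @return a \code{\link{HaplotypeTable}}.
#' @export
readHaplotypeData <- function(fastaPath, countsPath,
                              markerId = basename(fastaPath)) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  w <- Biostrings::width(seqs)
  if (length(unique(w)) > 1L)
    .formatError("aligned haplotype lengths differ: %s",
                 paste(unique(w), collapse = ", "))
  cnt <- read.delim(countsPath, stringsAsFactors = FALSE, check.names = FALSE)
  .stopifnotCols(cnt, c("genotype_id", "haplotype_id", "reads"),
                 "haplotype count table")
  unknown <- setdiff(cnt$haplotype_id, names(seqs))
  if (length(unknown))
    .integrityError("count rows reference unknown haplotype id(s): %s",
                    paste(unknown, collapse = ", "))
  reads <- suppressWarnings(as.numeric(cnt$reads))
  if (anyNA(reads) || any(reads < 0) || any(reads != round(reads)))
    .formatError("reads must be non-negative integers")
  gts <- unique(cnt$genotype_id)
  mat <- matrix(0L, length(gts), length(seqs),
                dimnames = list(gts, names(seqs)))
  mat[cbind(match(cnt$genotype_id, gts),
            match(cnt$haplotype_id, names(seqs)))] <- as.integer(reads)
  HaplotypeTable(markerId, seqs, mat)
}

#' Write amplicon haplotype data
#'
#' Inverse of \code{\link{readHaplotypeData}}: writes the aligned sequences
#' as FASTA and the non-zero read counts as a long-format TSV.
#'
#' @param x a \code{\link{HaplotypeTable}}.
#' @param fastaPath,countsPath output paths.
#' @return invisibly, a list of the two paths.
#' @export
writeHaplotypeData <- function(x, fastaPath, countsPath) {
  stopifnot(is(x, "HaplotypeTable"))
  Biostrings::writeXStringSet(haplotypeSequences(x), fastaPath)
  cm <- readCounts(x)
  idx <- which(cm > 0, arr.ind = TRUE)
  df <- data.frame(genotype_id = rownames(cm)[idx[, 1]],
                   haplotype_id = colnames(cm)[idx[, 2]],
                   reads = cm[idx], stringsAsFactors = FALSE)
  df <- df[order(df$genotype_id, df$haplotype_id), ]
  write.table(df, countsPath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(fasta = fastaPath, counts = countsPath))
}
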