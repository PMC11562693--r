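# Internal helpers: classed error conditions and seed substreams.

.err <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "polyfp_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

.formatError    <- function(msg, ...) .err("polyfp_format_error", msg, ...)
.integrityError <- function(msg, ...) .err("polyfp_integrity_error", msg, ...)
.usageError     <- function(msg, ...) .err("polyfp_usage_error", msg, ...)
.validationError<- function(msg, ...) .err("polyfp_validation_error", msg, ...)
.fitError       <- function(msg, ...) .err("polyfp_fit_error", msg, ...)

# Deterministic sub-seed for a named random substream, kept below 2^31.
.subSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

.stopifnotCols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    .formatError("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", "))
  invisible(df)
}
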