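#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish format, integrity,
# junction, address, volume and compile failures programmatically.
pf_stop <- function(message, class, data = list()) {
  cond <- structure(
    class = c(class, "pf_error", "error", "condition"),
    list(message = message, call = sys.call(-1), data = data)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Snap volumes to a dispenser's droplet quantum
#'
#' Acoustic dispensers move liquid in fixed droplet increments; every
#' emitted volume must be an exact multiple of that quantum. Rounding up
#' guarantees at least the requested amount (used for molar targets);
#' rounding down guarantees a fill never overflows.
#'
#' @param volume_ul numeric vector of volumes in microliters.
#' @param quantum_ul droplet quantum in microliters (e.g. 0.025 for a
#'   25 nL instrument, 0.0025 for 2.5 nL resolution).
#' @return volumes snapped to multiples of `quantum_ul`.
#' @export
quantize_up <- function(volume_ul, quantum_ul) {
  stopifnot(quantum_ul > 0)
  # guard against 123.599.../2.5 style float error pushing a boundary up
  ceiling(round(volume_ul / quantum_ul, 9)) * quantum_ul
}

#' @rdname quantize_up
#' @export
quantize_down <- function(volume_ul, quantum_ul) {
  stopifnot(quantum_ul > 0)
  floor(round(volume_ul / quantum_ul, 9)) * quantum_ul
}

# Reverse complement without pulling XStringSet machinery into hot loops.
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Deterministic CSV writers: stable column order, UTF-8, RFC-4180 quoting.
write_table_utf8 <- function(df, file) {
  utils::write.csv(df, file, row.names = FALSE, fileEncoding = "UTF-8",
                   na = "")
}

read_table_utf8 <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE,
                  fileEncoding = "UTF-8")
}

# canonical row order + clean rownames, so round-trips are byte-stable
canonical_df <- function(df, key) {
  if (nrow(df) > 1 && key %in% names(df)) df <- df[order(df[[key]]), ,
                                                   drop = FALSE]
  rownames(df) <- NULL
  df
}
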