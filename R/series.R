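#' Read an RR-interval series from a plain-text file
#'
#' The expected format is one RR interval per line, in milliseconds.  Lines
#' beginning with `#` and blank lines are ignored.
#'
#' @param path Path to the text file.
#' @return A numeric vector of RR intervals (ms).
#' @seealso [write_rri()], [clean_rri()]
#' @export
read_rri <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  x <- suppressWarnings(as.numeric(lines))
  if (anyNA(x))
    stop("non-numeric RR-interval lines in '", path, "'")
  x
}

#' Write an RR-interval series to a plain-text file
#'
#' One value per line, milliseconds; the inverse of [read_rri()].
#'
#' @param x Numeric vector of RR intervals (ms).
#' @param path Output file path.
#' @param digits Number of significant digits to keep.
#' @return `path`, invisibly.
#' @export
write_rri <- function(x, path, digits = 10) {
  check_series(x, min_len = 2)
  writeLines(formatC(x, digits = digits, format = "g"), path)
  invisible(path)
}

# shared input validation: finite numeric series of a minimum length
check_series <- function(x, min_len = 2, what = "x") {
  if (!is.numeric(x))
    stop("'", what, "' must be a numeric vector")
  if (length(x) < min_len)
    stop("'", what, "' must contain at least ", min_len, " samples")
  if (!all(is.finite(x)))
    stop("'", what, "' contains non-finite values")
  invisible(x)
}

# population standard deviation (divide by N); the tolerance r is defined as a
# fraction of this quantity for the series actually analysed
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}
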