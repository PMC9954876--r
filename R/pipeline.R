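#' Automated premature-beat removal from an RR-interval series
#'
#' A beat is removed (not interpolated) when it deviates from the median of
#' the surrounding `window`-beat window (window truncated at the record
#' edges, beat included) by more than `max_rel_dev` of that median — an
#' explicit, reproducible surrogate for visual premature-beat editing.
#' If more than 10\% of beats are removed the series is flagged low-quality
#' and a warning is raised.
#'
#' @param x RR-interval series (ms), length at least `window`.
#' @param max_rel_dev Maximum tolerated relative deviation from the running
#'   median (default 0.25).
#' @param window Running-median window in beats (default 5).
#' @return A list with `series` (cleaned values) and `report` (class
#'   `"cleaning_report"`): `n_input`, `n_removed`, `removed_indices`,
#'   `rule_parameters`, `low_quality`.
#' @examples
#' clean_rri(c(800, 810, 400, 805, 795))$report$removed_indices  # 3
#' @export
clean_rri <- function(x, max_rel_dev = 0.25, window = 5L) {
  window <- as.integer(window)
  if (window < 1L) stop("'window' must be a positive integer")
  check_series(x, min_len = window)
  h <- window %/% 2L
  n <- length(x)
  med <- vapply(seq_len(n), function(i)
    median(x[max(1L, i - h):min(n, i + h)]), numeric(1))
  bad <- abs(x - med) > max_rel_dev * med
  report <- structure(list(n_input = n, n_removed = sum(bad),
                           removed_indices = which(bad),
                           rule_parameters = list(max_rel_dev = max_rel_dev,
                                                  window = window),
                           low_quality = sum(bad) > 0.1 * n),
                      class = "cleaning_report")
  if (report$low_quality)
    warning("more than 10% of beats removed (", report$n_removed, "/", n,
            "); series flagged low-quality")
  list(series = x[!bad], report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("RRI cleaning: removed ", x$n_removed, " of ", x$n_input, " beats",
      if (x$low_quality) " [LOW QUALITY]", "\n", sep = "")
  invisible(x)
}

#' Select a contiguous analysis segment
#'
#' Returns a `length`-beat contiguous window of a (cleaned) series: the
#' first such window by default, or the centred one.
#'
#' @param x Numeric series of length at least `length`.
#' @param length Segment length in beats (default 512).
#' @param policy `"first"` (default) or `"middle"`.
#' @return The selected segment.
#' @examples
#' length(select_segment(rnorm(600) + 900))  # 512
#' @export
select_segment <- function(x, length = 512L, policy = c("first", "middle")) {
  policy <- match.arg(policy)
  length <- as.integer(length)
  n <- base::length(x)
  if (n < length)
    stop("series has ", n, " beats; need at least ", length)
  start <- switch(policy, first = 1L, middle = (n - length) %/% 2L + 1L)
  x[start:(start + length - 1L)]
}

#' Reproduce the benchmark-bank entropy summary tables
#'
#' Generates the five-process benchmark bank ([gen_bank()]), evaluates
#' SampEn, FuzzyEn and DistEn at scale 1 and, optionally, full multiscale
#' profiles, and returns per-process mean/SEM summary tables.
#'
#' @param seed Base seed for the bank.
#' @param n_series Series per process (default 30).
#' @param n_samples Samples per series (default 512).
#' @param m Embedding dimensions (default `c(1, 2)`).
#' @param scales Scales for the multiscale summary; `NULL` skips profiles.
#' @inheritParams multiscale_entropy
#' @return A list with data frames `tau1` (process, method, m, mean, sem,
#'   n_undefined) and, when `scales` is given, `profiles` (additionally per
#'   tau).
#' @export
reproduce_bank <- function(seed = 1L, n_series = 30L, n_samples = 512L,
                           m = c(1L, 2L), scales = NULL, r = 0.2, n = 2,
                           n_bins = 512L, filter = "butterworth",
                           order = 6L, rescale_r = TRUE) {
  bank <- gen_bank(n_series, n_samples, seed)
  manifest <- attr(bank, "manifest")
  methods <- c("sampen", "fuzzyen", "disten")
  summarise <- function(v) {
    ok <- !is.na(v)
    c(mean = mean(v[ok]), sem = sd(v[ok]) / sqrt(sum(ok)),
      n_undefined = sum(!ok))
  }
  tau1 <- list()
  for (proc in unique(manifest$process)) {
    labs <- manifest$label[manifest$process == proc]
    for (mm in m) for (meth in methods) {
      v <- vapply(labs, function(l)
        as.double(estimate_entropy(bank[[l]], meth, m = mm, r = r, n = n,
                                   n_bins = n_bins)), numeric(1))
      s <- summarise(v)
      tau1[[length(tau1) + 1L]] <- data.frame(
        process = proc, method = meth, m = as.integer(mm),
        mean = s[["mean"]], sem = s[["sem"]],
        n_undefined = as.integer(s[["n_undefined"]]))
    }
  }
  out <- list(tau1 = do.call(rbind, tau1))
  if (!is.null(scales)) {
    prof <- list()
    for (proc in unique(manifest$process)) {
      labs <- manifest$label[manifest$process == proc]
      for (mm in m) for (meth in methods) {
        vals <- sapply(labs, function(l)
          multiscale_entropy(bank[[l]], meth, m = mm, r = r, n = n,
                             n_bins = n_bins, scales = scales,
                             filter = filter, order = order,
                             rescale_r = rescale_r)$table$value)
        for (si in seq_along(scales)) {
          s <- summarise(vals[si, ])
          prof[[length(prof) + 1L]] <- data.frame(
            process = proc, method = meth, m = as.integer(mm),
            tau = as.integer(scales[si]), mean = s[["mean"]],
            sem = s[["sem"]], n_undefined = as.integer(s[["n_undefined"]]))
        }
      }
    }
    out$profiles <- do.call(rbind, prof)
  }
  out
}

#' CSV exports
#'
#' Writers for the package's tabular outputs: entropy estimate tables
#' ([entropy_table()] / [cohort_estimates()]), multiscale profiles and ePDFs.
#'
#' @param tab The object to write.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @name exports
NULL

#' @rdname exports
#' @export
write_estimates_csv <- function(tab, path) {
  cols <- intersect(c("series_label", "subject_id", "group", "posture",
                      "method", "m", "tau", "delay", "r_used", "value",
                      "defined"), names(tab))
  write.csv(tab[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname exports
#' @export
write_profile_csv <- function(tab, path) {
  if (inherits(tab, "multiscale_profile")) tab <- as.data.frame(tab)
  cols <- intersect(c("series_label", "method", "m", "tau", "value",
                      "defined", "filter_kind", "filter_order"), names(tab))
  write.csv(tab[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname exports
#' @export
write_epdf_csv <- function(tab, path) {
  if (inherits(tab, "entropy_estimate")) tab <- attr(tab, "epdf")
  stopifnot(all(c("bin_left", "bin_right", "probability") %in% names(tab)))
  write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}
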