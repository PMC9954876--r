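# constructor shared by the three estimators
new_entropy_estimate <- function(method, value, defined, reason = NA_character_,
                                 m, delay, r_used = NA_real_,
                                 n_pairs_m = NA_real_, n_pairs_m1 = NA_real_,
                                 n = NA_integer_, label = NULL) {
  structure(list(method = method, value = value, defined = defined,
                 reason = reason, m = as.integer(m), delay = as.integer(delay),
                 r_used = r_used, n_pairs_m = n_pairs_m,
                 n_pairs_m1 = n_pairs_m1, n = as.integer(n),
                 label = label),
            class = "entropy_estimate")
}

#' @export
print.entropy_estimate <- function(x, ...) {
  nm <- switch(x$method, sampen = "Sample Entropy",
               fuzzyen = "Fuzzy Entropy", disten = "Distribution Entropy",
               x$method)
  cat(nm, " (m = ", x$m, ", delay = ", x$delay,
      if (!is.na(x$r_used)) paste0(", r = ", signif(x$r_used, 4)), ")\n",
      sep = "")
  if (x$defined) {
    cat("  value:", format(x$value, digits = 6), "\n")
  } else {
    cat("  value: undefined (", x$reason, ")\n", sep = "")
  }
  invisible(x)
}

#' @export
as.double.entropy_estimate <- function(x, ...) {
  if (x$defined) x$value else NA_real_
}

#' Sample Entropy (SampEn)
#'
#' SampEn is \eqn{-\ln[n_p(m+1, r) / n_p(m, r)]}, where \eqn{n_p(m, r)} is the
#' number of unordered template-vector pairs at embedding dimension \eqn{m}
#' whose Chebyshev distance is strictly below the tolerance \eqn{r}.  Both
#' counts run over the same \eqn{N - m\tau} vectors (see [embed_delay()]).
#' The tolerance is `r` times the population standard deviation of `x`.
#'
#' When either count is zero the estimate is *undefined*: the returned object
#' carries `defined = FALSE` and the reason, rather than a silent `0` or
#' `Inf`; downstream summaries skip and count such cases.
#'
#' @param x Numeric series (an RR-interval series in ms, or any real series).
#' @param m Embedding dimension (default 2).
#' @param r Tolerance as a fraction of the series SD (default 0.20).
#' @param delay Embedding delay \eqn{\tau} (default 1).
#' @param label Optional series label carried into exports.
#' @return An object of class `"entropy_estimate"`; `as.double()` extracts the
#'   value (`NA` if undefined).
#' @examples
#' set.seed(1)
#' sample_entropy(rnorm(512))
#' @seealso [fuzzy_entropy()], [distribution_entropy()], [multiscale_entropy()]
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2, delay = 1L, label = NULL) {
  m <- as.integer(m); delay <- as.integer(delay)
  check_series(x, min_len = m * delay + 2L)
  if (r <= 0) stop("'r' must be positive")
  N <- length(x)
  n_vec <- N - m * delay
  r_used <- r * pop_sd(x)
  if (r_used == 0) {  # constant series: every pair matches at both dimensions
    np <- n_vec * (n_vec - 1) / 2
    return(new_entropy_estimate("sampen", 0, TRUE, NA_character_,
                                m, delay, r_used, np, np, N, label))
  }
  a <- cheb_paircount_lt_cpp(x, m, delay, n_vec, r_used)
  b <- cheb_paircount_lt_cpp(x, m + 1L, delay, n_vec, r_used)
  if (a == 0 || b == 0) {
    reason <- if (a == 0) "no template matches at dimension m"
              else "no template matches at dimension m+1"
    return(new_entropy_estimate("sampen", NA_real_, FALSE, reason,
                                m, delay, r_used, a, b, N, label))
  }
  new_entropy_estimate("sampen", -log(b / a), TRUE, NA_character_,
                       m, delay, r_used, a, b, N, label)
}

#' Fuzzy Entropy (FuzzyEn)
#'
#' FuzzyEn replaces SampEn's hard match threshold with a graded exponential
#' membership: \eqn{\ln\phi^m - \ln\phi^{m+1}}, where \eqn{\phi^m} is the mean
#' pairwise membership over the \eqn{N - m\tau} template vectors at dimension
#' \eqn{m}.  This is the *global* variant, without local trend removal, so
#' values are directly comparable to SampEn at the same \eqn{m}.
#'
#' Two membership families are available.  The default, `"scaled"`, is
#' \eqn{\exp[-(d/r)^n]}: it depends on distances only through \eqn{d/r}, which
#' makes the estimator exactly invariant under affine rescaling of the series.
#' `"chen"` is the quadratic-exponential family \eqn{\exp(-d^n/r)} of the
#' original surface-EMG formulation; it is not scale-invariant for
#' \eqn{n \ne 1} and is provided for comparison with that literature.
#'
#' FuzzyEn is always defined (memberships are strictly positive) and
#' non-negative (the Chebyshev distance is non-decreasing in the embedding
#' dimension, so \eqn{\phi^{m+1} \le \phi^m}).
#'
#' @inheritParams sample_entropy
#' @param n Membership exponent (default 2).
#' @param fuzzy_form Membership family, `"scaled"` (default) or `"chen"`.
#' @return An object of class `"entropy_estimate"`.
#' @examples
#' set.seed(1)
#' fuzzy_entropy(rnorm(512))
#' @export
fuzzy_entropy <- function(x, m = 2L, r = 0.2, n = 2, delay = 1L,
                          fuzzy_form = c("scaled", "chen"), label = NULL) {
  m <- as.integer(m); delay <- as.integer(delay)
  fuzzy_form <- match.arg(fuzzy_form)
  check_series(x, min_len = m * delay + 2L)
  if (r <= 0) stop("'r' must be positive")
  if (n <= 0) stop("'n' must be positive")
  N <- length(x)
  n_vec <- N - m * delay
  r_used <- r * pop_sd(x)
  if (r_used == 0) {  # constant series: all memberships 1 at both dimensions
    return(new_entropy_estimate("fuzzyen", 0, TRUE, NA_character_,
                                m, delay, r_used, n = N, label = label))
  }
  form <- if (fuzzy_form == "scaled") 0L else 1L
  phi_m  <- fuzzy_meansim_cpp(x, m,      delay, n_vec, r_used, n, form)
  phi_m1 <- fuzzy_meansim_cpp(x, m + 1L, delay, n_vec, r_used, n, form)
  new_entropy_estimate("fuzzyen", log(phi_m) - log(phi_m1), TRUE,
                       NA_character_, m, delay, r_used, n = N, label = label)
}

#' Distribution Entropy (DistEn)
#'
#' DistEn is the Shannon entropy of the empirical probability distribution
#' (ePDF) of the pairwise template-vector distances at dimension \eqn{m},
#' normalised by \eqn{\log_2 M}: neither a tolerance threshold nor an
#' \eqn{m+1} embedding is involved.  Values lie in \eqn{[0, 1]}; a degenerate
#' distance set (all distances equal, e.g. a constant series) gives 0.
#'
#' @inheritParams sample_entropy
#' @param n_bins Number of equispaced ePDF bins \eqn{M} (default 512).
#' @return An object of class `"entropy_estimate"` with an `epdf` attribute
#'   (see [empirical_pdf()]).
#' @examples
#' set.seed(1)
#' distribution_entropy(rnorm(512))
#' @export
distribution_entropy <- function(x, m = 2L, n_bins = 512L, delay = 1L,
                                 label = NULL) {
  m <- as.integer(m); delay <- as.integer(delay)
  check_series(x, min_len = m * delay + 2L)
  N <- length(x)
  n_vec <- N - m * delay
  d <- cheb_pairdist_cpp(x, m, delay, n_vec)
  pdf <- empirical_pdf(d, n_bins)
  value <- shannon_entropy(pdf$probability) / log2(as.integer(n_bins))
  est <- new_entropy_estimate("disten", value, TRUE, NA_character_,
                              m, delay, NA_real_,
                              n_pairs_m = length(d), n = N, label = label)
  attr(est, "epdf") <- pdf
  est
}

# dispatch by method keyword; used by multiscale and cohort layers
estimate_entropy <- function(x, method, m = 2L, r = 0.2, n = 2,
                             n_bins = 512L, delay = 1L,
                             fuzzy_form = "scaled", label = NULL) {
  switch(method,
         sampen  = sample_entropy(x, m = m, r = r, delay = delay, label = label),
         fuzzyen = fuzzy_entropy(x, m = m, r = r, n = n, delay = delay,
                                 fuzzy_form = fuzzy_form, label = label),
         disten  = distribution_entropy(x, m = m, n_bins = n_bins,
                                        delay = delay, label = label),
         stop("unknown method '", method, "'"))
}

#' Tabulate entropy estimates for a collection of series
#'
#' Convenience wrapper evaluating one or more estimators over a list of
#' series, returning the long-format table used by the CSV exports.
#'
#' @param series A list of numeric series (names become labels) or a single
#'   series.
#' @param methods Character vector among `"sampen"`, `"fuzzyen"`, `"disten"`.
#' @param m Embedding dimensions to evaluate.
#' @inheritParams fuzzy_entropy
#' @param n_bins ePDF bin count for DistEn.
#' @return A data frame with columns `series_label`, `method`, `m`, `delay`,
#'   `r_used`, `value`, `defined`.
#' @export
entropy_table <- function(series, methods = c("sampen", "fuzzyen", "disten"),
                          m = 2L, r = 0.2, n = 2, n_bins = 512L, delay = 1L,
                          fuzzy_form = "scaled") {
  if (is.numeric(series)) series <- list(series)
  if (is.null(names(series)))
    names(series) <- sprintf("series_%03d", seq_along(series))
  rows <- list()
  for (lab in names(series)) for (mm in m) for (meth in methods) {
    est <- estimate_entropy(series[[lab]], meth, m = mm, r = r, n = n,
                            n_bins = n_bins, delay = delay,
                            fuzzy_form = fuzzy_form, label = lab)
    rows[[length(rows) + 1L]] <- data.frame(
      series_label = lab, method = meth, m = as.integer(mm),
      delay = as.integer(delay), r_used = est$r_used,
      value = if (est$defined) est$value else NA_real_,
      defined = est$defined)
  }
  do.call(rbind, rows)
}
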