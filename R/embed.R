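#' Delay embedding of a series into template vectors
#'
#' Builds the template vectors used by all three entropy estimators: vector
#' \eqn{i} (1-based) is \eqn{[x_i, x_{i+\tau}, \ldots, x_{i+(m-1)\tau}]} with
#' delay \eqn{\tau}.  The number of vectors is \eqn{N - m\tau} for *both* the
#' dimension-\eqn{m} and dimension-\eqn{m+1} embeddings used by
#' [sample_entropy()] and [fuzzy_entropy()], so that the two match counts run
#' over equally many vectors and their normalisations cancel
#' (Richman--Moorman convention).
#'
#' @param x Numeric series.
#' @param m Embedding dimension (positive integer).
#' @param delay Delay between consecutive template-vector coordinates
#'   (positive integer); equals the scale \eqn{\tau} in multiscale use.
#' @param n_vectors Number of template vectors to build.  Defaults to
#'   `length(x) - m * delay`; [sample_entropy()] passes this explicitly so the
#'   \eqn{m+1} embedding keeps the dimension-\eqn{m} count.
#' @return A numeric matrix with one template vector per row.
#' @examples
#' embed_delay(c(1, 2, 3, 4), m = 2, delay = 1)     # rows (1,2) and (2,3)
#' embed_delay(c(1, 2, 3, 4, 5, 6), m = 2, delay = 2)
#' @export
embed_delay <- function(x, m, delay = 1L, n_vectors = NULL) {
  check_series(x, min_len = 2)
  m <- as.integer(m); delay <- as.integer(delay)
  if (m < 1L || delay < 1L)
    stop("'m' and 'delay' must be positive integers")
  N <- length(x)
  if (is.null(n_vectors)) n_vectors <- N - m * delay
  n_vectors <- as.integer(n_vectors)
  if (n_vectors < 2L)
    stop("series too short for m = ", m, ", delay = ", delay,
         ": need at least N = ", m * delay + 2L, " samples, got ", N)
  if ((n_vectors - 1L) + (m - 1L) * delay + 1L > N)
    stop("cannot build ", n_vectors, " template vectors of dimension ", m,
         " with delay ", delay, " from ", N, " samples")
  idx <- outer(seq_len(n_vectors), (seq_len(m) - 1L) * delay, "+")
  matrix(x[idx], nrow = n_vectors, ncol = m)
}

#' Pairwise Chebyshev distances between template vectors
#'
#' Infinity-norm (maximum coordinate difference) distance for every unordered
#' pair of template vectors (\eqn{j \ge i + 1}; self-pairs excluded).
#'
#' @param tvs A template-vector matrix from [embed_delay()], or a numeric
#'   series (delay-embedded with `m`, `delay` first).
#' @param m,delay Embedding parameters, used when `tvs` is a plain series.
#' @param n_vectors Optional vector-count override (see [embed_delay()]).
#' @return Numeric vector of the \eqn{n(n-1)/2} pairwise distances, ordered
#'   pair-wise: (1,2), (1,3), ..., (1,n), (2,3), ...
#' @examples
#' chebyshev_pairs(rbind(c(1, 2), c(2, 3), c(5, 5)))  # 1, 4, 3
#' @export
chebyshev_pairs <- function(tvs, m = 2L, delay = 1L, n_vectors = NULL) {
  if (is.matrix(tvs)) {
    n <- nrow(tvs)
    if (n < 2L) stop("need at least 2 template vectors")
    D <- matrix(0, n, n)
    for (k in seq_len(ncol(tvs)))
      D <- pmax(D, abs(outer(tvs[, k], tvs[, k], "-")))
    # column-major extraction below the diagonal of a symmetric matrix yields
    # exactly the (1,2), (1,3), ..., (2,3), ... pair order
    return(D[lower.tri(D)])
  }
  check_series(tvs, min_len = 2)
  m <- as.integer(m); delay <- as.integer(delay)
  if (is.null(n_vectors)) n_vectors <- length(tvs) - m * delay
  n_vectors <- as.integer(n_vectors)
  if (n_vectors < 2L)
    stop("series too short for m = ", m, ", delay = ", delay,
         ": need at least N = ", m * delay + 2L, " samples, got ", length(tvs))
  cheb_pairdist_cpp(as.numeric(tvs), m, delay, n_vectors)
}

#' Empirical probability distribution of pairwise distances (ePDF)
#'
#' Histogram of template-vector distances over `n_bins` equispaced bins
#' spanning the observed range, as relative frequencies.  Bins are
#' left-closed; the rightmost edge is inclusive so the maximum distance is
#' counted.  When all distances coincide the whole mass falls in one bin.
#'
#' @param d Numeric vector of pairwise distances (non-empty).
#' @param n_bins Number of bins \eqn{M} (default 512).
#' @return A data frame of class `"epdf"` with columns `bin_left`,
#'   `bin_right`, `probability`.
#' @examples
#' empirical_pdf(c(0, 0, 1, 1), n_bins = 2)  # 0.5 / 0.5
#' @export
empirical_pdf <- function(d, n_bins = 512L) {
  if (length(d) < 1L) stop("empty distance set")
  if (!all(is.finite(d)) || any(d < 0)) stop("distances must be finite and >= 0")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("'n_bins' must be at least 2")
  lo <- min(d); hi <- max(d)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  if (hi == lo) {
    p <- c(1, rep(0, n_bins - 1L))
  } else {
    w <- (hi - lo) / n_bins
    idx <- pmin(floor((d - lo) / w) + 1L, n_bins)  # clamp: right edge inclusive
    p <- tabulate(idx, nbins = n_bins) / length(d)
  }
  out <- data.frame(bin_left = edges[-(n_bins + 1L)],
                    bin_right = edges[-1L],
                    probability = p)
  class(out) <- c("epdf", "data.frame")
  out
}

# Shannon entropy (bits) of a probability vector, with 0 * log 0 = 0
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}
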