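#include <Rcpp.h>
using namespace Rcpp;

// Pairwise Chebyshev (infinity-norm) distances among delay-embedded template
// vectors.  Vector i (0-based) has coordinates x[i + k*delay], k = 0..m-1.
// n_vec is passed explicitly so that the m and m+1 embeddings can be computed
// over the same set of starting indices (equal-count convention).
// Returns the n_vec*(n_vec-1)/2 distances for all unordered pairs i < j.
// [[Rcpp::export]]
NumericVector cheb_pairdist_cpp(NumericVector x, int m, int delay, int n_vec) {
  const int n = x.size();
  if (m < 1 || delay < 1)
    stop("m and delay must be positive integers");
  if (n_vec < 2)
    stop("need at least 2 template vectors");
  if ((n_vec - 1) + (m - 1) * delay >= n)
    stop("series too short for the requested embedding");
  const R_xlen_t n_pairs = (R_xlen_t)n_vec * (n_vec - 1) / 2;
  NumericVector out(n_pairs);
  R_xlen_t idx = 0;
  for (int i = 0; i < n_vec - 1; ++i) {
    for (int j = i + 1; j < n_vec; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double diff = x[i + k * delay] - x[j + k * delay];
        if (diff < 0) diff = -diff;
        if (diff > d) d = diff;
      }
      out[idx++] = d;
    }
  }
  return out;
}

// Count of unordered template pairs with Chebyshev distance strictly below r,
// without materialising the distances (used by the Sample Entropy hot path).
// [[Rcpp::export]]
double cheb_paircount_lt_cpp(NumericVector x, int m, int delay, int n_vec,
                             double r) {
  const int n = x.size();
  if ((n_vec - 1) + (m - 1) * delay >= n)
    stop("series too short for the requested embedding");
  double count = 0.0;
  for (int i = 0; i < n_vec - 1; ++i) {
    for (int j = i + 1; j < n_vec; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double diff = x[i + k * delay] - x[j + k * delay];
        if (diff < 0) diff = -diff;
        if (diff > d) d = diff;
        if (d >= r) break;
      }
      if (d < r) count += 1.0;
    }
  }
  return count;
}

// Mean fuzzy membership over unordered template pairs.
// form = 0: exp(-(d/r)^n)  (scale-invariant, package default)
// form = 1: exp(-d^n / r)  (Chen et al. printed form)
// [[Rcpp::export]]
double fuzzy_meansim_cpp(NumericVector x, int m, int delay, int n_vec,
                         double r, double nexp, int form) {
  const int n = x.size();
  if ((n_vec - 1) + (m - 1) * delay >= n)
    stop("series too short for the requested embedding");
  long double acc = 0.0;
  for (int i = 0; i < n_vec - 1; ++i) {
    for (int j = i + 1; j < n_vec; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double diff = x[i + k * delay] - x[j + k * delay];
        if (diff < 0) diff = -diff;
        if (diff > d) d = diff;
      }
      double u = (form == 0) ? std::pow(d / r, nexp) : std::pow(d, nexp) / r;
      acc += std::exp(-u);
    }
  }
  const R_xlen_t n_pairs = (R_xlen_t)n_vec * (n_vec - 1) / 2;
  return (double)(acc / n_pairs);
}
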