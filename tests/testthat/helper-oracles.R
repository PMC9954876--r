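# Independent naive reference implementations used as oracles.  These follow
# the definitions directly (explicit double loops, no shared code with the
# package internals) and are deliberately slow.

oracle_pop_sd <- function(x) sqrt(sum((x - mean(x))^2) / length(x))

# all pairwise Chebyshev distances among delay-embedded vectors, double loop
oracle_pairdist <- function(x, m, delay = 1, n_vec = length(x) - m * delay) {
  vecs <- lapply(seq_len(n_vec), function(i)
    x[i + (seq_len(m) - 1) * delay])
  d <- numeric(0)
  for (i in seq_len(n_vec - 1))
    for (j in (i + 1):n_vec)
      d <- c(d, max(abs(vecs[[i]] - vecs[[j]])))
  d
}

# shared distance computation for the three estimator oracles (the estimators
# themselves remain independent of the package's code path)
oracle_distpair <- function(x, m, delay = 1) {
  n_vec <- length(x) - m * delay
  list(dm = oracle_pairdist(x, m, delay, n_vec),
       dm1 = oracle_pairdist(x, m + 1, delay, n_vec),
       n_vec = n_vec)
}

oracle_sampen <- function(x, m = 2, r = 0.2, delay = 1, dp = NULL) {
  if (is.null(dp)) dp <- oracle_distpair(x, m, delay)
  ru <- r * oracle_pop_sd(x)
  a <- sum(dp$dm < ru); b <- sum(dp$dm1 < ru)
  if (a == 0 || b == 0) return(NA_real_)
  -log(b / a)
}

oracle_fuzzyen <- function(x, m = 2, r = 0.2, n = 2, delay = 1,
                           form = c("scaled", "chen"), dp = NULL) {
  form <- match.arg(form)
  if (is.null(dp)) dp <- oracle_distpair(x, m, delay)
  ru <- r * oracle_pop_sd(x)
  memb <- function(d) if (form == "scaled") exp(-(d / ru)^n) else exp(-d^n / ru)
  log(mean(memb(dp$dm))) - log(mean(memb(dp$dm1)))
}

oracle_disten <- function(x, m = 2, M = 512, delay = 1, dp = NULL) {
  d <- if (is.null(dp)) oracle_pairdist(x, m, delay) else dp$dm
  lo <- min(d); hi <- max(d)
  if (hi == lo) return(0)
  # independent binning: graphics::hist with left-closed breaks
  cnt <- hist(d, breaks = seq(lo, hi, length.out = M + 1),
              right = FALSE, include.lowest = TRUE, plot = FALSE)$counts
  p <- cnt / sum(cnt); p <- p[p > 0]
  -sum(p * log2(p)) / log2(M)
}

# exact signed-rank p by full enumeration of all 2^n sign assignments
oracle_signedrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 14)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.numeric(signs %*% rk)
  p <- if (W > mu) 2 * mean(Ws >= W) else 2 * mean(Ws <= W)
  min(1, p)
}

# exact rank-sum p by enumeration of all group-A rank assignments
oracle_ranksum_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  rk <- rank(c(a, b))
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  splits <- utils::combn(na + nb, na)
  Us <- apply(splits, 2, function(idx) sum(rk[idx])) - na * (na + 1) / 2
  p <- if (U > mu) 2 * mean(Us >= U) else 2 * mean(Us <= U)
  min(1, p)
}

# log-log periodogram slope over a frequency band (for noise-colour checks)
periodogram_slope <- function(x, band = c(0.01, 0.4)) {
  n <- length(x)
  P <- Mod(fft(x - mean(x)))^2 / n
  f <- (seq_len(n) - 1) / n
  keep <- f > band[1] & f < band[2]
  coef(lm(log10(P[keep]) ~ log10(f[keep])))[[2]]
}

# period-4 comb contrast of a profile sequence: mean of the linearly
# detrended values off multiples of 4 minus the mean at multiples of 4
period4_contrast <- function(tau, value) {
  y <- resid(lm(value ~ tau))
  mean(y[tau %% 4 != 0]) - mean(y[tau %% 4 == 0])
}

# DFT amplitude of a detrended profile sequence at a given period
profile_amplitude <- function(tau, value, period) {
  y <- resid(lm(value ~ tau))
  Mod(sum(y * exp(-2i * pi * tau / period))) * 2 / length(y)
}
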