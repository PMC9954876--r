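# run expr with a temporarily seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

standardize <- function(x) (x - mean(x)) / pop_sd(x)

#' Gaussian white, pink and Brown noise generators
#'
#' White noise is i.i.d. standard Gaussian.  Pink (1/f) noise is synthesised
#' in the frequency domain: a Gaussian white spectrum is shaped by a
#' \eqn{1/\sqrt{f}} amplitude profile (zero DC), inverse-transformed and
#' standardised to zero mean and unit SD, giving a power spectrum with
#' log-log slope \eqn{-1}.  Brown noise is the cumulative sum of Gaussian
#' white noise (a random walk; log-log spectral slope \eqn{-2}, variance
#' growing linearly with time).
#'
#' @param kind `"white"`, `"pink"` or `"brown"`.
#' @param n Number of samples (at least 64).
#' @param seed Integer seed; the output is reproducible bit-for-bit.
#' @return A numeric series of length `n`.
#' @examples
#' x <- gen_noise("pink", 512, seed = 1)
#' @export
gen_noise <- function(kind = c("white", "pink", "brown"), n = 512L,
                      seed = NULL) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (n < 64L) stop("'n' must be at least 64")
  with_seed(seed, switch(kind,
    white = rnorm(n),
    brown = cumsum(rnorm(n)),
    pink = {
      spec <- fft(rnorm(n))
      f <- c(0, pmin(seq_len(n - 1L), n - seq_len(n - 1L))) / n
      shape <- c(0, 1 / sqrt(f[-1L]))
      standardize(Re(fft(spec * shape, inverse = TRUE)) / n)
    }))
}

#' Logistic-map series (chaotic and periodic regimes)
#'
#' Iterates \eqn{x_{k+1} = \omega x_k (1 - x_k)}.  The initial condition is
#' drawn uniformly in \eqn{(0.1, 0.9)} from `seed` unless supplied, and
#' `transient` iterations are discarded before recording, which guarantees
#' the \eqn{\omega = 3.5} orbit has settled on its period-4 attractor.
#' \eqn{\omega = 4} gives fully developed chaos.
#'
#' @param omega Map parameter in \eqn{(0, 4]}; 4 = chaotic, 3.5 = periodic.
#' @param n Number of recorded samples.
#' @param seed Integer seed for the initial condition.
#' @param transient Iterations discarded before recording (default 1000).
#' @param x0 Optional explicit initial condition in \eqn{(0, 1)}.
#' @return A numeric series of length `n`.
#' @examples
#' gen_logistic(4, 3, x0 = 0.2, transient = 0)  # 0.2, 0.64, 0.9216
#' @export
gen_logistic <- function(omega, n = 512L, seed = NULL, transient = 1000L,
                         x0 = NULL) {
  if (omega <= 0 || omega > 4) stop("'omega' must lie in (0, 4]")
  n <- as.integer(n); transient <- as.integer(transient)
  if (transient < 0L) stop("'transient' must be non-negative")
  if (is.null(x0)) x0 <- with_seed(seed, runif(1, 0.1, 0.9))
  if (x0 <= 0 || x0 >= 1) stop("'x0' must lie strictly inside (0, 1)")
  x <- x0
  for (i in seq_len(transient)) x <- omega * x * (1 - x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- x
    x <- omega * x * (1 - x)
  }
  out
}

#' Benchmark bank of synthetic series
#'
#' Generates `n_series` independent series per process: Gaussian white, pink
#' and Brown noise, and chaotic (\eqn{\omega = 4}) and periodic
#' (\eqn{\omega = 3.5}) logistic-map series.  Per-series seeds are derived as
#' `seed + index` over the whole bank, so the bank is reproducible and any
#' subset can be regenerated.
#'
#' @param n_series Series per process (default 30).
#' @param n_samples Samples per series (default 512).
#' @param seed Base integer seed.
#' @param processes Subset of
#'   `c("white", "pink", "brown", "chaotic", "periodic")`.
#' @return A named list of numeric series; names are `process_index` labels.
#'   The manifest (label, process, seed) is attached as attribute
#'   `"manifest"`.
#' @export
gen_bank <- function(n_series = 30L, n_samples = 512L, seed = 1L,
                     processes = c("white", "pink", "brown",
                                   "chaotic", "periodic")) {
  processes <- match.arg(processes, several.ok = TRUE)
  out <- list()
  manifest <- list()
  k <- 0L
  for (proc in processes) for (i in seq_len(n_series)) {
    k <- k + 1L
    s <- seed + k
    lab <- sprintf("%s_%02d", proc, i)
    out[[lab]] <- switch(proc,
      white = , pink = , brown = gen_noise(proc, n_samples, seed = s),
      chaotic = gen_logistic(4, n_samples, seed = s),
      periodic = gen_logistic(3.5, n_samples, seed = s))
    manifest[[k]] <- data.frame(label = lab, process = proc, seed = s)
  }
  attr(out, "manifest") <- do.call(rbind, manifest)
  out
}

#' Synthetic RR-interval series with posture and group presets
#'
#' A stand-in for restricted clinical recordings, *not* a physiological
#' model: it reproduces the directional structure that the entropy analysis
#' assumes.  The series is a standardised mixture
#' \deqn{RRI = \mu + \sigma \,[\sqrt{1-f}\, v + \sqrt{f}\, s]}
#' of a fast "vagal" component \eqn{v} (white noise, white/chaotic mixture
#' for the SCI preset) and a slow correlated "sympathetic" component \eqn{s}
#' (standardised \eqn{\sqrt{0.7}\,\mathrm{pink} + \sqrt{0.3}\,\mathrm{Brown}}).
#' Sitting raises the correlated variance fraction \eqn{f} (sympathetic
#' predominance), lowering SampEn/FuzzyEn; the SCI preset replaces a fraction
#' `chaos_frac` of the vagal variance with a standardised chaotic
#' logistic-map series, flattening the distance ePDF and raising DistEn while
#' the total SD (and hence all second-order amplitude statistics) stays
#' exactly `sd_rri` for every preset.
#'
#' @param group `"AB"` (able-bodied) or `"SCI"` (spinal-cord-injured preset).
#' @param posture `"supine"` or `"sitting"`.
#' @param n Number of beats (at least 128; default 512).
#' @param seed Integer seed.
#' @param mean_rri Mean RR interval in ms; defaults 950 (supine) / 860
#'   (sitting).
#' @param sd_rri SD of the series in ms (default 40; exact by construction).
#' @param f_corr Variance fraction of the correlated component; defaults 0.30
#'   (supine) / 0.60 (sitting).
#' @param chaos_frac Fraction of vagal variance replaced by the chaotic
#'   component; defaults 0 (AB) / 0.70 (SCI).
#' @return A numeric RR-interval series (ms), all values positive.
#' @examples
#' x <- gen_synthetic_rri("AB", "supine", seed = 1)
#' @export
gen_synthetic_rri <- function(group = c("AB", "SCI"),
                              posture = c("supine", "sitting"),
                              n = 512L, seed = NULL,
                              mean_rri = NULL, sd_rri = 40,
                              f_corr = NULL, chaos_frac = NULL) {
  group <- match.arg(group)
  posture <- match.arg(posture)
  n <- as.integer(n)
  if (n < 128L) stop("'n' must be at least 128")
  if (is.null(mean_rri)) mean_rri <- if (posture == "supine") 950 else 860
  if (is.null(f_corr))   f_corr   <- if (posture == "supine") 0.30 else 0.60
  if (is.null(chaos_frac)) chaos_frac <- if (group == "AB") 0 else 0.70
  if (f_corr < 0 || f_corr > 1 || chaos_frac < 0 || chaos_frac > 1)
    stop("'f_corr' and 'chaos_frac' must lie in [0, 1]")
  if (sd_rri <= 0 || sd_rri >= mean_rri / 4)
    stop("'sd_rri' must be positive and below mean_rri / 4")
  with_seed(seed, {
    w <- rnorm(n)
    s <- standardize(sqrt(0.7) * gen_noise("pink", n) +
                     sqrt(0.3) * standardize(cumsum(rnorm(n))))
    v <- if (chaos_frac > 0) {
      ch <- standardize(gen_logistic(4, n))
      standardize(sqrt(1 - chaos_frac) * w + sqrt(chaos_frac) * ch)
    } else w
    x <- mean_rri + sd_rri * standardize(sqrt(1 - f_corr) * v +
                                         sqrt(f_corr) * s)
    stopifnot(all(x > 0))
    x
  })
}

#' Synthetic cohort of subject-posture RR-interval recordings
#'
#' Builds a cohort of [gen_synthetic_rri()] recordings with the study's
#' structure: two groups (AB, SCI), each subject recorded in supine and
#' sitting postures.  Optionally some SCI supine recordings are dropped to
#' mimic missing data.
#'
#' @param n_ab,n_sci Subjects per group (defaults 20 and 20).
#' @param n Beats per recording (default 512).
#' @param seed Base integer seed; each recording uses `seed + k` for its
#'   running index `k`.
#' @param missing_supine_sci Number of SCI subjects whose supine recording is
#'   missing (default 0).
#' @param ... Passed on to [gen_synthetic_rri()] (e.g. preset overrides).
#' @return A data frame with columns `subject_id`, `group`, `posture` and a
#'   list column `series`.
#' @export
gen_cohort <- function(n_ab = 20L, n_sci = 20L, n = 512L, seed = 1L,
                       missing_supine_sci = 0L, ...) {
  rows <- list()
  series <- list()
  k <- 0L
  for (g in c("AB", "SCI")) {
    n_g <- if (g == "AB") n_ab else n_sci
    for (i in seq_len(n_g)) {
      id <- sprintf("%s%02d", g, i)
      for (pos in c("supine", "sitting")) {
        if (g == "SCI" && pos == "supine" && i <= missing_supine_sci) next
        k <- k + 1L
        rows[[k]] <- data.frame(subject_id = id, group = g, posture = pos)
        series[[k]] <- gen_synthetic_rri(g, pos, n = n, seed = seed + k, ...)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$series <- series
  out
}
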