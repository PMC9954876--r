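#' Wilcoxon signed-rank test (paired), exact under ties
#'
#' Two-sided signed-rank test on a vector of paired differences.  Zero
#' differences are dropped.  For `n <= exact_max` non-zero differences the
#' null distribution of the statistic is enumerated exactly by convolution
#' over the (possibly tied, midranked) ranks — unlike the classical exact
#' tables this remains exact in the presence of ties; above that, a normal
#' approximation with tie correction (and continuity correction) is used.
#'
#' @param diffs Numeric vector of paired differences.
#' @param exact_max Largest n for exact enumeration (default 25).
#' @param correct Continuity correction in the normal approximation.
#' @return A list with `p_value`, `statistic` (W, sum of positive ranks),
#'   `n` (non-zero differences), `n_zero`, `exact`, and `defined` (`FALSE`
#'   with a `reason` when all differences are zero).
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p_value   # 2/32
#' wilcoxon_signed_rank(c(-2, -1, 1, 2))$p_value    # 1
#' @export
wilcoxon_signed_rank <- function(diffs, exact_max = 25L, correct = TRUE) {
  if (!is.numeric(diffs) || length(diffs) < 1L)
    stop("'diffs' must be a non-empty numeric vector")
  n_zero <- sum(diffs == 0)
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0L)
    return(list(p_value = NA_real_, statistic = NA_real_, n = 0L,
                n_zero = n_zero, exact = NA, defined = FALSE,
                reason = "all differences zero"))
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= exact_max) {
    # exact null distribution of 2W by convolution over doubled ranks
    w2 <- round(2 * rk)
    f <- 1
    for (wi in w2) f <- c(f, numeric(wi)) + c(numeric(wi), f)
    tot <- 2^n
    W2 <- round(2 * W)
    p_le <- sum(f[seq_len(W2 + 1L)]) / tot
    p_ge <- sum(f[(W2 + 1L):length(f)]) / tot
    p <- if (W > mu) 2 * p_ge else 2 * p_le
    p <- min(1, p)
    exact <- TRUE
  } else {
    ties <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- W - mu
    if (correct) z <- z - sign(z) * 0.5
    z <- z / sqrt(sigma2)
    p <- 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))
    p <- min(1, p)
    exact <- FALSE
  }
  list(p_value = p, statistic = W, n = n, n_zero = n_zero, exact = exact,
       defined = TRUE, reason = NA_character_)
}

#' Wilcoxon rank-sum (Mann-Whitney) test, two groups
#'
#' Two-sided rank-sum test.  The exact null distribution (via the
#' Mann-Whitney U count distribution) is used when the smaller group has at
#' most `exact_max` observations and there are no ties; otherwise a normal
#' approximation with tie correction (and continuity correction).
#'
#' @param group_a,group_b Numeric vectors (both non-empty).
#' @param exact_max Largest min-group size for the exact branch (default 10).
#' @param correct Continuity correction in the normal approximation.
#' @return A list with `p_value`, `statistic` (U for `group_a`), `n_a`,
#'   `n_b`, `exact`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value  # 2/6
#' @export
wilcoxon_rank_sum <- function(group_a, group_b, exact_max = 10L,
                              correct = TRUE) {
  if (length(group_a) < 1L || length(group_b) < 1L)
    stop("both groups must be non-empty")
  na <- length(group_a); nb <- length(group_b)
  pooled <- c(group_a, group_b)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  has_ties <- anyDuplicated(pooled) > 0L
  if (min(na, nb) <= exact_max && !has_ties) {
    p <- if (U > mu) 2 * pwilcox(U - 1, na, nb, lower.tail = FALSE)
         else 2 * pwilcox(U, na, nb)
    p <- min(1, p)
    exact <- TRUE
  } else {
    Nn <- na + nb
    ties <- table(rk)
    sigma2 <- (na * nb / 12) *
      ((Nn + 1) - sum(ties^3 - ties) / (Nn * (Nn - 1)))
    z <- U - mu
    if (correct) z <- z - sign(z) * 0.5
    z <- z / sqrt(sigma2)
    p <- 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))
    p <- min(1, p)
    exact <- FALSE
  }
  list(p_value = p, statistic = U, n_a = na, n_b = nb, exact = exact)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1); a thin, validated
#' front-end to [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values)) stop("'p_values' must be numeric")
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Scale-wise nonparametric posture and group comparisons
#'
#' Computes the chosen entropy estimator (optionally across scales) for every
#' recording of a cohort and tests, at each scale: supine versus sitting
#' within each group (paired signed-rank over subjects with both postures)
#' and AB versus SCI within each posture (rank-sum).  The scale-1 contrasts
#' are a-posteriori comparisons and are FDR-adjusted together
#' (Benjamini-Hochberg); contrasts at scales \eqn{\tau \ge 2} each test
#' their own null hypothesis and are reported unadjusted.  Undefined entropy
#' estimates are excluded listwise per contrast, with the exclusion count
#' reported.
#'
#' @param records A cohort data frame as from [gen_cohort()]: columns
#'   `subject_id`, `group`, `posture`, list column `series`.
#' @inheritParams multiscale_entropy
#' @param min_cell Minimum usable recordings per contrast cell (default 5).
#' @return An object of class `"cohort_comparison"`: list with `contrasts`
#'   (data frame: `contrast`, `stratum`, `method`, `m`, `tau`, `n`,
#'   `statistic`, `p_raw`, `p_adjusted`, `n_excluded`) and `estimates` (long
#'   data frame: `subject_id`, `group`, `posture`, `method`, `m`, `tau`,
#'   `value`, `defined` — the input table for external mixed-model fits).
#' @export
compare_cohort <- function(records, method = c("sampen", "fuzzyen", "disten"),
                           m = 2L, r = 0.2, n = 2, n_bins = 512L,
                           scales = 1L, filter = c("butterworth", "ma"),
                           order = 6L, rescale_r = TRUE,
                           fuzzy_form = c("scaled", "chen"), min_cell = 5L) {
  method <- match.arg(method)
  filter <- match.arg(filter)
  fuzzy_form <- match.arg(fuzzy_form)
  scales <- as.integer(scales)
  stopifnot(is.data.frame(records),
            all(c("subject_id", "group", "posture", "series") %in%
                names(records)))
  est_rows <- list()
  for (i in seq_len(nrow(records))) {
    x <- records$series[[i]]
    prof <- multiscale_entropy(x, method, m = m, r = r, n = n,
                               n_bins = n_bins, scales = scales,
                               filter = filter, order = order,
                               rescale_r = rescale_r,
                               fuzzy_form = fuzzy_form)
    est_rows[[i]] <- data.frame(
      subject_id = records$subject_id[i], group = records$group[i],
      posture = records$posture[i], method = method, m = as.integer(m),
      tau = prof$table$tau, value = prof$table$value,
      defined = prof$table$defined)
  }
  est <- do.call(rbind, est_rows)
  out <- list()
  for (tau in scales) {
    et <- est[est$tau == tau, ]
    for (g in unique(et$group)) {
      sub <- et[et$group == g, ]
      wide <- merge(sub[sub$posture == "supine",
                        c("subject_id", "value", "defined")],
                    sub[sub$posture == "sitting",
                        c("subject_id", "value", "defined")],
                    by = "subject_id", suffixes = c("_sup", "_sit"))
      usable <- wide$defined_sup & wide$defined_sit
      n_exc <- sum(!usable)
      wide <- wide[usable, ]
      if (nrow(wide) < min_cell)
        stop("fewer than ", min_cell, " usable paired subjects in group ", g)
      ts <- wilcoxon_signed_rank(wide$value_sup - wide$value_sit)
      out[[length(out) + 1L]] <- data.frame(
        contrast = "posture_within_group", stratum = g, method = method,
        m = as.integer(m), tau = tau, n = ts$n,
        statistic = ts$statistic, p_raw = ts$p_value, n_excluded = n_exc)
    }
    for (pos in unique(et$posture)) {
      sub <- et[et$posture == pos, ]
      a <- sub[sub$group == "AB", ]
      b <- sub[sub$group == "SCI", ]
      n_exc <- sum(!a$defined) + sum(!b$defined)
      av <- a$value[a$defined]; bv <- b$value[b$defined]
      if (length(av) < min_cell || length(bv) < min_cell)
        stop("fewer than ", min_cell, " usable recordings in posture ", pos)
      tr <- wilcoxon_rank_sum(av, bv)
      out[[length(out) + 1L]] <- data.frame(
        contrast = "group_within_posture", stratum = pos, method = method,
        m = as.integer(m), tau = tau, n = tr$n_a + tr$n_b,
        statistic = tr$statistic, p_raw = tr$p_value, n_excluded = n_exc)
    }
  }
  contrasts <- do.call(rbind, out)
  contrasts$p_adjusted <- NA_real_
  at1 <- contrasts$tau == 1L
  if (any(at1)) contrasts$p_adjusted[at1] <- bh_fdr(contrasts$p_raw[at1])
  structure(list(contrasts = contrasts, estimates = est, method = method,
                 m = as.integer(m)),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("Cohort comparison -", x$method, "(m =", x$m, ")\n")
  cat(" recordings:", nrow(unique(x$estimates[c("subject_id", "posture")])),
      "; undefined estimates:", sum(!x$estimates$defined), "\n\n")
  df <- x$contrasts
  df$p_raw <- signif(df$p_raw, 3)
  df$p_adjusted <- signif(df$p_adjusted, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Long-format entropy table for a cohort
#'
#' Evaluates several estimators/dimensions at scale 1 for every recording;
#' the tidy table (one row per recording, method and m) is the input a
#' linear mixed-effects model expects in an external stats package.
#'
#' @inheritParams compare_cohort
#' @param methods Estimators to tabulate.
#' @param m Embedding dimensions to tabulate.
#' @return Data frame: `subject_id`, `group`, `posture`, `method`, `m`,
#'   `tau`, `value`, `defined`.
#' @export
cohort_estimates <- function(records,
                             methods = c("sampen", "fuzzyen", "disten"),
                             m = c(1L, 2L), r = 0.2, n = 2, n_bins = 512L) {
  rows <- list()
  for (i in seq_len(nrow(records))) for (mm in m) for (meth in methods) {
    e <- estimate_entropy(records$series[[i]], meth, m = mm, r = r, n = n,
                          n_bins = n_bins)
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = records$subject_id[i], group = records$group[i],
      posture = records$posture[i], method = meth, m = as.integer(mm),
      tau = 1L, value = as.double(e), defined = e$defined)
  }
  do.call(rbind, rows)
}
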