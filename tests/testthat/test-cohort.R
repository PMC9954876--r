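test_that("signed-rank test reproduces hand enumerations", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p_value, 2 / 32)
  expect_equal(wilcoxon_signed_rank(c(-2, -1, 1, 2))$p_value, 1)
  r <- wilcoxon_signed_rank(c(0, 0, 0))
  expect_false(r$defined)
  expect_true(is.na(r$p_value))
  expect_equal(r$n_zero, 3)
})

test_that("signed-rank exact branch matches full 2^n enumeration with ties", {
  set.seed(21)
  for (rep in 1:20) {
    d <- sample(c(-4:-1, 1:4), 9, replace = TRUE)  # heavy ties
    expect_equal(wilcoxon_signed_rank(d)$p_value, oracle_signedrank_p(d),
                 tolerance = 1e-12)
  }
})

test_that("signed-rank test matches the reference implementation", {
  set.seed(22)
  # exact branch, no ties
  for (rep in 1:10) {
    d <- rnorm(sample(6:20, 1))
    expect_equal(wilcoxon_signed_rank(d)$p_value,
                 wilcox.test(d)$p.value, tolerance = 1e-10)
  }
  # normal-approximation branch (n > 25), ties present
  for (rep in 1:10) {
    d <- round(rnorm(40), 1)
    d <- d[d != 0]
    expect_equal(wilcoxon_signed_rank(d)$p_value,
                 suppressWarnings(wilcox.test(d, exact = FALSE)$p.value),
                 tolerance = 1e-10)
  }
})

test_that("rank-sum test reproduces hand enumerations and the reference", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value, 2 / 6)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  set.seed(23)
  for (rep in 1:10) {  # exact branch vs combinatorial enumeration
    a <- rnorm(sample(3:6, 1)); b <- rnorm(sample(3:6, 1))
    expect_equal(wilcoxon_rank_sum(a, b)$p_value, oracle_ranksum_p(a, b),
                 tolerance = 1e-12)
    expect_equal(wilcoxon_rank_sum(a, b)$p_value,
                 wilcox.test(a, b)$p.value, tolerance = 1e-10)
  }
  for (rep in 1:10) {  # approximate branch with ties
    a <- round(rnorm(15), 1); b <- round(rnorm(18), 1)
    expect_equal(wilcoxon_rank_sum(a, b)$p_value,
                 suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value),
                 tolerance = 1e-10)
  }
})

test_that("both tests hold their nominal size under the null", {
  set.seed(24)
  # exact discrete null distributions reject at most at the nominal rate;
  # the observed rate must sit near 5% without exceeding it beyond MC error
  p_sr <- replicate(1000, wilcoxon_signed_rank(rnorm(15))$p_value)
  expect_lt(mean(p_sr < 0.05), 0.07)
  expect_gt(mean(p_sr < 0.05), 0.02)
  p_rs <- replicate(1000, wilcoxon_rank_sum(rnorm(12), rnorm(12))$p_value)
  expect_lt(mean(p_rs < 0.05), 0.07)
  expect_gt(mean(p_rs < 0.05), 0.02)
})

test_that("BH adjustment follows the step-up rule and never decreases p", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.5), 0.5)
  set.seed(25)
  for (rep in 1:10) {
    p <- runif(sample(3:12, 1))
    adj <- bh_fdr(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    expect_true(!is.unsorted(adj[order(p)]))
    expect_equal(adj, p.adjust(p, "BH"))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("compare_cohort applies the pairing and adjustment rules", {
  co <- gen_cohort(n_ab = 8, n_sci = 8, n = 256, seed = 31,
                   missing_supine_sci = 2)
  cc <- compare_cohort(co, "sampen", scales = 1L)
  tab <- cc$contrasts
  # paired contrast counts only complete subjects
  expect_equal(tab$n[tab$contrast == "posture_within_group" &
                     tab$stratum == "SCI"], 6)
  # group contrast in sitting keeps all SCI subjects
  expect_equal(tab$n[tab$contrast == "group_within_posture" &
                     tab$stratum == "sitting"], 16)
  expect_equal(tab$n[tab$contrast == "group_within_posture" &
                     tab$stratum == "supine"], 14)
  # scale-1 contrasts carry a BH adjustment that never lowers p
  expect_true(all(tab$p_adjusted >= tab$p_raw - 1e-15))
  # the long-format export covers every recording
  expect_equal(nrow(cc$estimates), nrow(co))
  expect_error(compare_cohort(gen_cohort(n_ab = 3, n_sci = 3, n = 256,
                                         seed = 1)),
               "fewer than")
})

test_that("multiscale contrasts are unadjusted at tau >= 2", {
  co <- gen_cohort(n_ab = 6, n_sci = 6, n = 256, seed = 33)
  cc <- compare_cohort(co, "disten", scales = c(1L, 2L))
  tab <- cc$contrasts
  expect_true(all(is.na(tab$p_adjusted[tab$tau == 2])))
  expect_true(all(!is.na(tab$p_adjusted[tab$tau == 1])))
})

test_that("posture separation by SampEn is reliably detected at defaults", {
  set.seed(35)
  hits <- replicate(20, {
    seed <- sample.int(1e6, 1)
    sup <- sapply(1:20, function(i)
      as.double(sample_entropy(gen_synthetic_rri("AB", "supine",
                                                 seed = seed + i))))
    sit <- sapply(1:20, function(i)
      as.double(sample_entropy(gen_synthetic_rri("AB", "sitting",
                                                 seed = seed + 1000 + i))))
    wilcoxon_signed_rank(sup - sit)$p_value <= 0.05
  })
  expect_gte(mean(hits), 0.8)
})
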