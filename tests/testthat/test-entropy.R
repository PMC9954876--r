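test_that("constant series give zero entropy for all three estimators", {
  x <- rep(5, 64)
  expect_equal(as.double(sample_entropy(x)), 0)
  expect_equal(as.double(fuzzy_entropy(x)), 0)
  expect_equal(as.double(distribution_entropy(x)), 0)
})

test_that("estimators agree with naive double-loop oracles to 1e-12", {
  set.seed(101)
  for (rep in 1:50) {
    x <- rnorm(128)
    dp <- oracle_distpair(x, 2)
    expect_equal(as.double(sample_entropy(x, m = 2)),
                 oracle_sampen(x, m = 2, dp = dp), tolerance = 1e-12)
    expect_equal(as.double(fuzzy_entropy(x, m = 2)),
                 oracle_fuzzyen(x, m = 2, dp = dp), tolerance = 1e-12)
    expect_equal(as.double(distribution_entropy(x, m = 2)),
                 oracle_disten(x, m = 2, dp = dp), tolerance = 1e-12)
  }
})

test_that("a 512-sample white-noise series matches the oracles at m = 2", {
  set.seed(512)
  x <- rnorm(512)
  dp <- oracle_distpair(x, 2)
  expect_equal(as.double(sample_entropy(x)), oracle_sampen(x, dp = dp),
               tolerance = 1e-12)
  expect_equal(as.double(fuzzy_entropy(x)), oracle_fuzzyen(x, dp = dp),
               tolerance = 1e-12)
})

test_that("the alternating series reproduces its exact pair enumeration", {
  x <- rep(c(0, 1), 32)
  est <- sample_entropy(x, m = 1)
  expect_equal(as.double(est), oracle_sampen(x, m = 1), tolerance = 1e-12)
  expect_lt(as.double(est), 0.05)  # near zero: parity matches persist
})

test_that("fuzzy membership families follow their definitions", {
  set.seed(11)
  x <- rnorm(200)
  expect_equal(as.double(fuzzy_entropy(x, fuzzy_form = "chen")),
               oracle_fuzzyen(x, form = "chen"), tolerance = 1e-12)
  # the two families genuinely differ
  expect_false(isTRUE(all.equal(as.double(fuzzy_entropy(x)),
                                as.double(fuzzy_entropy(x, fuzzy_form = "chen")))))
})

test_that("SampEn/FuzzyEn (scaled form) and DistEn are affine invariant", {
  set.seed(202)
  for (rep in 1:5) {
    x <- rnorm(256)
    for (ab in list(c(3.7, 100), c(-2.4, -8))) {
      y <- ab[1] * x + ab[2]
      expect_equal(as.double(sample_entropy(y)), as.double(sample_entropy(x)),
                   tolerance = 1e-10)
      expect_equal(as.double(fuzzy_entropy(y)), as.double(fuzzy_entropy(x)),
                   tolerance = 1e-10)
      expect_equal(as.double(distribution_entropy(y)),
                   as.double(distribution_entropy(x)), tolerance = 1e-12)
    }
  }
})

test_that("estimates respect their theoretical bounds", {
  set.seed(303)
  gens <- list(function() rnorm(150),
               function() cumsum(rnorm(150)),
               function() gen_logistic(4, 150, seed = sample.int(1e6, 1)),
               function() runif(150))
  for (g in gens) for (rep in 1:5) {
    x <- g()
    se <- sample_entropy(x)
    if (se$defined) expect_gte(se$value, 0)
    expect_gte(as.double(fuzzy_entropy(x)), 0)
    de <- as.double(distribution_entropy(x))
    expect_gte(de, 0); expect_lte(de, 1)
  }
})

test_that("a distance set with two equally frequent values gives DistEn 1/9", {
  # 36 zeros and 28 ones among the 64 scalar template vectors:
  # C(36,2) + C(28,2) = 36*28 = 1008, so distances 0 and 1 are equally
  # frequent and the 512-bin ePDF has exactly two occupied bins
  x <- c(rep(0, 36), rep(1, 29))
  d <- chebyshev_pairs(x, m = 1)
  expect_equal(sum(d == 0), sum(d == 1))
  expect_equal(as.double(distribution_entropy(x, m = 1)), 1 / log2(512),
               tolerance = 1e-12)
})

test_that("zero-match SampEn is flagged undefined, not a sentinel number", {
  # equal values never share an equal successor: matches exist at m = 1
  # but none survive at m = 2
  x <- as.numeric(rbind(1, c(10, 20, 30, 40, 50, 60, 70, 80)))
  est <- sample_entropy(x, m = 1)
  expect_false(est$defined)
  expect_true(is.na(as.double(est)))
  expect_match(est$reason, "m\\+1")
  expect_gt(est$n_pairs_m, 0)
  expect_equal(est$n_pairs_m1, 0)
})

test_that("entropy_table tabulates labels, parameters and undefined flags", {
  series <- list(a = rnorm(100), b = rep(1, 100))
  tab <- entropy_table(series, m = c(1, 2))
  expect_equal(nrow(tab), 2 * 2 * 3)
  expect_named(tab, c("series_label", "method", "m", "delay", "r_used",
                      "value", "defined"))
  expect_true(all(tab$value[tab$series_label == "b"] == 0))
})
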