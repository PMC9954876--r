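test_that("generators are reproducible from their seed", {
  expect_identical(gen_noise("pink", 256, seed = 5),
                   gen_noise("pink", 256, seed = 5))
  expect_false(identical(gen_noise("white", 256, seed = 5),
                         gen_noise("white", 256, seed = 6)))
  expect_identical(gen_logistic(4, 100, seed = 3), gen_logistic(4, 100, seed = 3))
  b1 <- gen_bank(n_series = 2, n_samples = 64, seed = 9)
  b2 <- gen_bank(n_series = 2, n_samples = 64, seed = 9)
  expect_identical(b1, b2)
  expect_false(identical(b1[[1]],
                         gen_bank(n_series = 2, n_samples = 64, seed = 10)[[1]]))
  # the generators restore the caller's RNG stream
  set.seed(1); r1 <- rnorm(1)
  set.seed(1); invisible(gen_noise("white", 64, seed = 99)); r2 <- rnorm(1)
  expect_identical(r1, r2)
})

test_that("noise colours have the expected spectral slopes", {
  expect_lt(abs(cor(gen_noise("white", 4096, seed = 2)[-1],
                    gen_noise("white", 4096, seed = 2)[-4096])),
            2 / sqrt(4096))
  expect_equal(periodogram_slope(gen_noise("pink", 4096, seed = 3)), -1,
               tolerance = 0.2)
  expect_equal(periodogram_slope(gen_noise("brown", 4096, seed = 4)), -2,
               tolerance = 0.15)
})

test_that("brown-noise variance grows linearly with time", {
  set.seed(44)
  xs <- replicate(400, gen_noise("brown", 512, seed = sample.int(1e6, 1)))
  v <- apply(xs, 1, var)  # across replicates, per time index
  fit <- lm(v ~ seq_len(512))
  expect_lt(abs(coef(fit)[[2]] - 1), 0.3)
  expect_gt(summary(fit)$r.squared, 0.95)
})

test_that("the logistic map follows its recursion and regimes", {
  expect_equal(gen_logistic(4, 3, x0 = 0.2, transient = 0),
               c(0.2, 0.64, 0.9216))
  # omega = 3.5: period-4 attractor after the transient
  x <- gen_logistic(3.5, 100, seed = 7)
  expect_lt(max(abs(x[1:96] - x[5:100])), 1e-6)
  expect_gt(min(abs(x[1:4] - x[2:5])), 1e-3)  # genuinely 4 distinct values
  # omega = 4: no period up to 16 anywhere in the record
  y <- gen_logistic(4, 200, seed = 8)
  for (p in 1:16)
    expect_gt(max(abs(y[1:(200 - p)] - y[(1 + p):200])), 1e-6)
  expect_error(gen_logistic(4, 10, x0 = 1), "inside")
  expect_error(gen_logistic(5, 10, seed = 1), "omega")
})

test_that("the benchmark bank has the study's shape", {
  bank <- gen_bank(n_series = 3, n_samples = 128, seed = 1)
  expect_length(bank, 15)
  expect_true(all(lengths(bank) == 128))
  man <- attr(bank, "manifest")
  expect_equal(nrow(man), 15)
  expect_setequal(unique(man$process),
                  c("white", "pink", "brown", "chaotic", "periodic"))
})

test_that("synthetic RRI series have the requested first two moments", {
  x <- gen_synthetic_rri("AB", "supine", seed = 3, mean_rri = 900)
  expect_equal(mean(x), 900, tolerance = 1e-9)  # exact by construction
  expect_equal(sqrt(mean((x - mean(x))^2)), 40, tolerance = 1e-9)
  expect_true(all(x > 0))
  expect_identical(x, gen_synthetic_rri("AB", "supine", seed = 3,
                                        mean_rri = 900))
})

test_that("AB and SCI presets are SD-matched while postures shift the mix", {
  sds <- sapply(1:20, function(i) c(
    sqrt(mean((gen_synthetic_rri("AB", "supine", seed = i) - 950)^2)),
    sqrt(mean((gen_synthetic_rri("SCI", "supine", seed = 100 + i) - 950)^2))))
  expect_lt(max(abs(sds[1, ] / sds[2, ] - 1)), 0.05)
})

test_that("preset contrasts point in the published directions", {
  sup <- sapply(1:20, function(i)
    as.double(sample_entropy(gen_synthetic_rri("AB", "supine", seed = i))))
  sit <- sapply(1:20, function(i)
    as.double(sample_entropy(gen_synthetic_rri("AB", "sitting", seed = 200 + i))))
  expect_gt(mean(sup), mean(sit))  # SampEn lower in sitting
  ab <- sapply(1:20, function(i)
    as.double(distribution_entropy(gen_synthetic_rri("AB", "supine", seed = i))))
  sci <- sapply(1:20, function(i)
    as.double(distribution_entropy(gen_synthetic_rri("SCI", "supine",
                                                     seed = 400 + i))))
  expect_gt(mean(sci), mean(ab))  # DistEn higher in SCI
})

test_that("gen_cohort assembles subject-posture records", {
  co <- gen_cohort(n_ab = 3, n_sci = 4, n = 128, seed = 2,
                   missing_supine_sci = 2)
  expect_equal(sum(co$group == "AB"), 6)
  expect_equal(sum(co$group == "SCI" & co$posture == "supine"), 2)
  expect_equal(sum(co$group == "SCI" & co$posture == "sitting"), 4)
  expect_true(all(lengths(co$series) == 128))
  expect_equal(anyDuplicated(co[c("subject_id", "posture")]), 0)
})
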