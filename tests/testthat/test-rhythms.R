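test_that("RPKM normalization with median-1 trimmed scale factors", {
  counts <- cbind(s1 = c(100, 50, 200), s2 = c(100, 50, 200),
    s3 = c(100, 50, 200))
  rpkm <- normalize_counts(counts, feature_lengths = c(1000, 500, 2000),
    library_sizes = rep(1e7, 3))
  # count 100, 1 kb, library 1e7, scale 1 -> RPKM 10
  expect_equal(unname(rpkm[1, 1]), 10)
  expect_equal(unname(attr(rpkm, "scale_factors")), rep(1, 3))

  # one sample with all counts doubled -> its scale factor 2
  base <- matrix(rep(c(20, 50, 80, 120, 200, 35), 150), 300, 3)
  m <- cbind(base, base[, 1] * 2)
  sf <- attr(normalize_counts(m, rep(1000, 300), rep(1e6, 4)), "scale_factors")
  expect_equal(unname(sf), c(1, 1, 1, 2), tolerance = 1e-6)
  expect_equal(median(sf), 1)

  expect_error(normalize_counts(counts, c(0, 500, 2000), rep(1e7, 3)), "lengths")
  expect_error(normalize_counts(counts, c(1000, 500, 2000), c(0, 1, 1)), "library")
})

test_that("cosinor fit recovers noiseless parameters exactly", {
  t <- seq(0, 44, by = 4)
  fit <- harmonic_fit(t, 2 + cos(2 * pi * t / 24))
  expect_equal(fit$mean, 2, tolerance = 1e-12)
  expect_equal(fit$relamp, 0.5, tolerance = 1e-12)
  expect_equal(fit$phase, 0, tolerance = 1e-10)
  expect_lt(fit$pvalue, 1e-12)

  flat <- harmonic_fit(t, rep(3, 12))
  expect_equal(flat$relamp, 0)
  expect_equal(flat$pvalue, 1)

  expect_error(harmonic_fit(c(0, 6, 12), 1:3), "4 time points")
  expect_error(harmonic_fit(rep(c(0, 12), 6), rnorm(12)), "rank-deficient")
})

test_that("cosinor phase and relamp transform correctly and recover under noise", {
  t <- seq(0, 44, by = 4)
  set.seed(3)
  y <- 5 + 2 * cos(2 * pi * (t - 8) / 24) + rnorm(12, 0, 0.1)
  f1 <- harmonic_fit(t, y)
  f2 <- harmonic_fit(t, 7 * y)          # positive scaling
  expect_equal(f1$relamp, f2$relamp)
  expect_equal(f1$phase, f2$phase)
  f3 <- harmonic_fit(t + 3, y)          # time shift moves the phase
  expect_equal((f3$phase - f1$phase) %% 24, 3, tolerance = 1e-8)

  # phase recovery: 200 replicates, planted phase 8
  reps <- vapply(1:200, function(i) {
    harmonic_fit(t, 5 + 2 * cos(2 * pi * (t - 8) / 24) + rnorm(12, 0, 0.1))$phase
  }, numeric(1))
  err <- circular_phase_diff(reps, 8)
  expect_lt(max(abs(err)), 0.3)

  # matrix form agrees with the vector form
  Y <- rbind(a = y, b = 7 * y)
  tab <- harmonic_fit(t, Y)
  expect_equal(unname(tab$relamp[1]), f1$relamp, ignore_attr = TRUE)
  expect_equal(unname(tab$phase[2]), f2$phase, ignore_attr = TRUE)
  expect_equal(tab$unit, c("a", "b"))
})

test_that("BH adjustment matches the hand step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(4)
  p <- runif(40)
  expect_equal(bh_adjust(p), bh_oracle(p))
})

test_that("transcript classification follows the organism thresholds", {
  fits <- tibble::tibble(
    mean = c(0.005, 1.0, 1.0, 1.0, 0.05),
    relamp = c(0, 0.25, 0.05, 0.01, 0.3),
    pvalue = c(0.9, 0.001, 0.002, 0.8, 0.01)
  )
  # supply bh_p directly to pin the examples
  out <- classify_transcripts(fits, "mouse",
    bh_p = c(0.9, 0.10, 0.19, 0.9, 0.05))
  expect_equal(as.character(out$rhythm_label),
    c("silent",      # mean 0.005 < 0.01
      "circadian",   # expressed, bh 0.1 < 0.2, relamp 0.25 > 0.1
      "other",       # amplitude gate: relamp 0.05
      "constitutive",# raw p 0.8 >= 0.5
      "other"))      # 0.01 <= mean <= 0.1: not expressed, not silent

  # fly: no amplitude gate, bh < 0.25, expressed > 1
  fly <- classify_transcripts(
    tibble::tibble(mean = c(2, 2, 0.5), relamp = c(0.05, 0.05, 0.5),
      pvalue = c(0.001, 0.6, 0.001)),
    "fly", bh_p = c(0.24, 0.8, 0.1))
  expect_equal(as.character(fly$rhythm_label),
    c("circadian", "constitutive", "other"))

  # partition property
  set.seed(6)
  rf <- tibble::tibble(mean = rlnorm(300, 0, 3), relamp = runif(300, 0, 0.6),
    pvalue = runif(300))
  lab <- classify_transcripts(rf, "mouse")$rhythm_label
  expect_false(anyNA(lab))
  expect_equal(sum(table(lab)), 300)
})

test_that("rhythm F test holds its nominal type-I error", {
  set.seed(12)
  t <- seq(0, 44, by = 4)
  Y <- matrix(rnorm(10000 * 12, mean = 5), ncol = 12)
  p <- harmonic_fit(t, Y)$pvalue
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
})

test_that("quantile flags use the type-7 upper quantile", {
  v <- 1:100
  fl <- quantile_flag(v, 0.75)
  expect_equal(v[fl], 76:100)  # type-7 q75 of 1..100 is 75.25
  expect_true(all(quantile_flag(rep(2, 5))))
  expect_true(quantile_flag(3.7))
})
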