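test_that("sub-sample-and-smoothen preserves constants and matches the oracle", {
  expect_equal(subsample_smooth(rep(5, 32), 32), rep(5, 32))
  expect_equal(subsample_smooth(rep(2.5, 96), 32), rep(2.5, 32))
  ramp <- seq(0, 1, length.out = 96)
  expect_equal(subsample_smooth(ramp, 32), oracle_subsample(ramp, 32),
               tolerance = 1e-12)
  set.seed(9)
  for (n in c(33, 64, 97, 200)) {
    v <- rnorm(n)
    expect_equal(subsample_smooth(v, 32), oracle_subsample(v, 32),
                 tolerance = 1e-12)
  }
  expect_error(subsample_smooth(rnorm(10), 32), "pad")
})

test_that("zero padding appends trailing zeros only", {
  expect_equal(pad_to_length(1:20, 32), c(1:20, rep(0, 12)))
  expect_equal(pad_to_length(1:32, 32), 1:32)
  expect_equal(pad_to_length(numeric(0), 32), rep(0, 32))
  expect_error(pad_to_length(1:40, 32), "longer")
})

test_that("stretch features are 16 FFT magnitudes plus window min and max", {
  z <- numeric(32)
  expect_equal(stretch_features(z, z), numeric(18))
  cst <- stretch_features(rep(2, 32), rep(2, 32))
  expect_equal(cst[1], 64 * 2)          # DC bin of the 64-point FFT
  expect_equal(cst[2:16], numeric(15))  # no other energy in a constant
  expect_equal(cst[17:18], c(2, 2))
  # a sinusoid's dominant non-DC bin must match the brute-force DFT
  tt <- seq(0, 63) / 25
  x <- sin(2 * pi * 2 * tt)             # 2 Hz at 25 Hz sampling
  got <- stretch_features(x[33:64], x[1:32])
  ref <- oracle_dft_mod(x)
  expect_equal(got[1:16], ref[1:16], tolerance = 1e-8)
  expect_equal(which.max(got[2:16]), which.max(ref[2:16]))
  expect_error(stretch_features(numeric(31)), "32")
})

test_that("body acceleration subtracts unit gravity from the magnitude", {
  expect_equal(body_accel(0, 0, 1), 0)
  expect_equal(body_accel(0, 0, 0), -1)
  set.seed(3)
  a <- rnorm(50); b <- rnorm(50); c <- rnorm(50)
  expect_equal(body_accel(a, b, c), sqrt(a^2 + b^2 + c^2) - 1)
  expect_error(body_accel(1:3, 1:2, 1:3), "equal length")
})

test_that("Haar A1 coefficients match the filter-bank oracle and conserve energy", {
  expect_equal(haar_a1(rep(3, 64)), rep(3 * sqrt(2), 32))
  expect_equal(haar_a1(rep(c(1, -1), 32)), numeric(32))
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(64)
    a1 <- haar_a1(x)
    expect_equal(a1, oracle_haar_a1(x), tolerance = 1e-12)
    # low-pass branch can never exceed the signal energy
    expect_lte(sum(a1^2), sum(x^2) + 1e-12)
  }
  # equality holds exactly when the detail branch vanishes
  smooth <- rep(rnorm(32), each = 2)
  expect_equal(sum(haar_a1(smooth)^2), sum(smooth^2), tolerance = 1e-12)
  expect_error(haar_a1(rnorm(63)), "64")
})

test_that("accelerometer features concatenate to 101 values in fixed order", {
  z <- numeric(64)
  f <- accel_features(z, z, z)
  expect_length(f, 101)
  expect_equal(f[1:64], numeric(64))           # A1 of the two zero channels
  expect_equal(f[65:96], rep(-sqrt(2), 32))    # A1 of constant bacc = -1
  expect_equal(f[97:100], numeric(4))          # four zero variances
  expect_equal(f[101], -1)                     # mean bacc of a zero signal
  set.seed(5)
  ax <- rnorm(64); ay <- rnorm(64); az <- rnorm(64)
  f2 <- accel_features(ax, ay, az)
  bacc <- sqrt(ax^2 + ay^2 + az^2) - 1
  # variance block against a two-pass oracle
  twopass <- function(v) sum((v - sum(v) / length(v))^2) / (length(v) - 1)
  expect_equal(f2[97:100], vapply(list(ax, ay, az, bacc), twopass, numeric(1)),
               tolerance = 1e-12)
  # ay is never wavelet-transformed: its A1 block must not appear
  expect_equal(f2[1:32], haar_a1(ax))
  expect_equal(f2[33:64], haar_a1(az))
  expect_equal(f2[65:96], haar_a1(bacc))
  expect_error(accel_features(rnorm(63), ay, az), "64")
})

test_that("feature vectors always have 120 entries in the documented layout", {
  seg <- make_test_segment(1)
  fv <- build_feature_vector(seg)
  expect_length(fv, 120)
  expect_true(all(is.finite(fv)))
  expect_equal(attr(fv, "label"), "walk")
  expect_equal(fv[120], seg$duration)
  # first segment of a stream: previous window is zeros, no error
  fv2 <- build_feature_vector(seg, previous = NULL)
  expect_length(fv2, 120)
  # deterministic: identical segments give bit-identical vectors
  expect_identical(build_feature_vector(seg), build_feature_vector(seg))
  # a static 3 s segment carries its duration as the last feature
  p <- har_profile(noise_sd_stretch = 0, noise_sd_accel = 0)
  rec <- generate_recording(har_script("stand", duration = 9), p, seed = 1)
  segs <- segment_recording(rec)
  fv3 <- build_feature_vector(segs[[1]])
  expect_equal(fv3[120], 3.0, tolerance = 1 / 25)
  empty <- seg
  empty$stretch <- empty$stretch[0, ]
  expect_error(build_feature_vector(empty), "empty")
})

test_that("the normalizer standardizes training columns to mean 0 and sd 1", {
  set.seed(21)
  x <- matrix(rnorm(50 * 7, mean = 3, sd = 2), 50, 7)
  nrm <- fit_normalizer(x)
  z <- apply_normalizer(x, nrm)
  expect_equal(colMeans(z), numeric(7), tolerance = 1e-9)
  expect_equal(apply(z, 2, sd), rep(1, 7), tolerance = 1e-9)
  # held-out vectors transform by the stored statistics
  v <- rnorm(7)
  expect_equal(apply_normalizer(v, nrm), (v - nrm$center) / nrm$scale)
  # constant columns pass through unscaled, with a warning
  x[, 3] <- 42
  expect_warning(nrm2 <- fit_normalizer(x), "constant")
  expect_equal(nrm2$scale[3], 1)
  expect_error(fit_normalizer(x[1, , drop = FALSE]), "at least 2")
})
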