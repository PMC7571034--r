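test_that("moving-average smoothing is exact against direct summation", {
  tt <- seq(0, 2, by = 0.04)
  expect_equal(smooth_stretch(sample_series(tt, tt * 2), 1)$value, tt * 2)
  expect_equal(smooth_stretch(sample_series(tt, rep(3, length(tt))), 7)$value,
               rep(3, length(tt)))
  set.seed(2)
  for (width in c(3L, 5L, 9L)) {
    v <- cumsum(rnorm(60))
    got <- smooth_stretch(sample_series(seq_along(v), v), width)$value
    expect_equal(got, oracle_moving_average(v, width), tolerance = 1e-12)
  }
  expect_error(smooth_stretch(sample_series(tt, tt), 4), "odd")
})

test_that("static streams split into 3-second windows exactly", {
  p <- har_profile(noise_sd_stretch = 0, noise_sd_accel = 0)
  rec <- generate_recording(har_script("stand", duration = 9), p, seed = 1)
  expect_equal(find_boundaries(rec$stretch), c(3, 6, 9))
  segs <- segment_recording(rec)
  expect_length(segs, 3)
  expect_true(all(vapply(segs, `[[`, character(1), "label") == "stand"))
})

test_that("a monotone ramp yields exactly one segment covering the ramp", {
  # flat - ramp - flat, noiseless: the only derivative sign change pair
  # should bracket the ramp
  dt <- 0.04
  tt <- seq(0, 8 - dt, by = dt)
  v <- c(rep(1, 100), seq(1, 2, length.out = 25), rep(2, 75))
  b <- find_boundaries(sample_series(tt, v), har_segparams())
  # boundaries at the ramp start (4 s) and settle point (~5 s), placed
  # within half a smoothing window of the true corners, plus the static
  # splits elsewhere
  expect_true(any(abs(b - 4.0) <= 6 * dt))
  expect_true(any(abs(b - 5.0) <= 6 * dt))
  ramp <- b[b > 3.5 & b < 5.5]
  expect_length(ramp, 2)
})

test_that("step segments are recovered from synthetic walks", {
  p <- har_profile(step_frequency = 1.5, rng_seed = 3)
  rec <- generate_recording(make_protocol_script(3), p, seed = 42)
  segs <- segment_recording(rec)
  labs <- vapply(segs, `[[`, character(1), "label")
  expect_gte(sum(labs == "walk"), 39)
  expect_lte(sum(labs == "walk"), 41)
})

test_that("an experiment-1 recording labels as stand runs around three jumps", {
  p <- har_profile(noise_sd_stretch = 0, noise_sd_accel = 0)
  rec <- generate_recording(make_protocol_script(1), p, seed = 1)
  labs <- vapply(segment_recording(rec), `[[`, character(1), "label")
  expect_equal(rle(labs)$values, c("stand", "jump", "stand"))
  expect_equal(sum(labs == "jump"), 3)
})

test_that("segments tile the recording without overlap and respect bounds", {
  params <- har_segparams()
  for (seed in 1:5) {
    p <- har_profile(step_frequency = 1 + 0.25 * seed, rng_seed = seed)
    rec <- generate_recording(make_protocol_script(4), p, seed = seed)
    segs <- segment_recording(rec, params)
    starts <- vapply(segs, `[[`, numeric(1), "start")
    ends <- vapply(segs, `[[`, numeric(1), "end")
    dt <- 1 / 25
    # contiguous, non-overlapping coverage of the span
    expect_equal(starts[-1], ends[-length(ends)])
    expect_equal(starts[1], rec$stretch$time[1])
    expect_equal(ends[length(ends)], max(rec$stretch$time) + dt,
                 tolerance = dt)
    # duration bounds with one-sample slack
    expect_true(all(ends - starts >= params$min_segment - dt - 1e-9))
    expect_true(all(ends - starts <= params$static_window + dt + 1e-9))
    # every sample lands in exactly one segment
    n_samples <- sum(vapply(segs, function(s) nrow(s$stretch), integer(1)))
    expect_equal(n_samples, nrow(rec$stretch))
  }
})

test_that("an all-constant labeled stream labels every segment identically", {
  p <- har_profile(noise_sd_stretch = 0, noise_sd_accel = 0)
  rec <- generate_recording(har_script("sit", duration = 12), p, seed = 1)
  labs <- vapply(segment_recording(rec), `[[`, character(1), "label")
  expect_true(all(labs == "sit"))
})

test_that("degenerate inputs are rejected or warned about", {
  expect_error(har_segparams(min_segment = 0), "min_segment")
  expect_error(har_segparams(min_segment = 5, static_window = 3),
               "min_segment")
  short <- sample_series(c(0, 0.04), c(1, 1))
  expect_warning(b <- find_boundaries(short), "short")
  expect_length(b, 0)
  p <- har_profile()
  rec <- generate_recording(har_script("stand", duration = 5), p)
  rec$stretch_to_accel <- NULL
  expect_error(segment_recording(rec), "align")
})
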