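test_that("recordings parse from CSV, sort by time, and flag missing columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(time = c(0.08, 0, 0.04), stretch = c(3, 1, 2),
                   ax = c(0.3, 0.1, 0.2), ay = 0, az = 1)
  write.csv(df, path, row.names = FALSE)
  rec <- read_recording(path)
  expect_s3_class(rec, "har_recording")
  expect_equal(nrow(rec$stretch), 3)
  expect_equal(rec$stretch$value, c(1, 2, 3))   # sorted by time
  expect_equal(rec$accel$ax, c(0.1, 0.2, 0.3))

  # shuffled rows give the same recording
  write.csv(df[c(2, 1, 3), ], path, row.names = FALSE)
  expect_equal(read_recording(path, user_id = "u")$stretch$value, c(1, 2, 3))

  # a missing mandatory channel is named in the error
  write.csv(df[, setdiff(names(df), "ax")], path, row.names = FALSE)
  expect_error(read_recording(path), "ax")
  expect_error(read_recording("no/such/file.csv"), "not found")
})

test_that("column maps adapt foreign layouts and reject unknown channels", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(t_ms = c(0, 40, 80), flex = c(1, 2, 3),
                   accx = 0.1, accy = 0, accz = 1)
  write.csv(df, path, row.names = FALSE)
  cm <- har_colmap(time = "t_ms", stretch = "flex", ax = "accx",
                   ay = "accy", az = "accz", time_scale = 1e-3)
  rec <- read_recording(path, cm)
  expect_equal(rec$stretch$time, c(0, 0.04, 0.08))
  expect_error(har_colmap(bogus = "x"), "unknown channel")
})

test_that("stream alignment matches exhaustive nearest-timestamp search", {
  set.seed(4)
  for (offset in c(0, 0.5, -0.31)) {
    ts <- sort(runif(40, 0, 10))
    ta <- sort(runif(300, 0, 10))
    stretch <- sample_series(ts, rnorm(40))
    accel <- data.frame(time = ta, ax = rnorm(300), ay = rnorm(300),
                        az = rnorm(300))
    rec <- align_streams(stretch, accel, offset = offset)
    # brute force: for every retained stretch time, scan all accel times
    expected <- vapply(rec$stretch$time, function(tq) {
      d <- abs(rec$accel$time - tq)
      which(d == min(d))[1]   # tie toward the earlier sample
    }, integer(1))
    expect_equal(rec$stretch_to_accel, expected)
  }
  # identical grids with zero offset associate one-to-one
  g <- seq(0, 1, by = 0.1)
  acc <- data.frame(time = g, ax = 0, ay = 0, az = 1)
  rec <- align_streams(sample_series(g, g), acc, offset = 0)
  expect_equal(rec$stretch_to_accel, seq_along(g))
  # disjoint spans cannot be aligned
  far <- data.frame(time = g + 100, ax = 0, ay = 0, az = 1)
  expect_error(align_streams(sample_series(g, g), far, 0), "common time span")
})

test_that("recordings, segments and features round-trip through CSV", {
  p <- har_profile(rng_seed = 8)
  rec <- generate_recording(make_protocol_script(1), p)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  rec2 <- read_recording(path, user_id = rec$user_id)
  expect_equal(rec2$stretch$value, rec$stretch$value)
  expect_equal(rec2$accel$az, rec$accel$az)
  expect_equal(rec2$labels, rec$labels)

  segs <- segment_recording(rec)[1:3]
  spath <- withr::local_tempfile(fileext = ".csv")
  write_segments(segs, spath)
  segs2 <- read_segments(spath)
  expect_length(segs2, 3)
  for (i in 1:3) {
    expect_equal(segs2[[i]]$stretch$value, segs[[i]]$stretch$value)
    expect_equal(segs2[[i]]$accel$ax, segs[[i]]$accel$ax)
    expect_equal(segs2[[i]]$label, segs[[i]]$label)
    expect_equal(segs2[[i]]$start, segs[[i]]$start)
  }
  expect_error(write_segments(list(), spath), "no segments")

  feats <- har_featurize(segment_recording(rec), user_id = "u1")
  fpath <- withr::local_tempfile(fileext = ".csv")
  write_features(feats, fpath)
  feats2 <- read_features(fpath)
  expect_equal(as.matrix(feats2[, 1:120]), as.matrix(feats[, 1:120]),
               tolerance = 1e-12)
  expect_equal(feats2$label, feats$label)
  expect_error(write_features(feats[0, ], fpath), "no feature")
})

test_that("configuration files carry sampling rates and column maps", {
  cfg <- har_config()
  expect_equal(cfg$fs_stretch, 25)
  expect_equal(cfg$fs_accel, 250)
  expect_equal(cfg$gravity, 1)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("fs_stretch: 50", "colmap:", "  stretch: Flex"), path)
  cfg2 <- har_config(path)
  expect_equal(cfg2$fs_stretch, 50)
  expect_equal(cfg2$fs_accel, 250)
  expect_equal(cfg2$colmap$map$stretch, "Flex")
})
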