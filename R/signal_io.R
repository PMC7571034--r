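#' Activity label set
#'
#' The eight activity classes recognised by the framework, in the canonical
#' class order used by the classifier output layer: jump, lie down, sit,
#' stand, walk, stairs up, stairs down, transition.
#'
#' @return Character vector of the 8 canonical activity tags.
#' @export
har_activities <- function() {
  c("jump", "lie_down", "sit", "stand", "walk",
    "stairs_up", "stairs_down", "transition")
}

#' Construct a single-channel sample series
#'
#' A sample series is the basic container for one sensor channel: a vector of
#' wall-clock timestamps (seconds) and one value per timestamp.
#'
#' @param time Numeric vector of timestamps in seconds, sorted ascending.
#' @param value Numeric vector of samples, same length as `time`.
#' @return An object of class `"sample_series"`: a data frame with columns
#'   `time` and `value`.
#' @export
sample_series <- function(time, value) {
  if (length(time) != length(value))
    stop_validation("`time` and `value` must have equal length (%d vs %d)",
                    length(time), length(value))
  if (length(time) && is.unsorted(time))
    stop_validation("timestamps must be sorted ascending")
  structure(data.frame(time = as.numeric(time), value = as.numeric(value)),
            class = c("sample_series", "data.frame"))
}

#' Construct a sensor recording
#'
#' A recording bundles the stretch-sensor stream (nominal 25 Hz), the 3-axis
#' accelerometer stream in units of g (nominal 250 Hz), optional gyroscope
#' channels (deg/s; carried but never featurised) and optional per-sample
#' activity labels on the stretch timeline.
#'
#' @param user_id Character scalar identifying the wearer.
#' @param stretch A [sample_series()] for the stretch channel.
#' @param accel Data frame with columns `time`, `ax`, `ay`, `az` (units of g).
#' @param gyro Optional data frame with columns `time`, `gx`, `gy`, `gz`.
#' @param labels Optional character vector, one activity tag per stretch
#'   sample, drawn from [har_activities()].
#' @param stretch_to_accel Optional integer vector mapping each stretch sample
#'   to its nearest-in-time accelerometer row (filled in by
#'   [align_streams()]).
#' @return An object of class `"har_recording"`.
#' @export
har_recording <- function(user_id, stretch, accel, gyro = NULL, labels = NULL,
                          stretch_to_accel = NULL) {
  if (!inherits(stretch, "sample_series"))
    stretch <- sample_series(stretch$time, stretch$value)
  for (col in c("time", "ax", "ay", "az"))
    if (is.null(accel[[col]]))
      stop_validation("accel is missing column `%s`", col)
  if (is.unsorted(accel$time))
    stop_validation("accel timestamps must be sorted ascending")
  if (!is.null(labels)) {
    if (length(labels) != nrow(stretch))
      stop_validation("labels must have one tag per stretch sample")
    bad <- setdiff(unique(labels), har_activities())
    if (length(bad))
      stop_validation("unknown activity tag(s): %s", paste(bad, collapse = ", "))
  }
  structure(list(user_id = as.character(user_id), stretch = stretch,
                 accel = accel, gyro = gyro, labels = labels,
                 stretch_to_accel = stretch_to_accel),
            class = "har_recording")
}

#' @export
print.har_recording <- function(x, ...) {
  span <- if (nrow(x$stretch)) diff(range(x$stretch$time)) else 0
  cat(sprintf("<har_recording> user %s: %.1f s, %d stretch / %d accel samples%s\n",
              x$user_id, span, nrow(x$stretch), nrow(x$accel),
              if (is.null(x$labels)) "" else ", labeled"))
  invisible(x)
}

#' Column mapping for external CSV layouts
#'
#' Maps the canonical channel names (`time`, `stretch`, `ax`, `ay`, `az`,
#' optionally `gx`, `gy`, `gz`, `label`) to the column names used by a source
#' file, so externally released data can be read without hard-coding its
#' layout. A channel mapped to `NA` is explicitly absent.
#'
#' @param ... Named mappings, e.g. `stretch = "Stretch_Value"`. Unnamed
#'   channels default to their canonical names.
#' @param time_scale Multiplier converting the file's time unit to seconds
#'   (e.g. `1e-3` for milliseconds).
#' @return An object of class `"har_colmap"`.
#' @export
har_colmap <- function(..., time_scale = 1) {
  canon <- c("time", "stretch", "ax", "ay", "az", "gx", "gy", "gz", "label")
  user <- list(...)
  bad <- setdiff(names(user), canon)
  if (length(bad))
    stop_validation("unknown channel(s) in column map: %s",
                    paste(bad, collapse = ", "))
  m <- stats::setNames(as.list(canon), canon)
  m[names(user)] <- user
  structure(list(map = m, time_scale = time_scale), class = "har_colmap")
}

#' Read a recording from CSV
#'
#' Reads a comma-separated file with a header row where each row carries a
#' timestamp plus any subset of the mapped channels (missing entries `NA`).
#' Stretch and accelerometer streams may share one timeline or interleave two
#' sampling rates; a channel's series is formed from the rows where it is
#' non-missing. Rows are sorted by time on input.
#'
#' @param path Path to the CSV file.
#' @param colmap A [har_colmap()]; defaults to canonical column names.
#' @param user_id User identifier to attach; defaults to the file name.
#' @return A [har_recording()].
#' @export
read_recording <- function(path, colmap = har_colmap(), user_id = NULL) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- colmap$map
  getcol <- function(ch, required = FALSE) {
    nm <- m[[ch]]
    if (is.null(nm) || is.na(nm)) {
      if (required) stop_validation("column map marks mandatory channel `%s` absent", ch)
      return(NULL)
    }
    if (!nm %in% names(df)) {
      if (required || ch %in% c("time", "stretch", "ax", "ay", "az"))
        stop_validation("missing mandatory column `%s` (mapped from `%s`)", nm, ch)
      return(NULL)
    }
    df[[nm]]
  }
  tm <- getcol("time", required = TRUE)
  if (!is.numeric(tm)) stop_validation("time column must be numeric")
  nonmono <- which(is.na(tm))
  if (length(nonmono))
    stop_validation("missing timestamp at row %d", nonmono[1])
  tm <- tm * colmap$time_scale
  ord <- order(tm)
  tm <- tm[ord]

  stretch_v <- getcol("stretch", required = TRUE)[ord]
  keep_s <- !is.na(stretch_v)
  stretch <- sample_series(tm[keep_s], stretch_v[keep_s])

  acc <- lapply(c("ax", "ay", "az"), function(ch) getcol(ch, required = TRUE)[ord])
  keep_a <- !is.na(acc[[1]])
  accel <- data.frame(time = tm[keep_a], ax = acc[[1]][keep_a],
                      ay = acc[[2]][keep_a], az = acc[[3]][keep_a])

  gyr <- lapply(c("gx", "gy", "gz"), getcol)
  gyro <- NULL
  if (!any(vapply(gyr, is.null, logical(1)))) {
    gyro <- data.frame(time = tm[keep_a], gx = gyr[[1]][ord][keep_a],
                       gy = gyr[[2]][ord][keep_a], gz = gyr[[3]][ord][keep_a])
  }

  lab <- getcol("label")
  labels <- NULL
  if (!is.null(lab)) labels <- as.character(lab[keep_s])

  har_recording(user_id %||% basename(path), stretch, accel, gyro, labels)
}

#' Write a recording to CSV
#'
#' Inverse of [read_recording()]: emits one row per timestamp in the union of
#' the stretch and accelerometer timelines, with `NA` for channels not sampled
#' at that instant.
#'
#' @param rec A [har_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  ts <- rec$stretch$time
  ta <- rec$accel$time
  tall <- sort(unique(c(ts, ta)))
  idx_s <- match(ts, tall)
  idx_a <- match(ta, tall)
  out <- data.frame(time = tall, stretch = NA_real_, ax = NA_real_,
                    ay = NA_real_, az = NA_real_)
  out$stretch[idx_s] <- rec$stretch$value
  out$ax[idx_a] <- rec$accel$ax
  out$ay[idx_a] <- rec$accel$ay
  out$az[idx_a] <- rec$accel$az
  if (!is.null(rec$gyro)) {
    out$gx <- out$gy <- out$gz <- NA_real_
    out$gx[idx_a] <- rec$gyro$gx
    out$gy[idx_a] <- rec$gyro$gy
    out$gz[idx_a] <- rec$gyro$gz
  }
  if (!is.null(rec$labels)) {
    out$label <- NA_character_
    out$label[idx_s] <- rec$labels
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Align stretch and accelerometer streams
#'
#' Shifts the accelerometer timeline by a known sensor offset, trims both
#' streams to their common time span, and associates every stretch sample with
#' its nearest-in-time accelerometer sample (ties broken toward the earlier
#' sample). Stretch samples outside the common span are dropped, along with
#' their labels.
#'
#' @param stretch A [sample_series()].
#' @param accel Data frame with `time`, `ax`, `ay`, `az`.
#' @param offset Seconds to add to the accelerometer timestamps.
#' @param user_id,gyro,labels Passed through to the resulting recording.
#' @return A [har_recording()] whose `stretch_to_accel` field maps each
#'   retained stretch sample to an accelerometer row index.
#' @export
align_streams <- function(stretch, accel, offset = 0, user_id = "user",
                          gyro = NULL, labels = NULL) {
  if (!nrow(stretch) || !nrow(accel))
    stop_validation("cannot align empty streams")
  accel$time <- accel$time + offset
  if (!is.null(gyro)) gyro$time <- gyro$time + offset
  lo <- max(min(stretch$time), min(accel$time))
  hi <- min(max(stretch$time), max(accel$time))
  if (lo > hi) stop_validation("streams have no common time span")
  keep_s <- stretch$time >= lo & stretch$time <= hi
  keep_a <- accel$time >= lo & accel$time <= hi
  stretch <- sample_series(stretch$time[keep_s], stretch$value[keep_s])
  if (!is.null(labels)) labels <- labels[keep_s]
  accel <- accel[keep_a, , drop = FALSE]
  rownames(accel) <- NULL
  if (!is.null(gyro)) {
    gyro <- gyro[keep_a, , drop = FALSE]
    rownames(gyro) <- NULL
  }
  assoc <- nearest_index(stretch$time, accel$time)
  har_recording(user_id, stretch, accel, gyro, labels, stretch_to_accel = assoc)
}

# Nearest-neighbour index of each query time in a sorted reference timeline;
# ties go to the earlier reference sample.
nearest_index <- function(query, ref) {
  n <- length(ref)
  pos <- findInterval(query, ref)          # ref[pos] <= q < ref[pos+1]
  pos[pos < 1L] <- 1L
  lo <- pos
  hi <- pmin(pos + 1L, n)
  d_lo <- abs(query - ref[lo])
  d_hi <- abs(query - ref[hi])
  ifelse(d_hi < d_lo, hi, lo)
}

#' Write / read segment tables
#'
#' Segments are serialised to a long-format CSV (one row per retained sample,
#' keyed by segment id and channel) so that a written list of segments
#' round-trips exactly through [read_segments()].
#'
#' @param segments Non-empty list of segments from [segment_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  if (!length(segments)) stop_validation("no segments to write")
  rows <- lapply(seq_along(segments), function(i) {
    sg <- segments[[i]]
    hdr <- data.frame(segment = i, start = sg$start, end = sg$end,
                      label = sg$label %||% NA_character_)
    st <- cbind(hdr, channel = "stretch", time = sg$stretch$time,
                value = sg$stretch$value, row.names = NULL)
    acc <- do.call(rbind, lapply(c("ax", "ay", "az"), function(ch)
      cbind(hdr, channel = ch, time = sg$accel$time,
            value = sg$accel[[ch]], row.names = NULL)))
    rbind(st, acc)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- utils::read.csv(path)
  lapply(split(df, df$segment), function(d) {
    st <- d[d$channel == "stretch", ]
    ax <- d[d$channel == "ax", ]
    ay <- d[d$channel == "ay", ]
    az <- d[d$channel == "az", ]
    lab <- d$label[1]
    har_segment(start = d$start[1], end = d$end[1],
                stretch = sample_series(st$time, st$value),
                accel = data.frame(time = ax$time, ax = ax$value,
                                   ay = ay$value, az = az$value),
                label = if (is.na(lab)) NULL else as.character(lab))
  })
}

#' Write / read feature tables
#'
#' Feature vectors are stored wide: 120 feature columns `f001`..`f120`
#' followed by `label`, `user_id`, `start`, `end` metadata.
#'
#' @param features A data frame from [har_featurize()] (or the same shape).
#' @param path CSV path.
#' @return `path` invisibly for the writer; the feature data frame for the
#'   reader.
#' @export
write_features <- function(features, path) {
  if (!NROW(features)) stop_validation("no feature vectors to write")
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- utils::read.csv(path)
  fcols <- grep("^f[0-9]{3}$", names(df))
  if (length(fcols) != 120L)
    stop_validation("feature file must contain 120 f-columns, found %d",
                    length(fcols))
  df
}

#' Read a pipeline configuration file
#'
#' The configuration is a YAML file holding the nominal sampling rates
#' (250 Hz IMU, 25 Hz stretch), the gravity constant (1, because the
#' accelerometer reports units of g), and an optional column map for external
#' files.
#'
#' @param path Path to a YAML file; `NULL` returns the built-in defaults.
#' @return A list with elements `fs_stretch`, `fs_accel`, `gravity`, `colmap`.
#' @export
har_config <- function(path = NULL) {
  cfg <- list(fs_stretch = 25, fs_accel = 250, gravity = 1, colmap = NULL)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
    if (!is.null(cfg$colmap) && !inherits(cfg$colmap, "har_colmap"))
      cfg$colmap <- do.call(har_colmap, cfg$colmap)
  }
  cfg
}
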