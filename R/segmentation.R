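#' Segmenter parameters
#'
#' Controls the variable-length activity segmenter, which monitors the
#' derivative of the (smoothed) stretch signal and opens a new segment at
#' every local minimum from which the signal rises, with a fixed-length
#' fallback window when the signal is static.
#'
#' @param smoothing_width Odd moving-average width in samples (default 5,
#'   i.e. 0.2 s at 25 Hz).
#' @param derivative_threshold Rise threshold in a.u./s for declaring a
#'   boundary; `NULL` (default) estimates it per stream as 4x the robust
#'   noise level of the smoothed derivative.
#' @param min_segment Minimum segment length in seconds; detected boundaries
#'   closer than this are merged, keeping the deeper minimum. The default
#'   0.3 s admits one segment per step at cadences past 2 Hz even when noise
#'   jitters the detected minima.
#' @param static_window Seconds after which a boundary is forced when no
#'   activity is detected (default 3 s).
#' @param neutral_band Derivative magnitudes below this (a.u./s) count as
#'   "at rest" when locating the minimum preceding a rise; `NULL` estimates
#'   2x the robust noise level.
#' @return An object of class `"har_segparams"`.
#' @export
har_segparams <- function(smoothing_width = 5L, derivative_threshold = NULL,
                          min_segment = 0.3, static_window = 3.0,
                          neutral_band = NULL) {
  if (min_segment <= 0 || min_segment > static_window)
    stop_validation("need 0 < min_segment <= static_window")
  if (!is.null(derivative_threshold) && derivative_threshold <= 0)
    stop_validation("derivative_threshold must be positive")
  structure(list(smoothing_width = as.integer(smoothing_width),
                 derivative_threshold = derivative_threshold,
                 min_segment = min_segment, static_window = static_window,
                 neutral_band = neutral_band),
            class = "har_segparams")
}

#' Centred moving-average smoothing
#'
#' Smooths a sample series with a centred moving average of odd width. At the
#' boundaries the window is truncated and the divisor is the actual number of
#' terms, so constants (and the overall mean structure) are preserved.
#' Width 1 is the identity.
#'
#' @param series A [sample_series()].
#' @param width Odd integer window width in samples.
#' @return A [sample_series()] of the same length.
#' @export
smooth_stretch <- function(series, width = 5L) {
  if (width < 1L || width %% 2L == 0L)
    stop_validation("smoothing width must be odd and >= 1")
  v <- series$value
  n <- length(v)
  if (width == 1L || n == 0L) return(series)
  half <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sample_series(series$time, (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

# Robust noise scale of the raw stretch samples, from second differences
# (insensitive to smooth trends and isolated bumps).
stretch_noise_sd <- function(v) {
  if (length(v) < 4L) return(0)
  stats::mad(diff(v, differences = 2L)) / sqrt(6)
}

#' Detect segment boundaries in a stretch stream
#'
#' A boundary is placed at each local minimum from which the smoothed stretch
#' derivative rises above `derivative_threshold` (crossing from at-rest to
#' rising); boundaries closer than `min_segment` are merged keeping the
#' deeper minimum (ties toward the earlier one), and whenever no boundary has
#' occurred within `static_window` of the previous one a boundary is forced,
#' so static stretches fall into fixed 3 s windows. The stream end is always
#' the final boundary.
#'
#' @param stretch A [sample_series()].
#' @param params A [har_segparams()].
#' @return Numeric vector of strictly increasing boundary times (seconds),
#'   excluding the stream start, including the stream end.
#' @export
find_boundaries <- function(stretch, params = har_segparams()) {
  n <- nrow(stretch)
  tt <- stretch$time
  if (n < 2L) {
    warning("stream too short to segment")
    return(numeric(0))
  }
  dt <- stats::median(diff(tt))
  span_end <- tt[n] + dt
  if (span_end - tt[1] < params$min_segment) {
    warning("stream shorter than min_segment; no boundaries")
    return(numeric(0))
  }
  sm <- smooth_stretch(stretch, params$smoothing_width)
  v <- sm$value
  d <- c(0, diff(v)) / dt
  sigma <- stretch_noise_sd(stretch$value)
  # noise sd of the smoothed derivative: successive width-w moving averages
  # differ by (x[i+h+1] - x[i-h]) / w
  d_noise <- sigma * sqrt(2) / max(params$smoothing_width, 1L) / dt
  thr <- params$derivative_threshold %||% max(4 * d_noise, 1e-9)
  neutral <- params$neutral_band %||% (2 * d_noise)

  # Event detector. An activity repetition starts with a rise from a local
  # minimum (derivative crossing from the neutral band to above the
  # threshold) and ends when the signal settles back to rest; a drop from a
  # rested level is handled symmetrically, so falling transitions and the
  # end of the last repetition of a bout are delimited too. A rise/fall is
  # only considered "ended" if the signal then stays at rest for
  # `settle_s` seconds, which prevents the brief at-rest instants at bump
  # peaks and valleys inside a bout from splitting every repetition.
  half <- (params$smoothing_width - 1L) %/% 2L
  settle_s <- 0.8
  settle_n <- max(1L, ceiling(settle_s / dt))
  dwell_n <- params$smoothing_width          # rest run required before a fall
  cand_t <- numeric(0)
  cand_depth <- numeric(0)
  add_cand <- function(idx) {
    cand_t <<- c(cand_t, tt[idx])
    cand_depth <<- c(cand_depth, v[idx])
  }
  armed_rise <- FALSE
  rest_idx <- 1L       # last sample with derivative <= neutral
  rest_run <- 0L       # current run of |d| <= neutral samples
  phase <- "rest"      # rest | rising | falling
  level_idx <- NA_integer_   # where the signal last settled after an event
  for (i in seq_len(n)) {
    if (d[i] <= neutral) {
      if (d[i] >= -neutral) rest_run <- rest_run + 1L else rest_run <- 0L
      rest_idx <- i
      armed_rise <- TRUE
    } else rest_run <- 0L

    if (phase %in% c("rising", "falling") && abs(d[i]) <= neutral) {
      if (is.na(level_idx)) level_idx <- i
      if (i - level_idx + 1L >= settle_n) {
        # event over: boundary where the signal levelled out
        win <- level_idx:min(n, level_idx + half)
        add_cand(win[which.min(v[win])])
        phase <- "rest"
        level_idx <- NA_integer_
      }
    } else if (abs(d[i]) > neutral && phase != "rest" && !is.na(level_idx)) {
      level_idx <- NA_integer_   # did not settle; event continues
    }

    if (d[i] > thr) {
      if (armed_rise && phase != "rising") {
        win <- max(1L, rest_idx - half):rest_idx
        add_cand(win[which.min(v[win])])
        armed_rise <- FALSE
      }
      phase <- "rising"
      level_idx <- NA_integer_
    } else if (d[i] < -thr) {
      if (phase == "rest" && rest_run >= dwell_n) add_cand(rest_idx)
      phase <- "falling"
      level_idx <- NA_integer_
    }
  }
  # Merge candidates closer than min_segment, keeping the deeper minimum.
  if (length(cand_t) > 1L) {
    ord <- order(cand_t)
    cand_t <- cand_t[ord]
    cand_depth <- cand_depth[ord]
    keep_t <- cand_t[1]; keep_d <- cand_depth[1]
    out_t <- numeric(0); out_d <- numeric(0)
    for (i in 2L:length(cand_t)) {
      if (cand_t[i] - keep_t < params$min_segment) {
        if (cand_depth[i] < keep_d) { keep_t <- cand_t[i]; keep_d <- cand_depth[i] }
      } else {
        out_t <- c(out_t, keep_t); out_d <- c(out_d, keep_d)
        keep_t <- cand_t[i]; keep_d <- cand_depth[i]
      }
    }
    cand_t <- c(out_t, keep_t)
  }
  cand_t <- cand_t[cand_t - tt[1] >= params$min_segment &
                   span_end - cand_t >= params$min_segment]

  # Force a boundary every static_window when nothing was detected, and close
  # the stream with a final boundary at its end.
  bounds <- numeric(0)
  last <- tt[1]
  for (ct in c(cand_t, span_end)) {
    while (ct - last > params$static_window + 1e-9) {
      nxt <- last + params$static_window
      # keep the trailing piece at least min_segment long
      if (ct - nxt < params$min_segment) nxt <- ct - params$min_segment
      if (nxt - last < params$min_segment) break
      bounds <- c(bounds, nxt)
      last <- nxt
    }
    bounds <- c(bounds, ct)
    last <- ct
  }
  bounds
}

#' A single activity segment
#'
#' One variable-length window of the recording with its raw stretch and
#' accelerometer slices. Intervals are half-open `[start, end)`.
#'
#' @param start,end Segment limits in seconds.
#' @param stretch A [sample_series()] slice.
#' @param accel Data frame slice with `time`, `ax`, `ay`, `az`.
#' @param label Optional activity tag.
#' @return An object of class `"har_segment"`.
#' @export
har_segment <- function(start, end, stretch, accel, label = NULL) {
  structure(list(start = start, end = end, duration = end - start,
                 stretch = stretch, accel = accel, label = label),
            class = "har_segment")
}

#' @export
print.har_segment <- function(x, ...) {
  cat(sprintf("<har_segment> [%.2f, %.2f) %s (%d stretch / %d accel samples)\n",
              x$start, x$end, x$label %||% "unlabeled",
              nrow(x$stretch), nrow(x$accel)))
  invisible(x)
}

#' Segment a recording into activity windows
#'
#' Applies [find_boundaries()] to the stretch stream and slices both sensor
#' streams at the resulting boundaries into contiguous, non-overlapping
#' segments covering the whole recording. If the recording carries labels,
#' each segment is labeled by majority vote over its per-sample labels; when
#' no label holds at least 75% of the samples the segment is tagged
#' `transition`.
#'
#' @param rec An aligned [har_recording()].
#' @param params A [har_segparams()].
#' @return List of [har_segment()] objects.
#' @export
segment_recording <- function(rec, params = har_segparams()) {
  if (!inherits(rec, "har_recording"))
    stop_validation("`rec` must be a har_recording")
  if (is.null(rec$stretch_to_accel))
    stop_validation("recording is not aligned; run align_streams() first")
  tt <- rec$stretch$time
  bounds <- find_boundaries(rec$stretch, params)
  if (!length(bounds)) return(list())
  starts <- c(tt[1], bounds[-length(bounds)])
  ends <- bounds
  lapply(seq_along(starts), function(i) {
    is_ <- tt >= starts[i] - 1e-9 & tt < ends[i] - 1e-9
    ia_ <- rec$accel$time >= starts[i] - 1e-9 & rec$accel$time < ends[i] - 1e-9
    lab <- NULL
    if (!is.null(rec$labels)) {
      seg_lab <- rec$labels[is_]
      counts <- table(seg_lab)
      lab <- names(counts)[which.max(counts)]
      if (max(counts) < 0.75 * length(seg_lab)) lab <- "transition"
    }
    acc <- rec$accel[ia_, , drop = FALSE]
    rownames(acc) <- NULL
    har_segment(starts[i], ends[i],
                sample_series(tt[is_], rec$stretch$value[is_]), acc, lab)
  })
}
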