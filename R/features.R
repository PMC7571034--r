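# Feature layout: 16 FFT magnitudes + min + max of the stretch window (18),
# then Haar A1 of ax, az, bacc (3 x 32), variances of ax, ay, az, bacc (4),
# mean(bacc) (1), and the segment duration (1): 120 in total.
STRETCH_SAMPLES <- 32L
ACCEL_SAMPLES <- 64L
N_STRETCH_FEATURES <- 18L
N_ACCEL_FEATURES <- 101L
N_FEATURES <- 120L

# The feature appended to reach the stated accelerometer feature count; kept
# behind one name so it can be swapped in a single place.
accel_extra_feature <- function(bacc) mean(bacc)

#' Sub-sample and smooth a window to a fixed length
#'
#' Reduces `N >= M` samples to `M` by evaluating, at each target position
#' `k = 0..M-1`, the mean of the input over the window
#' `[k*SR - SR, k*SR + SR]` with `SR = floor(N/M)`. Window indices are
#' clamped to the valid range and the divisor is the actual number of terms,
#' so constant inputs map to the same constant.
#'
#' @param values Numeric vector of length `N`.
#' @param target Output length `M <= N`.
#' @return Numeric vector of length `M`.
#' @export
subsample_smooth <- function(values, target) {
  n <- length(values)
  m <- as.integer(target)
  if (n < m)
    stop_validation("cannot sub-sample %d values to %d; pad instead", n, m)
  sr <- n %/% m
  vapply(seq_len(m) - 1L, function(k) {
    idx <- (k * sr - sr):(k * sr + sr)
    idx <- pmin(pmax(idx, 0L), n - 1L)
    mean(values[idx + 1L])
  }, numeric(1))
}

#' Zero-pad a window to a fixed length
#'
#' @param values Numeric vector of length `<= target`.
#' @param target Output length.
#' @return `values` with trailing zeros appended to length `target`.
#' @export
pad_to_length <- function(values, target) {
  if (length(values) > target)
    stop_validation("input longer than target length (%d > %d)",
                    length(values), target)
  c(values, numeric(target - length(values)))
}

# Standardize a window to exactly `target` samples: sub-sample when longer,
# zero-pad when shorter.
standardize_window <- function(values, target) {
  if (length(values) >= target) subsample_smooth(values, target)
  else pad_to_length(values, target)
}

#' Stretch-sensor features of one segment
#'
#' Computes the 18 stretch features: the magnitudes of the leading 16 bins of
#' the 64-point FFT of the previous and current standardized 32-sample
#' windows concatenated (capturing the 0--8 Hz band where gait energy lives),
#' plus the minimum and maximum of the current window.
#'
#' @param current,previous Numeric vectors of length 32 (use zeros for
#'   `previous` at the start of a stream).
#' @return Numeric vector of length 18.
#' @export
stretch_features <- function(current, previous = numeric(STRETCH_SAMPLES)) {
  if (length(current) != STRETCH_SAMPLES || length(previous) != STRETCH_SAMPLES)
    stop_validation("stretch windows must hold exactly %d samples", STRETCH_SAMPLES)
  spec <- Mod(stats::fft(c(previous, current)))
  c(spec[1:16], min(current), max(current))
}

#' Body acceleration
#'
#' Magnitude of the 3-axis acceleration with the gravitational component
#' removed: `sqrt(ax^2 + ay^2 + az^2) - g`, with `g = 1` because the
#' accelerometer reports units of g.
#'
#' @param ax,ay,az Numeric vectors of equal length (units of g).
#' @param g Gravity magnitude (default 1).
#' @return Numeric vector of body acceleration samples.
#' @export
body_accel <- function(ax, ay, az, g = 1) {
  if (length(ay) != length(ax) || length(az) != length(ax))
    stop_validation("accelerometer channels must have equal length")
  sqrt(ax^2 + ay^2 + az^2) - g
}

#' Level-1 Haar approximation coefficients
#'
#' First-level approximation (low-pass) half of the Haar discrete wavelet
#' transform: `A1[k] = (x[2k] + x[2k+1]) / sqrt(2)`, mapping 64 samples to
#' 32 coefficients covering the lower half of the band.
#'
#' @param values Numeric vector of length 64.
#' @return Numeric vector of 32 approximation coefficients.
#' @export
haar_a1 <- function(values) {
  if (length(values) != ACCEL_SAMPLES)
    stop_validation("Haar A1 expects exactly %d samples", ACCEL_SAMPLES)
  (values[c(TRUE, FALSE)] + values[c(FALSE, TRUE)]) / sqrt(2)
}

#' Accelerometer features of one segment
#'
#' Computes the 101 accelerometer features from channels standardized to 64
#' samples: Haar A1 coefficients of ax, az and body acceleration (3 x 32; the
#' lateral ay axis is not wavelet-transformed since lateral movement is
#' already captured by the body acceleration), the variances of ax, ay, az
#' and bacc, and the mean body acceleration.
#'
#' @param ax,ay,az Numeric vectors of length 64 (units of g).
#' @param g Gravity magnitude used for the body acceleration.
#' @return Numeric vector of length 101.
#' @export
accel_features <- function(ax, ay, az, g = 1) {
  for (ch in list(ax, ay, az))
    if (length(ch) != ACCEL_SAMPLES)
      stop_validation("accelerometer windows must hold exactly %d samples",
                      ACCEL_SAMPLES)
  bacc <- body_accel(ax, ay, az, g)
  c(haar_a1(ax), haar_a1(az), haar_a1(bacc),
    stats::var(ax), stats::var(ay), stats::var(az), stats::var(bacc),
    accel_extra_feature(bacc))
}

#' Build the 120-element feature vector of a segment
#'
#' Standardizes the segment's stretch slice to 32 samples and each
#' accelerometer channel to 64 samples (sub-sample/smooth when longer,
#' zero-pad when shorter), then concatenates 18 stretch features, 101
#' accelerometer features and the segment duration.
#'
#' @param segment A [har_segment()].
#' @param previous The preceding [har_segment()] in the stream, or `NULL`
#'   at the stream start (previous stretch window treated as zeros).
#' @param g Gravity magnitude.
#' @return Numeric vector of length 120, with the segment's label (or `NA`)
#'   in attribute `"label"`.
#' @export
build_feature_vector <- function(segment, previous = NULL, g = 1) {
  if (!nrow(segment$stretch) || !nrow(segment$accel))
    stop_validation("segment has empty sensor slices")
  cur <- standardize_window(segment$stretch$value, STRETCH_SAMPLES)
  prev <- if (is.null(previous)) numeric(STRETCH_SAMPLES)
          else standardize_window(previous$stretch$value, STRETCH_SAMPLES)
  ax <- standardize_window(segment$accel$ax, ACCEL_SAMPLES)
  ay <- standardize_window(segment$accel$ay, ACCEL_SAMPLES)
  az <- standardize_window(segment$accel$az, ACCEL_SAMPLES)
  out <- c(stretch_features(cur, prev), accel_features(ax, ay, az, g),
           segment$duration)
  stopifnot(length(out) == N_FEATURES)
  attr(out, "label") <- segment$label %||% NA_character_
  out
}

#' Featurize a list of segments
#'
#' Applies [build_feature_vector()] along a stream of segments (each segment's
#' previous-window context is the preceding segment) and assembles the wide
#' feature table used throughout the package.
#'
#' @param segments List of [har_segment()] from one recording, in order.
#' @param user_id Identifier stored alongside the features.
#' @param g Gravity magnitude.
#' @return Data frame with columns `f001`..`f120`, `label`, `user_id`,
#'   `start`, `end`.
#' @export
har_featurize <- function(segments, user_id = "user", g = 1) {
  if (!length(segments)) stop_validation("no segments to featurize")
  mat <- matrix(NA_real_, length(segments), N_FEATURES,
                dimnames = list(NULL, sprintf("f%03d", seq_len(N_FEATURES))))
  labs <- character(length(segments))
  for (i in seq_along(segments)) {
    fv <- build_feature_vector(segments[[i]],
                               if (i > 1L) segments[[i - 1L]] else NULL, g)
    mat[i, ] <- fv
    labs[i] <- attr(fv, "label")
  }
  out <- as.data.frame(mat)
  out$label <- labs
  out$user_id <- user_id
  out$start <- vapply(segments, `[[`, numeric(1), "start")
  out$end <- vapply(segments, `[[`, numeric(1), "end")
  out
}

#' Per-feature standardisation
#'
#' `fit_normalizer()` learns per-feature means and standard deviations on a
#' training matrix; `apply_normalizer()` maps vectors or matrices to zero
#' mean and unit variance per feature. Features that are constant in training
#' get scale 1 (with a warning) so they pass through centred but unscaled.
#'
#' @param x Numeric matrix (rows = feature vectors) with >= 2 rows.
#' @return `fit_normalizer()`: an object of class `"har_normalizer"` with
#'   fields `center` and `scale`; `apply_normalizer()`: the standardized
#'   input with the same shape.
#' @export
fit_normalizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L)
    stop_validation("need at least 2 training vectors to fit a normalizer")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  degenerate <- !is.finite(scl) | scl <= 0
  if (any(degenerate)) {
    warning(sprintf("%d constant feature(s); scale set to 1", sum(degenerate)))
    scl[degenerate] <- 1
  }
  structure(list(center = ctr, scale = scl), class = "har_normalizer")
}

#' @rdname fit_normalizer
#' @param normalizer A fitted `"har_normalizer"`.
#' @export
apply_normalizer <- function(x, normalizer) {
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    sweep(sweep(x, 2, normalizer$center), 2, normalizer$scale, "/")
  } else {
    (x - normalizer$center) / normalizer$scale
  }
}
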