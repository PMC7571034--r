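#' Synthetic wearer profile
#'
#' Parameters of the signal simulator for one wearer. The stretch channel is
#' modelled as per-posture constant baselines plus one raised-cosine bump per
#' step during locomotion; the accelerometer as a posture-dependent gravity
#' projection plus a damped-sinusoid burst per step. Units: stretch in
#' arbitrary units (a.u.), acceleration in units of g.
#'
#' @param step_frequency Locomotion cadence in Hz (one stretch bump per step).
#' @param stretch_baseline Named numeric vector of posture levels (a.u.) with
#'   entries `stand`, `sit`, `lie`.
#' @param stretch_step_amplitude Peak height of a walking bump above the
#'   stand baseline (a.u.).
#' @param accel_burst_amplitude Peak of the per-step accelerometer burst (g).
#' @param mount_angle Mounting angle of the IMU in degrees: the device is
#'   rotated by this much about the lateral (y) axis, mixing the ax and az
#'   channels. 0 is a perfectly aligned device.
#' @param noise_sd_stretch,noise_sd_accel Gaussian noise standard deviations.
#' @param rng_seed Integer seed attached to the profile.
#' @return An object of class `"har_profile"`.
#' @export
har_profile <- function(step_frequency = 1.6,
                        stretch_baseline = c(stand = 1.0, sit = 1.6, lie = 0.6),
                        stretch_step_amplitude = 0.5,
                        accel_burst_amplitude = 0.8,
                        mount_angle = 0,
                        noise_sd_stretch = 0.02,
                        noise_sd_accel = 0.05,
                        rng_seed = 1L) {
  if (stretch_step_amplitude <= 0 || accel_burst_amplitude <= 0)
    stop_validation("amplitudes must be positive")
  need <- c("stand", "sit", "lie")
  if (!all(need %in% names(stretch_baseline)))
    stop_validation("stretch_baseline must name stand, sit and lie levels")
  gaps <- abs(diff(sort(stretch_baseline[need])))
  if (noise_sd_stretch > 0 && any(gaps <= 3 * noise_sd_stretch))
    stop_validation("posture baselines must be separated by > 3 x noise_sd_stretch")
  structure(list(step_frequency = step_frequency,
                 stretch_baseline = stretch_baseline[need],
                 stretch_step_amplitude = stretch_step_amplitude,
                 accel_burst_amplitude = accel_burst_amplitude,
                 mount_angle = mount_angle,
                 noise_sd_stretch = noise_sd_stretch,
                 noise_sd_accel = noise_sd_accel,
                 rng_seed = as.integer(rng_seed)),
            class = "har_profile")
}

#' Activity script
#'
#' An ordered list of activities, each with either a duration in seconds
#' (postures) or a repetition count (locomotion: walk, jump, stairs).
#' Transition ramps between different posture levels are inserted
#' automatically by [generate_recording()].
#'
#' @param activity Character vector of activity tags (the 7 primary
#'   activities; `transition` is never scripted directly).
#' @param duration Numeric vector: seconds for postures, `NA` for locomotion.
#' @param reps Integer vector: step counts for locomotion, `NA` for postures.
#' @return An object of class `"har_script"` (a data frame).
#' @export
har_script <- function(activity, duration = NA_real_, reps = NA_integer_) {
  primary <- setdiff(har_activities(), "transition")
  bad <- setdiff(activity, primary)
  if (length(bad))
    stop_validation("activities must be scripted from the 7 primary classes; got: %s",
                    paste(bad, collapse = ", "))
  df <- data.frame(activity = activity,
                   duration = rep_len(as.numeric(duration), length(activity)),
                   reps = rep_len(as.integer(reps), length(activity)))
  loco <- df$activity %in% c("walk", "jump", "stairs_up", "stairs_down")
  if (any(loco & (is.na(df$reps) | df$reps < 1)))
    stop_validation("locomotion entries need a positive repetition count")
  if (any(!loco & (is.na(df$duration) | df$duration <= 0)))
    stop_validation("posture entries need a positive duration")
  structure(df, class = c("har_script", "data.frame"))
}

#' Scripts of the seven data-collection experiments
#'
#' Returns the activity script of one of the seven scripted experiments used
#' to collect the reference dataset (e.g. experiment 1: stand 30 s, jump 3
#' times, stand 30 s; experiment 3: stand 10 s, walk 40 steps, stand 10 s).
#' Stair experiments script one flight as 12 steps.
#'
#' @param experiment_id Integer in 1..7.
#' @return A [har_script()].
#' @export
make_protocol_script <- function(experiment_id) {
  if (!is.numeric(experiment_id) || length(experiment_id) != 1L ||
      is.na(experiment_id) || experiment_id != round(experiment_id) ||
      experiment_id < 1 || experiment_id > 7)
    stop_validation("experiment_id must be an integer in 1..7")
  stair_steps <- 12L
  switch(as.integer(experiment_id),
    har_script(c("stand", "jump", "stand"),
               duration = c(30, NA, 30), reps = c(NA, 3L, NA)),
    har_script(c("stand", "sit", "stand", "jump", "sit"),
               duration = c(10, 30, 10, NA, 30), reps = c(NA, NA, NA, 3L, NA)),
    har_script(c("stand", "walk", "stand"),
               duration = c(10, NA, 10), reps = c(NA, 40L, NA)),
    har_script(c("stand", "jump", "walk", "sit"),
               duration = c(10, NA, NA, 20), reps = c(NA, 3L, 40L, NA)),
    har_script(c("stand", "sit", "lie_down", "sit"),
               duration = c(10, 10, 30, 10), reps = NA_integer_),
    har_script(c("stand", "stairs_down", "stand"),
               duration = c(10, NA, 10), reps = c(NA, stair_steps, NA)),
    har_script(c("stand", "stairs_up", "stand"),
               duration = c(10, NA, 10), reps = c(NA, stair_steps, NA)))
}

# Per-activity simulator constants. Bump width is the fraction of the step
# period occupied by the raised-cosine flexion bump; stairs get narrower /
# wider bumps than walking so the classes are separable but related. Jumps
# are large 1 Hz bumps regardless of walking cadence.
sim_constants <- function() {
  list(bump_duty = c(walk = 0.50, stairs_up = 0.32, stairs_down = 0.68),
       # knee flexion is much deeper on stairs than in level walking
       amp_scale = c(walk = 1.0, stairs_up = 1.5, stairs_down = 1.3,
                     jump = 2.0),
       jump_freq = 1.0, jump_duty = 0.5,
       # per-activity accelerometer burst dynamics: stair gait differs from
       # level walking in impact sharpness and vertical push-off
       burst_scale = c(walk = 1.0, stairs_up = 1.3, stairs_down = 1.7,
                       jump = 2.5),
       burst_freq = c(walk = 8, stairs_up = 5, stairs_down = 11, jump = 8),
       transition_s = 1.0, burst_tau = 0.10,
       # unit gravity vector (ax, az) per posture; ay carries no gravity
       orient = list(stand = c(0, 1), walk = c(0, 1), stairs_up = c(0, 1),
                     stairs_down = c(0, 1), jump = c(0, 1),
                     sit = c(sqrt(1 - 0.7^2), 0.7), lie = c(1, 0)))
}

# Baseline stretch level for a block: postures use their own level,
# locomotion rides on the stand level.
block_level <- function(activity, baseline) {
  switch(activity,
         sit = baseline[["sit"]],
         lie_down = baseline[["lie"]],
         baseline[["stand"]])
}

#' Generate a labeled synthetic recording
#'
#' Renders an activity script into synchronized stretch (25 Hz) and
#' accelerometer (250 Hz) streams with per-sample ground-truth labels on the
#' stretch timeline. Postures are constant stretch baselines; locomotion adds
#' one raised-cosine bump per step at the profile's cadence; 1 s monotone
#' ramps labeled `transition` join blocks whose baseline levels differ.
#' The accelerometer carries the posture's gravity projection plus one damped
#' sinusoid burst per step and white noise. Gyroscope channels are emitted as
#' zeros. Output is deterministic in (script, profile, seed).
#'
#' @param script A [har_script()].
#' @param profile A [har_profile()].
#' @param seed Integer seed; defaults to the profile's `rng_seed`.
#' @param fs_stretch,fs_accel Sampling rates in Hz.
#' @param user_id Identifier stored in the recording.
#' @return A labeled, aligned [har_recording()].
#' @export
generate_recording <- function(script, profile, seed = profile$rng_seed,
                               fs_stretch = 25, fs_accel = 250,
                               user_id = "synthetic") {
  if (!inherits(script, "har_script")) stop_validation("`script` must be a har_script")
  if (!inherits(profile, "har_profile")) stop_validation("`profile` must be a har_profile")
  k <- sim_constants()
  bl <- profile$stretch_baseline

  # Build the block list: scripted blocks + automatic transition ramps.
  blocks <- list()
  prev_level <- NULL
  for (i in seq_len(nrow(script))) {
    act <- script$activity[i]
    lvl <- block_level(act, bl)
    if (!is.null(prev_level) && abs(lvl - prev_level) > 1e-12)
      blocks[[length(blocks) + 1L]] <-
        list(activity = "transition", from = prev_level, to = lvl,
             dur = k$transition_s)
    if (act %in% c("walk", "jump", "stairs_up", "stairs_down")) {
      f <- if (act == "jump") k$jump_freq else profile$step_frequency
      blocks[[length(blocks) + 1L]] <-
        list(activity = act, level = lvl, reps = script$reps[i],
             freq = f, dur = script$reps[i] / f)
    } else {
      blocks[[length(blocks) + 1L]] <-
        list(activity = act, level = lvl, dur = script$duration[i])
    }
    prev_level <- lvl
  }

  total <- sum(vapply(blocks, `[[`, numeric(1), "dur"))
  ns <- round(total * fs_stretch)
  na <- round(total * fs_accel)
  ts <- (seq_len(ns) - 1L) / fs_stretch
  ta <- (seq_len(na) - 1L) / fs_accel

  stretch <- numeric(ns)
  labels <- character(ns)
  ax <- numeric(na); ay <- numeric(na); az <- numeric(na)

  t0 <- 0
  for (b in blocks) {
    t1 <- t0 + b$dur
    is_ <- ts >= t0 - 1e-9 & ts < t1 - 1e-9
    ia_ <- ta >= t0 - 1e-9 & ta < t1 - 1e-9
    rel_s <- ts[is_] - t0
    rel_a <- ta[ia_] - t0
    labels[is_] <- b$activity
    if (b$activity == "transition") {
      frac <- rel_s / b$dur
      stretch[is_] <- b$from + (b$to - b$from) * frac
      # interpolate the gravity projection between neighbouring postures
      o_from <- orientation_for_level(b$from, bl, k)
      o_to <- orientation_for_level(b$to, bl, k)
      fa <- rel_a / b$dur
      ax[ia_] <- o_from[1] + (o_to[1] - o_from[1]) * fa
      az[ia_] <- o_from[2] + (o_to[2] - o_from[2]) * fa
    } else if (b$activity %in% c("walk", "jump", "stairs_up", "stairs_down")) {
      per <- 1 / b$freq
      duty <- if (b$activity == "jump") k$jump_duty else k$bump_duty[[b$activity]]
      amp <- profile$stretch_step_amplitude * k$amp_scale[[b$activity]]
      width <- duty * per
      phase <- rel_s %% per
      in_bump <- phase < width & rel_s < b$reps * per
      bump <- numeric(length(rel_s))
      bump[in_bump] <- amp * 0.5 * (1 - cos(2 * pi * phase[in_bump] / width))
      stretch[is_] <- b$level + bump
      o <- k$orient[[b$activity]]
      burst_amp <- profile$accel_burst_amplitude * k$burst_scale[[b$activity]]
      pa <- rel_a %% per
      env <- burst_amp * exp(-pa / k$burst_tau) *
        sin(2 * pi * k$burst_freq[[b$activity]] * pa)
      env[rel_a >= b$reps * per] <- 0
      ax[ia_] <- o[1] + 0.3 * env
      az[ia_] <- o[2] + env
    } else {
      stretch[is_] <- b$level
      o <- k$orient[[if (b$activity == "lie_down") "lie" else b$activity]]
      ax[ia_] <- o[1]
      az[ia_] <- o[2]
    }
    t0 <- t1
  }

  with_seed(seed, {
    # device mounting rotation about the lateral axis mixes ax and az; the
    # habitual per-user angle gets per-recording jitter because the device
    # is re-donned for every session
    a <- (profile$mount_angle + stats::rnorm(1, 0, 2)) * pi / 180
    ax_r <- cos(a) * ax + sin(a) * az
    az <- -sin(a) * ax + cos(a) * az
    ax <- ax_r
    if (profile$noise_sd_stretch > 0)
      stretch <- stretch + stats::rnorm(ns, 0, profile$noise_sd_stretch)
    if (profile$noise_sd_accel > 0) {
      ax <- ax + stats::rnorm(na, 0, profile$noise_sd_accel)
      ay <- ay + stats::rnorm(na, 0, profile$noise_sd_accel)
      az <- az + stats::rnorm(na, 0, profile$noise_sd_accel)
    }
  })

  align_streams(sample_series(ts, stretch),
                data.frame(time = ta, ax = ax, ay = ay, az = az),
                offset = 0, user_id = user_id,
                gyro = data.frame(time = ta, gx = 0, gy = 0, gz = 0),
                labels = labels)
}

# Gravity projection for a stretch level: matches the posture whose baseline
# is nearest (used only inside transition ramps).
orientation_for_level <- function(level, baseline, k) {
  post <- c("stand", "sit", "lie")
  nearest <- post[which.min(abs(baseline - level))]
  k$orient[[nearest]]
}

#' Generate a cohort of synthetic wearers
#'
#' Draws `n_users` profiles with parameters sampled uniformly from fixed
#' ranges: cadence 1.0--2.2 Hz, stand baseline 0.9--1.1 a.u., sit
#' 0.5--0.65 a.u. above stand, lie 0.35--0.5 a.u. below stand, step
#' amplitude 0.4--0.6 a.u., burst amplitude 0.6--1.0 g, habitual IMU
#' mounting angle -6 to 6 degrees, stretch noise 0.01--0.025 a.u., accel
#' noise 0.03--0.08 g.
#'
#' With `shifted = TRUE` the profile emulates a wearer whose signal
#' characteristics were never seen during offline training: a reduced
#' knee-flexion range compresses the posture levels toward standing (sit
#' +0.15--0.2, lie -0.1--0.14 a.u.) and the device is worn at a markedly
#' larger tilt (14--16 degrees, random sign); gait parameters stay in the
#' training ranges.
#'
#' @param n_users Number of profiles (>= 1).
#' @param seed Integer seed.
#' @param shifted Logical; draw out-of-distribution profiles (see above).
#' @return List of [har_profile()] objects.
#' @export
generate_cohort <- function(n_users, seed = 1L, shifted = FALSE) {
  if (!is.numeric(n_users) || n_users < 1)
    stop_validation("n_users must be >= 1")
  n_users <- as.integer(n_users)
  with_seed(seed, {
    lapply(seq_len(n_users), function(i) {
      sit_off <- if (shifted) stats::runif(1, 0.15, 0.2) else stats::runif(1, 0.5, 0.65)
      lie_off <- if (shifted) stats::runif(1, 0.1, 0.14) else stats::runif(1, 0.35, 0.5)
      stand <- stats::runif(1, 0.9, 1.1)
      har_profile(
        step_frequency = stats::runif(1, 1.0, 2.2),
        stretch_baseline = c(stand = stand, sit = stand + sit_off,
                             lie = stand - lie_off),
        stretch_step_amplitude = stats::runif(1, 0.4, 0.6),
        accel_burst_amplitude = stats::runif(1, 0.6, 1.0),
        mount_angle = if (shifted) sample(c(-1, 1), 1) * stats::runif(1, 14, 16)
                      else stats::runif(1, -6, 6),
        noise_sd_stretch = stats::runif(1, 0.01, 0.025),
        noise_sd_accel = stats::runif(1, 0.03, 0.08),
        rng_seed = child_seed(seed, i))
    })
  })
}
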