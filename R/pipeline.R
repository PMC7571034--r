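#' Experiment plan for the end-to-end harness
#'
#' Describes a full synthetic study: cohort size, how many users are held
#' out for online adaptation, how many offline/online split combinations to
#' evaluate, and the architecture grid for the design-space exploration.
#'
#' @param cohort_size Total number of synthetic wearers (default 22).
#' @param online_users Number held out for online adaptation per combination
#'   (default 4; the rest train the classifier offline).
#' @param combinations Number of offline/online split combinations
#'   (default 30). Splits are seeded random draws; consecutive combinations
#'   are re-drawn when they would share more than `max_overlap` online users.
#' @param experiments Which of the 7 scripted experiments each user performs.
#' @param dse_grid Architecture grid for [run_dse()], or `NULL` to skip DSE
#'   and use `hidden` directly.
#' @param hidden Architecture used when `dse_grid` is `NULL`.
#' @param episodes Online-learning episodes per held-out user.
#' @param seed Master seed.
#' @param max_overlap Maximum shared online users between consecutive
#'   combinations.
#' @return An object of class `"har_plan"`.
#' @export
har_plan <- function(cohort_size = 22L, online_users = 4L, combinations = 30L,
                     experiments = 1:7, dse_grid = NULL, hidden = c(4L, 8L),
                     episodes = 100L, seed = 1L, max_overlap = 2L) {
  if (online_users >= cohort_size)
    stop_validation("online_users must be smaller than cohort_size")
  if (combinations < 1L) stop_validation("need at least one combination")
  structure(list(cohort_size = as.integer(cohort_size),
                 online_users = as.integer(online_users),
                 combinations = as.integer(combinations),
                 experiments = experiments, dse_grid = dse_grid,
                 hidden = as.integer(hidden), episodes = as.integer(episodes),
                 seed = as.integer(seed), max_overlap = as.integer(max_overlap)),
            class = "har_plan")
}

#' Feature table of one simulated user
#'
#' Simulates the scripted experiments for one profile (optionally over
#' several recording sessions, each with its own noise and donning jitter),
#' segments each recording and returns the combined feature table.
#'
#' @param profile A [har_profile()].
#' @param user_id Identifier stored with the features.
#' @param experiments Which scripted experiments the user performs.
#' @param params Segmenter parameters.
#' @param sessions Number of recording sessions of the full protocol.
#' @return Feature data frame as from [har_featurize()].
#' @export
user_feature_table <- function(profile, user_id, experiments = 1:7,
                               params = har_segparams(), sessions = 1L) {
  tabs <- lapply(seq_len(sessions), function(s) {
    do.call(rbind, lapply(experiments, function(e) {
      rec <- generate_recording(make_protocol_script(e), profile,
                                seed = child_seed(profile$rng_seed,
                                                  e + 7L * (s - 1L)),
                                user_id = user_id)
      har_featurize(segment_recording(rec, params), user_id = user_id)
    }))
  })
  do.call(rbind, tabs)
}

#' Build the feature table of a whole cohort
#'
#' Runs simulate -> segment -> featurize for every profile in a cohort.
#'
#' @param profiles List of [har_profile()] (e.g. from [generate_cohort()]).
#' @param experiments Which scripted experiments each user performs.
#' @param params Segmenter parameters.
#' @param sessions How many times each user records the full protocol
#'   (training cohorts use 2 sessions by default so that per-session device
#'   donning variation is represented in the training data).
#' @return Feature data frame with `user_id` identifying each wearer.
#' @export
cohort_features <- function(profiles, experiments = 1:7,
                            params = har_segparams(), sessions = 2L) {
  tabs <- lapply(seq_along(profiles), function(i)
    user_feature_table(profiles[[i]], sprintf("user%02d", i), experiments,
                       params, sessions))
  do.call(rbind, tabs)
}

feature_cols <- function(df) grep("^f[0-9]{3}$", names(df))

# Seeded offline/online user splits with a cap on how many online users
# consecutive combinations may share.
draw_splits <- function(user_ids, online_users, combinations, seed,
                        max_overlap) {
  with_seed(seed, {
    splits <- vector("list", combinations)
    prev <- character(0)
    for (k in seq_len(combinations)) {
      for (try in 1:50) {
        onl <- sample(user_ids, online_users)
        if (length(intersect(onl, prev)) <= max_overlap) break
      }
      splits[[k]] <- list(online = onl, offline = setdiff(user_ids, onl))
      prev <- onl
    }
    splits
  })
}

#' Run the full synthetic experiment
#'
#' Reproduces the study flow end to end on synthetic wearers: generate a
#' cohort, segment and featurize every recording, then for each
#' offline/online combination train the classifier on the offline users
#' (60/20/20 split), record its confusion matrix, and adapt it to each
#' held-out user with both online-learning methods. Fully determined by the
#' plan's seed.
#'
#' @param plan A [har_plan()].
#' @param progress Print per-stage progress to stderr.
#' @return An object of class `"har_report"`: list with `features` (the
#'   cohort feature table), `dse` (if run), `fits` (per-combination models),
#'   `adaptation` (data frame: combination, user, method, initial and final
#'   accuracy, episodes to 95%) and `plan`.
#' @export
run_experiment <- function(plan = har_plan(), progress = interactive()) {
  say <- function(...) if (progress) message(sprintf(...))
  t0 <- Sys.time()
  say("simulating cohort of %d users...", plan$cohort_size)
  profiles <- generate_cohort(plan$cohort_size, seed = plan$seed)
  shifted <- generate_cohort(plan$cohort_size, seed = child_seed(plan$seed, 777),
                             shifted = TRUE)
  feats <- cohort_features(profiles, plan$experiments)
  say("featurized %d segments [%.1f s]", nrow(feats),
      as.numeric(Sys.time() - t0, units = "secs"))

  fc <- feature_cols(feats)
  dse <- NULL
  hidden <- plan$hidden
  if (!is.null(plan$dse_grid)) {
    say("running design-space exploration...")
    dse <- run_dse(feats[, fc], feats$label, grid = plan$dse_grid,
                   seed = child_seed(plan$seed, 1))
    hidden <- dse$chosen
    say("chosen architecture: %s", paste(hidden, collapse = "x"))
  }

  users <- unique(feats$user_id)
  splits <- draw_splits(users, plan$online_users, plan$combinations,
                        child_seed(plan$seed, 2), plan$max_overlap)
  fits <- vector("list", plan$combinations)
  rows <- list()
  for (k in seq_len(plan$combinations)) {
    sp <- splits[[k]]
    off <- feats[feats$user_id %in% sp$offline, ]
    fit <- har_mlp(off[, fc], off$label, hidden = hidden,
                   seed = child_seed(plan$seed, 100L + k))
    fits[[k]] <- fit
    say("combination %d/%d: test accuracy %.1f%%", k, plan$combinations,
        100 * fit$metrics[["test"]])
    for (u in sp$online) {
      i <- match(u, users)
      ufeats <- user_feature_table(shifted[[i]], u, plan$experiments)
      keep <- ufeats$label %in% fit$classes
      for (m in c("pg", "il")) {
        log <- run_adaptation(fit, ufeats[keep, fc], ufeats$label[keep],
                              method = m, episodes = plan$episodes,
                              seed = child_seed(plan$seed, 200L + k))
        hit <- which(log$accuracy >= 0.95)
        rows[[length(rows) + 1L]] <- data.frame(
          combination = k, user = u, method = m,
          initial = log$initial_accuracy, final = log$final_accuracy,
          episodes_to_95 = if (length(hit)) hit[1] else NA_integer_)
      }
    }
  }
  structure(list(features = feats, dse = dse, fits = fits,
                 adaptation = do.call(rbind, rows), plan = plan),
            class = "har_report")
}

#' @export
print.har_report <- function(x, ...) {
  accs <- vapply(x$fits, function(f) f$metrics[["test"]], numeric(1))
  cat(sprintf("<har_report> %d combinations, offline test accuracy %.1f%% (mean)\n",
              length(x$fits), 100 * mean(accs)))
  ad <- x$adaptation
  for (m in unique(ad$method))
    cat(sprintf("  %s: initial %.1f%% -> final %.1f%% (mean over %d runs)\n",
                m, 100 * mean(ad$initial[ad$method == m]),
                100 * mean(ad$final[ad$method == m]), sum(ad$method == m)))
  invisible(x)
}

#' Write a report to disk
#'
#' Emits the adaptation table and per-combination accuracies as CSV plus a
#' plain-text summary.
#'
#' @param report A `"har_report"` from [run_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$adaptation, file.path(dir, "adaptation.csv"),
                   row.names = FALSE)
  accs <- data.frame(combination = seq_along(report$fits),
                     train = vapply(report$fits, function(f) f$metrics[["train"]], numeric(1)),
                     cv = vapply(report$fits, function(f) f$metrics[["cv"]], numeric(1)),
                     test = vapply(report$fits, function(f) f$metrics[["test"]], numeric(1)))
  utils::write.csv(accs, file.path(dir, "offline_accuracy.csv"),
                   row.names = FALSE)
  con <- file(file.path(dir, "summary.txt"), "w")
  sink(con); print(report); sink()
  close(con)
  invisible(dir)
}
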