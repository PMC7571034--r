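# The packaged study conditions, built once per test run and cached:
# an 18-user offline training cohort recorded over 2 sessions, the fitted
# 120-4-8-8 classifier, and 4 held-out wearers with shifted profiles.

.study_cache <- new.env(parent = emptyenv())

study_features <- function() {
  if (is.null(.study_cache$feats)) {
    profiles <- generate_cohort(18, seed = 11)
    .study_cache$feats <- cohort_features(profiles)
  }
  .study_cache$feats
}

study_fit <- function() {
  if (is.null(.study_cache$fit)) {
    feats <- study_features()
    fc <- grep("^f[0-9]{3}$", names(feats))
    .study_cache$fit <- har_mlp(feats[, fc], feats$label, seed = 3)
  }
  .study_cache$fit
}

study_feature_cols <- function(df) grep("^f[0-9]{3}$", names(df))

study_heldout <- function() {
  if (is.null(.study_cache$heldout)) {
    shifted <- generate_cohort(4, seed = 1, shifted = TRUE)
    fit <- study_fit()
    .study_cache$heldout <- lapply(seq_along(shifted), function(i) {
      uf <- user_feature_table(shifted[[i]], sprintf("new%02d", i))
      uf[uf$label %in% fit$classes, ]
    })
  }
  .study_cache$heldout
}
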