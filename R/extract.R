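# Top-level feature extraction: one recording -> its registry block;
# one subject's six recordings -> the full 345-feature vector.

#' Compute the stimulus-specific features of a recording
#'
#' Dispatches to the per-stimulus extractor
#' ([circuit1_features()] ... [loops_features()]).
#'
#' @param rec A [recording()].
#' @param tpl Template from [make_template()] (defaults to the packaged
#'   geometry for the recording's stimulus).
#' @return Named numeric vector (length depends on the stimulus).
#' @export
compute_specific_features <- function(rec, tpl = make_template(rec$stimulus_id)) {
  switch(rec$stimulus_id,
         circuit1 = circuit1_features(rec, tpl),
         circuit2 = circuit2_features(rec, tpl),
         circuit3 = circuit3_features(rec, tpl),
         shapes1 = shapes1_features(rec, tpl),
         shapes2 = shapes2_features(rec, tpl),
         loops = loops_features(rec, tpl))
}

#' Extract all features of one recording
#'
#' Resamples to the nominal grid if needed, low-pass filters the
#' trajectory, then computes the 47 general features and the stimulus's
#' specific features, named `"<stimulus>.<feature>"` in registry order.
#'
#' @param rec A [recording()].
#' @param filter Apply the 15 Hz Butterworth preprocessing (default TRUE).
#' @return Named numeric vector.
#' @export
extract_features <- function(rec, filter = TRUE) {
  rec <- resample_recording(rec)
  if (filter) rec <- filter_recording(rec)
  vals <- c(compute_general_features(rec), compute_specific_features(rec))
  stats::setNames(vals, paste(rec$stimulus_id, names(vals), sep = "."))
}

#' Build a subject-by-feature table from a cohort of recordings
#'
#' @param cohort List of subjects; each subject a list with `meta` (a
#'   [subject_meta()]) and `recordings` (list of [recording()]s, at most
#'   one per stimulus). Missing stimuli yield `NA` features.
#' @param filter Passed to [extract_features()].
#' @return Data frame: columns `subject_id`, `age_days`, `gender`,
#'   `laterality`, `group`, then the 345 registry features.
#' @export
feature_table <- function(cohort, filter = TRUE) {
  reg <- feature_registry()
  rows <- lapply(cohort, function(subj) {
    vals <- stats::setNames(rep(NA_real_, nrow(reg)), reg$name)
    for (rec in subj$recordings) {
      fv <- extract_features(rec, filter = filter)
      vals[names(fv)] <- fv
    }
    m <- subj$meta
    cbind(data.frame(subject_id = m$subject_id, age_days = m$age_days,
                     gender = m$gender, laterality = m$laterality,
                     group = m$group, stringsAsFactors = FALSE),
          as.data.frame(as.list(vals), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Metadata column names of a feature table
#' @return Character vector.
#' @export
feature_table_meta_cols <- function() {
  c("subject_id", "age_days", "gender", "laterality", "group")
}
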