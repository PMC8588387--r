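# Moving (age-windowed) Z-score standardization against a reference
# cohort of typical writers. The reference cohort is disjoint from the
# classified (active) cohort, so no statistic ever depends on active
# subjects and train/test splitting cannot leak through standardization.

#' Build an age-indexed reference table
#'
#' @param features Data frame of reference subjects: metadata columns (see
#'   [feature_table_meta_cols()]) plus feature columns, as produced by
#'   [feature_table()].
#' @param active_ids Subject ids of the active cohort; any overlap with
#'   the reference is an integrity error (leakage guard).
#' @return Object of class `grapho_reference`: list with `age_days`,
#'   `values` (matrix subjects x features) and `subject_id`.
#' @export
build_reference <- function(features, active_ids = character()) {
  ids <- features$subject_id
  if (anyDuplicated(ids))
    stop("duplicate subject ids in reference cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  overlap <- intersect(ids, active_ids)
  if (length(overlap))
    stop("active subject(s) present in reference cohort: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  feat_cols <- setdiff(names(features), feature_table_meta_cols())
  structure(list(subject_id = ids,
                 age_days = features$age_days,
                 values = as.matrix(features[feat_cols])),
            class = "grapho_reference")
}

#' Moving Z-score of one feature value
#'
#' Standardizes `value` against reference subjects at most `window` days
#' younger or older than the subject: `z = (value - mean) / sd`, sample
#' standard deviation (n - 1). If fewer than 2 reference subjects fall in
#' the window it is widened symmetrically to the smallest window holding
#' 2 (with a warning); zero spread yields `z = 0` (with a warning).
#'
#' @param value Feature value.
#' @param age_days Subject age in days.
#' @param ref A [build_reference()] object.
#' @param feature Feature (column) name in the reference.
#' @param window Half-window in days; 183 days is the packaged reading of
#'   "6 months".
#' @return Standardized value (dimensionless). `NA` input gives `NA`.
#' @export
moving_zscore <- function(value, age_days, ref, feature, window = 183) {
  if (is.na(value)) return(NA_real_)
  v <- ref$values[, feature]
  ok <- is.finite(v)
  gap <- abs(ref$age_days - age_days)
  sel <- ok & gap <= window
  if (sum(sel) < 2) {
    need <- sort(gap[ok])
    if (length(need) < 2)
      stop("reference cohort has fewer than 2 usable subjects for feature ",
           feature, call. = FALSE)
    warning("age window widened to ", ceiling(need[2]), " days for feature ",
            feature, call. = FALSE)
    sel <- ok & gap <= need[2]
  }
  mu <- mean(v[sel]); sdev <- stats::sd(v[sel])
  if (!is.finite(sdev) || sdev == 0) {
    warning("zero spread in reference window for feature ", feature,
            call. = FALSE)
    return(0)
  }
  (value - mu) / sdev
}

#' Age-standardize a whole feature table
#'
#' Applies [moving_zscore()] to every feature of every active subject.
#' Missing feature values (failed extraction) are imputed as `z = 0`, the
#' reference mean, after standardization.
#'
#' @param features Active-cohort feature table ([feature_table()]).
#' @param ref A [build_reference()] object.
#' @param window Half-window in days (default 183).
#' @param impute Impute `NA` as 0 (default TRUE).
#' @return Feature table with the same layout, features standardized.
#' @export
apply_zscore <- function(features, ref, window = 183, impute = TRUE) {
  feat_cols <- setdiff(names(features), feature_table_meta_cols())
  out <- features
  for (fc in feat_cols) {
    out[[fc]] <- vapply(seq_len(nrow(features)), function(i)
      suppressWarnings(
        moving_zscore(features[[fc]][i], features$age_days[i], ref, fc,
                      window)),
      numeric(1))
    if (impute) out[[fc]][is.na(out[[fc]])] <- 0
  }
  out
}

#' Export reference window statistics for audit
#'
#' For each feature and each queried age, the window's n, mean and sd.
#'
#' @param ref A [build_reference()] object.
#' @param ages_days Window-center ages to tabulate.
#' @param window Half-window in days.
#' @return Data frame with columns `feature`, `age_days`, `n`, `mean`, `sd`.
#' @export
reference_stats <- function(ref, ages_days, window = 183) {
  feats <- colnames(ref$values)
  rows <- lapply(feats, function(f) {
    v <- ref$values[, f]
    do.call(rbind, lapply(ages_days, function(a) {
      sel <- is.finite(v) & abs(ref$age_days - a) <= window
      data.frame(feature = f, age_days = a, n = sum(sel),
                 mean = if (any(sel)) mean(v[sel]) else NA_real_,
                 sd = if (sum(sel) >= 2) stats::sd(v[sel]) else NA_real_)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
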