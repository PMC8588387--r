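# The four-step evaluation pipeline: correlation filtering,
# standardization, embedded feature selection and classification, all
# fitted strictly on training rows and applied to held-out rows, under
# repeated stratified cross-validation.

#' Pipeline configuration
#'
#' @param correlation_threshold Absolute Pearson correlation above which
#'   the later of two features (canonical order) is dropped (default 0.85).
#' @param selector Feature-selection estimator: `"linear_svm"` (C = 0.1,
#'   absolute coefficients) or `"extra_trees"` (100 trees, impurity
#'   importance).
#' @param n_selected Number of features kept by the selector (default 10).
#' @param estimator One of [estimator_names()].
#' @param cv_folds Stratified folds per repeat (default 5).
#' @param cv_repeats Cross-validation repeats (default 100); the repeat
#'   index seeds the fold shuffler and all stochastic fits of that repeat.
#' @param seed Base seed added to the repeat index.
#' @return List of class `grapho_config`.
#' @export
pipeline_config <- function(correlation_threshold = 0.85,
                            selector = c("linear_svm", "extra_trees"),
                            n_selected = 10,
                            estimator = "random_forest",
                            cv_folds = 5, cv_repeats = 100, seed = 0) {
  selector <- match.arg(selector)
  estimator <- match.arg(estimator, estimator_names())
  stopifnot(correlation_threshold > 0, correlation_threshold < 1,
            n_selected >= 1, cv_folds >= 2, cv_repeats >= 1)
  structure(list(correlation_threshold = correlation_threshold,
                 selector = selector, n_selected = n_selected,
                 estimator = estimator, cv_folds = cv_folds,
                 cv_repeats = cv_repeats, seed = seed),
            class = "grapho_config")
}

#' Drop highly correlated features
#'
#' Greedy scan in canonical (column) order: a feature is dropped when its
#' absolute Pearson correlation with any earlier kept feature exceeds the
#' threshold, so of two redundant features only the earlier is kept.
#' Computed on training rows only. Constant features have undefined
#' correlation, which is treated as 0 (the feature is kept) with a
#' warning.
#'
#' @param x Numeric matrix (training rows x features), >= 2 columns.
#' @param threshold Absolute correlation threshold (default 0.85).
#' @return Character vector of surviving feature names.
#' @export
drop_correlated <- function(x, threshold = 0.85) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 features", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    warning("constant feature(s) kept with correlation treated as 0: ",
            paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  cm <- suppressWarnings(abs(stats::cor(x)))
  cm[!is.finite(cm)] <- 0
  keep <- logical(ncol(x))
  for (j in seq_len(ncol(x))) {
    keep[j] <- !any(cm[j, keep] > threshold)
  }
  colnames(x)[keep]
}

#' Rank and select features with an embedded estimator
#'
#' Importance is the absolute hyperplane coefficient of a linear SVM
#' (C = 0.1) or the impurity importance of 100 extremely randomized
#' trees; the top `k` features are returned, ties broken by canonical
#' (column) order.
#'
#' @param x Standardized training matrix.
#' @param y Factor labels, levels `c("TD", "DYS")`.
#' @param selector `"linear_svm"` or `"extra_trees"`.
#' @param k Number of features to select.
#' @param seed Seed for the tree selector.
#' @return Character vector of `k` selected feature names.
#' @export
fit_select <- function(x, y, selector = c("linear_svm", "extra_trees"),
                       k = 10, seed = 0) {
  selector <- match.arg(selector)
  x <- as.matrix(x)
  if (k > ncol(x))
    stop("k (", k, ") exceeds available features (", ncol(x), ")",
         call. = FALSE)
  imp <- if (selector == "linear_svm") {
    fit <- e1071::svm(x, y, kernel = "linear", cost = 0.1, scale = FALSE)
    w <- t(fit$coefs) %*% fit$SV
    abs(as.numeric(w))
  } else {
    fit <- ranger::ranger(x = x, y = y, num.trees = 100,
                          splitrule = "extratrees", replace = FALSE,
                          sample.fraction = 1, importance = "impurity",
                          seed = seed)
    as.numeric(fit$variable.importance)
  }
  ord <- order(-imp, seq_along(imp))
  colnames(x)[ord[seq_len(k)]]
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)` (DYS detection
#' rate) and specificity `TN/(TN+FP)` (TD recognition rate). Undefined
#' ratios (empty denominator) are `NA`.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts; total must be > 0.
#' @return Named list with `accuracy`, `sensitivity`, `specificity`.
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  if (any(c(tp, tn, fp, fn) < 0) || total == 0)
    stop("confusion counts must be non-negative with positive total",
         call. = FALSE)
  list(accuracy = (tp + tn) / total,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Fit the four-step pipeline on a training set
#'
#' All four steps (correlation filter, standardization, feature
#' selection, estimator) are fitted strictly on the training rows; the
#' fitted object carries every parameter, so it is structurally
#' impossible for held-out rows to influence any of them.
#'
#' @param train_x Numeric matrix (training rows x features).
#' @param train_y Factor labels, levels `c("TD", "DYS")`; both classes
#'   must be present.
#' @param config A [pipeline_config()].
#' @param seed Seed for the stochastic steps of this split.
#' @return List of class `grapho_pipeline` with `kept` (features
#'   surviving the correlation filter), `mu`, `sdev` (standardization
#'   parameters), `selected` (feature names) and `model` (the fitted
#'   estimator).
#' @export
fit_pipeline <- function(train_x, train_y, config, seed = 0) {
  if (nlevels(droplevels(train_y)) < 2)
    stop("a class is absent from the training set", call. = FALSE)
  train_x <- as.matrix(train_x)
  kept <- suppressWarnings(
    drop_correlated(train_x, config$correlation_threshold))
  tr <- train_x[, kept, drop = FALSE]
  mu <- colMeans(tr)
  sdev <- apply(tr, 2, stats::sd)
  sdev[sdev == 0] <- 1
  tr <- sweep(sweep(tr, 2, mu), 2, sdev, "/")
  k <- min(config$n_selected, ncol(tr))
  selected <- fit_select(tr, train_y, config$selector, k, seed)
  model <- fit_estimator(config$estimator, tr[, selected, drop = FALSE],
                         train_y, seed = seed)
  structure(list(kept = kept, mu = mu, sdev = sdev, selected = selected,
                 model = model), class = "grapho_pipeline")
}

#' Predict held-out rows with a fitted pipeline
#'
#' @param pipe A [fit_pipeline()] object.
#' @param newx Numeric matrix with the full original feature columns.
#' @return Factor of predicted labels.
#' @export
predict_pipeline <- function(pipe, newx) {
  te <- as.matrix(newx)[, pipe$kept, drop = FALSE]
  te <- sweep(sweep(te, 2, pipe$mu), 2, pipe$sdev, "/")
  predict_estimator(pipe$model, te[, pipe$selected, drop = FALSE])
}

#' Fit the pipeline on a train set and evaluate one test fold
#'
#' Convenience wrapper around [fit_pipeline()] and [predict_pipeline()]
#' returning the fold's confusion counts.
#'
#' @param train_x,test_x Numeric matrices with identical columns.
#' @param train_y,test_y Factor labels, levels `c("TD", "DYS")`.
#' @param config A [pipeline_config()].
#' @param seed Seed for the stochastic steps of this split.
#' @return List with `selected` (feature names) and `confusion`
#'   (named counts tp, tn, fp, fn).
#' @export
fit_predict_pipeline <- function(train_x, train_y, test_x, test_y, config,
                                 seed = 0) {
  pipe <- fit_pipeline(train_x, train_y, config, seed)
  pred <- predict_pipeline(pipe, test_x)
  list(selected = pipe$selected,
       confusion = c(tp = sum(pred == "DYS" & test_y == "DYS"),
                     tn = sum(pred == "TD" & test_y == "TD"),
                     fp = sum(pred == "DYS" & test_y == "TD"),
                     fn = sum(pred == "TD" & test_y == "DYS")))
}

# stratified fold assignment: within each class, shuffle and deal
# round-robin so every fold keeps the class balance
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Repeated stratified cross-validation of the pipeline
#'
#' Runs `cv_repeats` repeats of stratified `cv_folds`-fold
#' cross-validation; repeat r uses seed `config$seed + r - 1` for the
#' fold shuffle and every stochastic fit of that repeat, so the whole
#' report is reproducible from the configuration alone. Per-repeat
#' metrics pool the repeat's fold confusions (each subject is predicted
#' exactly once per repeat).
#'
#' @param x Numeric matrix of (already age-standardized) features.
#' @param y Factor labels, levels `c("TD", "DYS")`; at least `cv_folds`
#'   subjects per class.
#' @param config A [pipeline_config()].
#' @return List of class `grapho_evaluation`: `metrics` (data frame of
#'   per-repeat accuracy/sensitivity/specificity), `summary` (means and
#'   sds), `selection_frequency` (named vector over all splits),
#'   `fold_confusions`, `n_splits` and `config`.
#' @export
cross_validate <- function(x, y, config = pipeline_config()) {
  x <- as.matrix(x)
  y <- factor(y, levels = c("TD", "DYS"))
  if (min(table(y)) < config$cv_folds)
    stop("need at least cv_folds subjects per class", call. = FALSE)
  sel_count <- stats::setNames(rep(0L, ncol(x)), colnames(x))
  metrics <- vector("list", config$cv_repeats)
  fold_conf <- list()
  for (r in seq_len(config$cv_repeats)) {
    seed_r <- config$seed + r - 1L
    folds <- stratified_folds(y, config$cv_folds, seed_r)
    conf <- c(tp = 0, tn = 0, fp = 0, fn = 0)
    for (f in seq_len(config$cv_folds)) {
      test <- folds == f
      res <- fit_predict_pipeline(x[!test, , drop = FALSE], y[!test],
                                  x[test, , drop = FALSE], y[test],
                                  config, seed = seed_r)
      sel_count[res$selected] <- sel_count[res$selected] + 1L
      conf <- conf + res$confusion
      fold_conf[[length(fold_conf) + 1L]] <-
        c(repeat_ = r, fold = f, res$confusion)
    }
    m <- classification_metrics(conf["tp"], conf["tn"], conf["fp"],
                                conf["fn"])
    metrics[[r]] <- data.frame(repeat_ = r, accuracy = m$accuracy,
                               sensitivity = m$sensitivity,
                               specificity = m$specificity)
  }
  metrics <- do.call(rbind, metrics)
  n_splits <- as.integer(config$cv_repeats * config$cv_folds)
  structure(list(
    metrics = metrics,
    summary = data.frame(
      metric = c("accuracy", "sensitivity", "specificity"),
      mean = c(mean(metrics$accuracy), mean(metrics$sensitivity),
               mean(metrics$specificity)),
      sd = c(stats::sd(metrics$accuracy), stats::sd(metrics$sensitivity),
             stats::sd(metrics$specificity))),
    selection_frequency = sel_count / n_splits,
    fold_confusions = do.call(rbind, fold_conf),
    n_splits = n_splits,
    config = config), class = "grapho_evaluation")
}

#' @export
print.grapho_evaluation <- function(x, ...) {
  cat(sprintf("<grapho_evaluation> %s selector, %s estimator, %dx%d-fold CV\n",
              x$config$selector, x$config$estimator, x$config$cv_repeats,
              x$config$cv_folds))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Feature selection frequencies and the frequently-selected report
#'
#' @param eval_or_counts A `grapho_evaluation` or a named frequency
#'   vector.
#' @param min_frequency Report threshold (default 0.4: features selected
#'   in at least 40% of splits).
#' @return Data frame `stimulus`, `feature`, `frequency`, sorted by
#'   stimulus then descending frequency.
#' @export
selection_frequency <- function(eval_or_counts, min_frequency = 0.4) {
  freq <- if (inherits(eval_or_counts, "grapho_evaluation"))
    eval_or_counts$selection_frequency else eval_or_counts
  sel <- freq[freq >= min_frequency]
  if (!length(sel))
    return(data.frame(stimulus = character(), feature = character(),
                      frequency = numeric()))
  parts <- strsplit(names(sel), ".", fixed = TRUE)
  out <- data.frame(stimulus = vapply(parts, `[`, "", 1),
                    feature = vapply(parts, function(p)
                      paste(p[-1], collapse = "."), ""),
                    frequency = as.numeric(sel))
  out[order(match(out$stimulus, GRAPHO_STIMULI), -out$frequency), ] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Age-, gender- and laterality-matched control selection
#'
#' For each DYS subject (processed in ascending age order) picks the
#' unused TD candidate with the same gender and laterality minimizing the
#' absolute age gap; ties go to the younger candidate.
#'
#' @param dys Data frame of DYS subjects with columns `subject_id`,
#'   `age_days`, `gender`, `laterality`.
#' @param td_pool Data frame of TD candidates, same columns.
#' @return Data frame with one row per DYS subject: `dys_id`, `td_id`,
#'   `age_gap_days`.
#' @export
pair_match <- function(dys, td_pool) {
  dys <- dys[order(dys$age_days), ]
  used <- logical(nrow(td_pool))
  rows <- lapply(seq_len(nrow(dys)), function(i) {
    d <- dys[i, ]
    elig <- which(!used & td_pool$gender == d$gender &
                    td_pool$laterality == d$laterality)
    if (!length(elig))
      stop("no eligible TD candidate for subject ", d$subject_id,
           call. = FALSE)
    gap <- abs(td_pool$age_days[elig] - d$age_days)
    best <- elig[order(gap, td_pool$age_days[elig])][1]
    used[best] <<- TRUE
    data.frame(dys_id = d$subject_id, td_id = td_pool$subject_id[best],
               age_gap_days = abs(td_pool$age_days[best] - d$age_days))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
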