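# The nine classifiers evaluated by the pipeline, behind a uniform
# fit/predict interface. Labels are a factor with levels c("TD", "DYS");
# DYS is the positive class.

#' Names of the available estimators
#' @return Character vector of length 9.
#' @export
estimator_names <- function() {
  c("random_forest", "extra_trees", "mlp", "svm_linear", "svm_poly",
    "svm_sigmoid", "svm_rbf", "gaussian_nb", "adaboost")
}

# ---- discrete AdaBoost (SAMME) over depth-1 rpart stumps ----
fit_adaboost <- function(x, y, n_rounds = 50, seed = 0) {
  set.seed(seed)
  n <- nrow(x)
  w <- rep(1 / n, n)
  df <- data.frame(y = y, x, check.names = FALSE)
  stumps <- list(); alphas <- numeric()
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = -1, minsplit = 2,
                                                       xval = 0))
    pred <- stats::predict(fit, df, type = "class")
    miss <- pred != y
    err <- sum(w[miss]) / sum(w)
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
    if (err < 1e-9) break
  }
  structure(list(stumps = stumps, alphas = alphas, levels = levels(y)),
            class = "grapho_adaboost")
}

predict_adaboost <- function(model, newx) {
  df <- as.data.frame(newx, check.names = FALSE)
  if (!length(model$stumps))
    return(factor(rep(model$levels[1], nrow(df)), levels = model$levels))
  score <- rep(0, nrow(df))
  for (m in seq_along(model$stumps)) {
    pred <- stats::predict(model$stumps[[m]], df, type = "class")
    score <- score + model$alphas[m] * ifelse(pred == model$levels[2], 1, -1)
  }
  factor(ifelse(score >= 0, model$levels[2], model$levels[1]),
         levels = model$levels)
}

#' Fit one of the nine classifiers
#'
#' Hyperparameters follow the evaluated configurations: 500 trees for the
#' random forest and the extremely randomized trees, a single hidden
#' layer of 12 logistic units for the MLP (up to 1000 epochs, no early
#' stopping), library-default SVM and Gaussian naive Bayes settings, and
#' 50 stump rounds for AdaBoost.
#'
#' @param name One of [estimator_names()].
#' @param x Numeric matrix (rows = subjects).
#' @param y Factor with levels `c("TD", "DYS")`.
#' @param seed Seed for the stochastic estimators.
#' @return Fitted model with class `grapho_estimator`.
#' @export
fit_estimator <- function(name, x, y, seed = 0) {
  name <- match.arg(name, estimator_names())
  x <- as.matrix(x)
  fit <- switch(name,
    random_forest = ranger::ranger(x = x, y = y, num.trees = 500,
                                   seed = seed, probability = FALSE),
    extra_trees = ranger::ranger(x = x, y = y, num.trees = 500,
                                 splitrule = "extratrees",
                                 replace = FALSE, sample.fraction = 1,
                                 seed = seed, probability = FALSE),
    mlp = {
      set.seed(seed)
      df <- data.frame(y = y, x, check.names = FALSE)
      nnet::nnet(y ~ ., data = df, size = 12, maxit = 1000, decay = 1e-4,
                 trace = FALSE, MaxNWts = 10000)
    },
    svm_linear = e1071::svm(x, y, kernel = "linear", scale = FALSE),
    svm_poly = e1071::svm(x, y, kernel = "polynomial", scale = FALSE),
    svm_sigmoid = e1071::svm(x, y, kernel = "sigmoid", scale = FALSE),
    svm_rbf = e1071::svm(x, y, kernel = "radial", scale = FALSE),
    gaussian_nb = e1071::naiveBayes(as.data.frame(x, check.names = FALSE), y),
    adaboost = fit_adaboost(x, y, seed = seed))
  structure(list(name = name, fit = fit, levels = levels(y),
                 features = colnames(x)),
            class = "grapho_estimator")
}

#' Predict with a fitted estimator
#'
#' @param model A [fit_estimator()] result.
#' @param newx Numeric matrix with the same columns as at fit time.
#' @return Factor of predicted labels.
#' @export
predict_estimator <- function(model, newx) {
  newx <- as.matrix(newx)[, model$features, drop = FALSE]
  pred <- switch(model$name,
    random_forest = ,
    extra_trees = stats::predict(model$fit, data = as.data.frame(newx,
      check.names = FALSE))$predictions,
    mlp = {
      cls <- stats::predict(model$fit,
                            newdata = as.data.frame(newx,
                                                    check.names = FALSE),
                            type = "class")
      factor(cls, levels = model$levels)
    },
    svm_linear = ,
    svm_poly = ,
    svm_sigmoid = ,
    svm_rbf = stats::predict(model$fit, newx),
    gaussian_nb = stats::predict(model$fit,
                                 as.data.frame(newx, check.names = FALSE)),
    adaboost = predict_adaboost(model$fit, newx))
  factor(as.character(pred), levels = model$levels)
}
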