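#' Classification metrics from confusion counts
#'
#' PD is the positive class. Accuracy, recall (sensitivity), precision and f1
#' are recomputed exactly from the four counts; `f1 = 2PR / (P + R)`.
#'
#' @param tp,fp,tn,fn confusion counts.
#' @return named numeric vector `accuracy`, `recall`, `precision`, `f1`
#'   (fractions).
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  c(accuracy = (tp + tn) / n, recall = recall, precision = precision, f1 = f1)
}

#' Fit a PD-versus-control classifier behind the uniform model interface
#'
#' Backends: `"logistic"` — ridge-regularized logistic regression (glmnet,
#' `alpha = 0`, fixed small lambda, standardized); `"rf"` — random forest;
#' `"xgb"` — gradient-boosted trees (xgboost, 100 rounds, depth 3, eta 0.1).
#' Missing feature values are imputed with per-feature medians learned here
#' and reused at prediction time.
#'
#' @param X numeric feature matrix (subjects x indicators).
#' @param y group labels (`"PD"` / `"control"`).
#' @param model backend name.
#' @param seed optional RNG seed for the stochastic backends.
#' @return object of class `spiral_model` (backend, fit, feature names,
#'   imputation medians).
#' @export
fit_model <- function(X, y, model = c("logistic", "rf", "xgb"), seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  med <- apply(X, 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  X <- impute_median(X, med)
  fit <- switch(model,
    logistic = glmnet::glmnet(X, factor(y, c("control", "PD")),
                              family = "binomial", alpha = 0,
                              lambda = 1 / nrow(X), standardize = TRUE),
    rf = randomForest::randomForest(X, factor(y, c("control", "PD")),
                                    ntree = 500),
    xgb = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3, eta = 0.1,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = as.numeric(y == "PD")),
      nrounds = 100))
  structure(list(backend = model, fit = fit, features = colnames(X),
                 medians = med), class = "spiral_model")
}

impute_median <- function(X, med) {
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- med[j]
  }
  X
}

predict_prob <- function(object, X) {
  X <- impute_median(X[, object$features, drop = FALSE], object$medians)
  switch(object$backend,
    logistic = as.numeric(stats::predict(object$fit, newx = X, type = "response")),
    rf = stats::predict(object$fit, X, type = "prob")[, "PD"],
    xgb = stats::predict(object$fit, xgboost::xgb.DMatrix(X)))
}

#' Leave-one-out cross-validated PD-versus-control classification
#'
#' For each subject, a classifier is trained on the remaining subjects and
#' predicts the held-out one; pooled predictions give the confusion counts
#' and metrics. With `subset = "significant"` the indicator list is
#' recomputed inside each fold on the training fold only (via
#' [between_group()] at `alpha`) so no test-fold information leaks into the
#' feature selection. Missing indicator values are imputed with training-fold
#' medians.
#'
#' @param table subject-level table from [aggregate_trials()] (needs `group`
#'   and indicator columns; both classes present, >= 10 subjects).
#' @param model `"logistic"` (ridge-regularized), `"rf"` (random forest) or
#'   `"xgb"` (gradient-boosted trees).
#' @param subset `"all"` indicators, or `"significant"` (per-fold selection).
#' @param alpha selection level for `subset = "significant"`.
#' @param seed RNG seed recorded in the report and used for every stochastic
#'   backend.
#' @return list of class `classification_report`: `model`, `subset`, `seed`,
#'   counts `tp/fp/tn/fn`, `metrics` (see [classification_metrics()]),
#'   `predictions` (per-subject truth, probability, label),
#'   `selected_per_fold` (for `"significant"`).
#' @export
loocv_classify <- function(table, model = c("logistic", "rf", "xgb"),
                           subset = c("all", "significant"), alpha = 0.05,
                           seed = 1L) {
  model <- match.arg(model)
  subset <- match.arg(subset)
  ind_cols <- intersect(indicator_names(), names(table))
  n <- nrow(table)
  if (n < 10) stop("need >= 10 subjects")
  if (length(unique(table$group)) < 2) stop("both classes must be present")
  prob <- numeric(n)
  selected <- vector("list", n)
  for (i in seq_len(n)) {
    train <- table[-i, , drop = FALSE]
    if (length(unique(train$group)) < 2)
      stop("a training fold contains one class only")
    feats <- ind_cols
    if (subset == "significant") {
      bg <- between_group(train)
      sig <- bg$indicator[bg$p_value < alpha]
      if (length(sig) >= 2) feats <- sig
      selected[[i]] <- feats
    }
    Xtr <- as.matrix(train[, feats, drop = FALSE])
    fit <- fit_model(Xtr, train$group, model, seed = seed + i)
    prob[i] <- predict_prob(fit, as.matrix(table[i, feats, drop = FALSE]))
  }
  pred <- ifelse(prob >= 0.5, "PD", "control")
  truth <- table$group
  tp <- sum(pred == "PD" & truth == "PD")
  fp <- sum(pred == "PD" & truth == "control")
  tn <- sum(pred == "control" & truth == "control")
  fn <- sum(pred == "control" & truth == "PD")
  structure(list(
    model = model, subset = subset, seed = seed,
    tp = tp, fp = fp, tn = tn, fn = fn,
    metrics = classification_metrics(tp, fp, tn, fn),
    predictions = data.frame(subject_id = table$subject_id, truth = truth,
                             prob_PD = prob, predicted = pred),
    selected_per_fold = if (subset == "significant") selected),
    class = "classification_report")
}

#' @exportS3Method base::print
print.classification_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<classification_report> %s / subset %s: acc %.2f%%, f1 %.2f%%, recall %.2f%%, precision %.2f%% (TP %d FP %d TN %d FN %d)\n",
    x$model, x$subset, 100 * m["accuracy"], 100 * m["f1"], 100 * m["recall"],
    100 * m["precision"], x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Per-indicator attribution of a fitted classifier
#'
#' Shapley additive attributions for the boosted-tree backend (TreeSHAP as
#' implemented by xgboost's `predcontrib` predictions; per-subject
#' attributions plus the base value reproduce the model margin exactly) and
#' coefficient-times-centered-value attributions for the linear backend.
#' Positive values push the prediction toward PD. The random-forest backend
#' has no Shapley implementation here and raises an error naming the
#' supported backends.
#'
#' @param object a `spiral_model` from [fit_model()] (or the `$fit`-bearing
#'   model refit on the full table, see [loocv_classify()]).
#' @param table subject-level table with the model's feature columns.
#' @return list of class `attribution_summary`: `values` (subjects x
#'   indicators signed attributions), `base_value`, `summary` (per indicator:
#'   `mean_abs`, `rank`), `feature_values`.
#' @export
attribute <- function(object, table) {
  stopifnot(inherits(object, "spiral_model"))
  X <- impute_median(as.matrix(table[, object$features, drop = FALSE]),
                     object$medians)
  if (object$backend == "xgb") {
    contrib <- stats::predict(object$fit, xgboost::xgb.DMatrix(X),
                              predcontrib = TRUE)
    bias_col <- ncol(contrib)   # last column is the base value
    base <- contrib[1, bias_col]
    vals <- contrib[, -bias_col, drop = FALSE]
  } else if (object$backend == "logistic") {
    beta <- as.matrix(stats::coef(object$fit))[-1, 1]
    center <- colMeans(X)
    vals <- sweep(X, 2, center) %*% diag(beta, length(beta))
    colnames(vals) <- object$features
    base <- as.matrix(stats::coef(object$fit))[1, 1] + sum(beta * center)
  } else {
    stop("attribution supports backends: xgb (TreeSHAP), logistic ",
         "(coefficient x centered value); not: ", object$backend)
  }
  mean_abs <- colMeans(abs(vals))
  summary <- data.frame(indicator = colnames(vals), mean_abs = mean_abs,
                        rank = rank(-mean_abs, ties.method = "first"))
  summary <- summary[order(summary$rank), ]
  rownames(summary) <- NULL
  structure(list(values = vals, base_value = base, summary = summary,
                 feature_values = X),
            class = "attribution_summary")
}
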