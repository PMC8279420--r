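#' Stratified train/test split
#'
#' Splits the samples into disjoint, exhaustive train and test sets,
#' stratified by group: `floor(test_prop * n_g)` test samples per group.
#' With `test_prop = 0` — or when any group would contribute no test
#' sample — the test set is empty and the full data are used for training.
#' Reproducible given the seed.
#'
#' @param ds an [omics_data].
#' @param test_prop test proportion in `[0, 1)`.
#' @param seed integer seed.
#' @return list with `train` ([omics_data]) and `test` ([omics_data] or
#'   `NULL`).
#' @export
split_train_test <- function(ds, test_prop = 0.2, seed = NULL) {
  stopifnot(is_omics_data(ds))
  if (test_prop < 0 || test_prop >= 1) abort("test_prop must be in [0, 1).")
  if (test_prop == 0) return(list(train = ds, test = NULL))
  g <- groups(ds)
  n_test <- floor(test_prop * tabulate(g))
  if (any(n_test < 1)) {
    warn("test_prop leaves some group without a test sample; using an empty test set.")
    return(list(train = ds, test = NULL))
  }
  pick <- function() {
    unlist(lapply(seq_along(levels(g)), function(i) {
      idx <- which(g == levels(g)[i])
      sort(sample(idx, n_test[i]))
    }))
  }
  test_idx <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  ids <- sample_ids(ds)
  list(train = subset_samples(ds, ids[-test_idx]),
       test = subset_samples(ds, ids[test_idx]))
}

#' Penalized logistic regression with internal lambda selection
#'
#' Elastic-net-penalized logistic regression of group on the features
#' (`alpha = 1` LASSO, `alpha = 0` ridge, in between elastic net) via
#' glmnet. The penalty `lambda` is chosen on the training set by
#' stratified k-fold cross-validation over a 100-value log-spaced grid
#' spanning four decades below `lambda_max`, minimizing mean CV deviance
#' (`lambda_rule = "1se"` picks the sparsest model within one standard
#' error instead). Features are standardized before the fit and
#' coefficients are reported on the standardized scale. When a test set is
#' held out, all reported metrics come exclusively from it.
#'
#' @param ds a complete [omics_data] with exactly 2 groups.
#' @param alpha elastic-net mixing parameter in `[0, 1]`.
#' @param test_prop held-out test proportion (0 disables external
#'   validation).
#' @param nfolds internal CV folds (default 10; reduced to the smallest
#'   training group size when needed).
#' @param seed integer seed (split + folds).
#' @param lambda_rule `"min"` (CV-deviance minimum) or `"1se"`.
#' @return A `predictive_eval`; see [prediction_metrics()] for the metric
#'   definitions. `tidy()` returns the nonzero coefficients.
#' @export
regularized_logistic <- function(ds, alpha = 1, test_prop = 0.2, nfolds = 10,
                                 seed = NULL, lambda_rule = c("min", "1se")) {
  check_groups(ds, exactly = 2)
  lambda_rule <- rlang::arg_match(lambda_rule)
  stopifnot(alpha >= 0, alpha <= 1)
  if (anyNA(ds$values)) abort("Matrix has missing cells; impute first.")
  sp <- split_train_test(ds, test_prop, seed)
  train <- sp$train; test <- sp$test
  x <- scale(train$values)
  ctr <- attr(x, "scaled:center"); scl <- attr(x, "scaled:scale")
  scl[scl == 0] <- 1
  x[, attr(x, "scaled:scale") == 0] <- 0
  y <- groups(train)
  nfolds_eff <- max(3, min(nfolds, min(tabulate(y))))
  foldid <- make_folds(y, nfolds_eff, seed)
  one_class <- any(vapply(seq_len(nfolds_eff), function(f) {
    nlevels(droplevels(y[foldid != f])) < 2
  }, logical(1)))
  if (one_class) {
    foldid <- make_folds(y, nfolds_eff, if (is.null(seed)) NULL else seed + 1L)
    if (any(vapply(seq_len(nfolds_eff), function(f) {
      nlevels(droplevels(y[foldid != f])) < 2
    }, logical(1)))) abort("Cross-validation folds keep losing a whole class.")
  }
  cvfit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                             nlambda = 100, lambda.min.ratio = 1e-4,
                             foldid = foldid, standardize = FALSE,
                             type.measure = "deviance")
  lam <- if (lambda_rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  co <- coef(cvfit, s = lam)
  coefs <- tibble::tibble(
    term = rownames(co), estimate = as.numeric(co)) |>
    dplyr::filter(.data$term != "(Intercept)")
  eval <- NULL
  if (!is.null(test)) {
    xt <- sweep(sweep(test$values, 2, ctr), 2, scl, "/")
    pred <- predict(cvfit, newx = xt, s = lam, type = "class")
    eval <- confusion_eval(groups(test), factor(pred, levels = levels(y)))
  }
  new_predictive_eval(
    method = "elastic_net", ds = ds, split = sp, seed = seed,
    hyperparameters = list(alpha = alpha, lambda = lam, nfolds = nfolds_eff,
                           lambda_rule = lambda_rule),
    coefficients = coefs, eval = eval, model = cvfit)
}

#' Random forest classification with external test-set validation
#'
#' Fits a random forest on the training split only; the confusion matrix
#' and error metrics are computed exclusively on the held-out test set
#' (external validation is the point — an empty test set is an error).
#' Feature importance is the forest's mean decrease in node impurity.
#'
#' @param ds a complete [omics_data] with >= 2 groups.
#' @param n_trees number of trees (default 500).
#' @param test_prop held-out test proportion (must give a nonempty test
#'   set).
#' @param seed integer seed (split + forest).
#' @return A `predictive_eval`; `tidy()` returns the importance ranking.
#' @export
random_forest_eval <- function(ds, n_trees = 500, test_prop = 0.2, seed = NULL) {
  check_groups(ds, min_levels = 2)
  if (anyNA(ds$values)) abort("Matrix has missing cells; impute first.")
  sp <- split_train_test(ds, test_prop, seed)
  if (is.null(sp$test)) abort("Random forest evaluation requires a nonempty test set.")
  fit_fun <- function() {
    randomForest::randomForest(x = sp$train$values, y = groups(sp$train), ntree = n_trees)
  }
  fit <- if (is.null(seed)) fit_fun() else withr::with_seed(seed, fit_fun())
  pred <- predict(fit, sp$test$values)
  imp <- randomForest::importance(fit)
  importances <- tibble::tibble(term = rownames(imp),
                                importance = imp[, "MeanDecreaseGini"]) |>
    dplyr::arrange(dplyr::desc(.data$importance))
  new_predictive_eval(
    method = "random_forest", ds = ds, split = sp, seed = seed,
    hyperparameters = list(n_trees = n_trees),
    coefficients = importances,
    eval = confusion_eval(groups(sp$test), factor(pred, levels = levels(groups(ds)))),
    model = fit)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy with an exact Clopper–Pearson 95% binomial confidence interval
#' and, for the two-class case, sensitivity and specificity with the
#' *second* group level as the positive class (the package-wide contrast
#' convention).
#'
#' @param confusion square contingency matrix, rows = truth, columns =
#'   predicted.
#' @return A tibble with `accuracy`, `ci_low`, `ci_high`, and (2x2 only)
#'   `sensitivity`, `specificity`.
#' @export
prediction_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) abort("Confusion matrix must be square.")
  n <- sum(confusion)
  if (n == 0) abort("Confusion matrix is empty.")
  correct <- sum(diag(confusion))
  out <- tibble::tibble(
    accuracy = correct / n,
    ci_low = if (correct == 0) 0 else qbeta(0.025, correct, n - correct + 1),
    ci_high = if (correct == n) 1 else qbeta(0.975, correct + 1, n - correct),
    n_test = n)
  if (nrow(confusion) == 2) {
    out$sensitivity <- confusion[2, 2] / sum(confusion[2, ])
    out$specificity <- confusion[1, 1] / sum(confusion[1, ])
  }
  out
}

confusion_eval <- function(truth, pred) {
  cm <- table(truth = truth, predicted = factor(pred, levels = levels(truth)))
  list(confusion = unclass(cm), metrics = prediction_metrics(cm))
}

new_predictive_eval <- function(method, ds, split, seed, hyperparameters,
                                coefficients, eval, model) {
  structure(list(
    method = method,
    split = list(
      test_prop = if (is.null(split$test)) 0 else n_samples(split$test) / n_samples(ds),
      seed = seed, stratified = TRUE,
      train_ids = sample_ids(split$train),
      test_ids = if (is.null(split$test)) character() else sample_ids(split$test)),
    hyperparameters = hyperparameters,
    coefficients = coefficients,
    confusion = eval$confusion,
    metrics = eval$metrics,
    model = model),
    class = "predictive_eval")
}

#' @export
print.predictive_eval <- function(x, ...) {
  cat(sprintf("<predictive_eval> method=%s; train n=%d, test n=%d\n",
              x$method, length(x$split$train_ids), length(x$split$test_ids)))
  if (!is.null(x$metrics)) {
    m <- x$metrics
    cat(sprintf("  accuracy %.3f (95%% CI %.3f-%.3f)", m$accuracy, m$ci_low, m$ci_high))
    if (!is.null(m$sensitivity)) {
      cat(sprintf("; sensitivity %.3f, specificity %.3f", m$sensitivity, m$specificity))
    }
    cat("\n  confusion (rows = truth):\n")
    print(x$confusion)
  }
  invisible(x)
}

#' Odds ratios from a logistic model
#'
#' One logistic regression of group (second level = event) on the selected
#' features jointly, plus optional covariates; per-feature odds ratio
#' `exp(coefficient)` with Wald 95% confidence interval. Features under
#' (quasi-)perfect separation are flagged and their OR reported missing.
#'
#' @param ds an [omics_data] with exactly 2 groups.
#' @param features feature ids to include (complete columns).
#' @param covariate_names optional covariates added to the model.
#' @return A tibble: `term`, `estimate` (log odds), `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `separation` flag.
#' @export
odds_ratios <- function(ds, features, covariate_names = NULL) {
  check_groups(ds, exactly = 2)
  unknown <- setdiff(features, feature_ids(ds))
  if (length(unknown)) abort(paste0("Unknown feature(s): ", paste(unknown, collapse = ", ")))
  if (anyNA(ds$values[, features])) abort("Selected features contain missing values.")
  dat <- as.data.frame(ds$values[, features, drop = FALSE])
  cvn <- covariate_names %||% character()
  cv <- covariates(ds)
  missing_cv <- setdiff(cvn, names(cv))
  if (length(missing_cv)) abort(paste0("Unknown covariate(s): ", paste(missing_cv, collapse = ", ")))
  for (nm in cvn) dat[[nm]] <- cv[[nm]]
  dat$.y <- as.integer(groups(ds) == levels(groups(ds))[2])
  fit <- suppressWarnings(glm(.y ~ ., data = dat, family = binomial()))
  sm <- summary(fit)$coefficients
  sep <- !fit$converged | abs(coef(fit)) > 15 | sm[, "Std. Error"] > 100
  if (any(sep[features], na.rm = TRUE)) {
    warn(paste0("(Quasi-)perfect separation; OR reported missing for: ",
                paste(features[sep[features]], collapse = ", ")))
  }
  rows <- intersect(rownames(sm), c(features, cvn))
  est <- unname(sm[rows, "Estimate"]); se <- unname(sm[rows, "Std. Error"])
  sep_r <- unname(sep[rows])
  tibble::tibble(
    term = rows,
    estimate = ifelse(sep_r, NA_real_, est),
    odds_ratio = exp(ifelse(sep_r, NA_real_, est)),
    ci_low = exp(ifelse(sep_r, NA_real_, est - qnorm(0.975) * se)),
    ci_high = exp(ifelse(sep_r, NA_real_, est + qnorm(0.975) * se)),
    p_value = ifelse(sep_r, NA_real_, unname(sm[rows, "Pr(>|z|)"])),
    separation = sep_r)
}
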