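test_that("train/test splits are stratified, disjoint and reproducible", {
  ds <- gauss_ds(c(10, 10), p = 5, seed = 2)
  sp <- split_train_test(ds, test_prop = 0.2, seed = 7)
  expect_equal(n_samples(sp$test), 4)
  expect_equal(as.integer(table(groups(sp$test))), c(2L, 2L))
  expect_length(intersect(sample_ids(sp$train), sample_ids(sp$test)), 0)
  expect_setequal(c(sample_ids(sp$train), sample_ids(sp$test)), sample_ids(ds))

  sp2 <- split_train_test(ds, test_prop = 0.2, seed = 7)
  expect_identical(sample_ids(sp2$test), sample_ids(sp$test))

  none <- split_train_test(ds, test_prop = 0)
  expect_null(none$test)
  expect_equal(n_samples(none$train), 20)

  expect_warning(tiny <- split_train_test(ds, test_prop = 0.05, seed = 1), "empty test")
  expect_null(tiny$test)
  expect_error(split_train_test(ds, test_prop = 1), "\\[0, 1\\)")
})

test_that("penalty extremes behave as the elastic-net theory dictates", {
  ds <- gauss_ds(c(15, 15), p = 20, shift = 2, shifted_features = 1:3, seed = 4)
  # ridge never sparsifies
  ridge <- regularized_logistic(ds, alpha = 0, test_prop = 0, seed = 1)
  expect_true(all(ridge$coefficients$estimate != 0))

  # lasso at lambda >= lambda_max keeps only the intercept
  lasso <- regularized_logistic(ds, alpha = 1, test_prop = 0, seed = 1)
  lam_max <- max(lasso$model$lambda)
  co <- coef(lasso$model$glmnet.fit, s = lam_max)
  expect_true(all(abs(co[-1]) < 1e-10))

  # the lasso path is non-increasing in nonzero count with lambda (allowing ties)
  nz <- lasso$model$nzero
  lam <- lasso$model$lambda
  expect_true(all(diff(nz[order(lam, decreasing = TRUE)]) >= 0))
})

test_that("held-out evaluation uses only unseen samples", {
  ds <- gauss_ds(c(15, 15), p = 20, shift = 3, shifted_features = 1:5, seed = 5)
  pe <- regularized_logistic(ds, alpha = 1, test_prop = 0.2, seed = 9)
  expect_length(intersect(pe$split$train_ids, pe$split$test_ids), 0)
  expect_setequal(c(pe$split$train_ids, pe$split$test_ids), sample_ids(ds))
  expect_equal(sum(pe$confusion), length(pe$split$test_ids))
  expect_equal(pe$metrics$accuracy, sum(diag(pe$confusion)) / sum(pe$confusion))

  rf <- random_forest_eval(ds, n_trees = 100, test_prop = 0.2, seed = 9)
  expect_length(intersect(rf$split$train_ids, rf$split$test_ids), 0)
  expect_equal(sum(rf$confusion), length(rf$split$test_ids))
  expect_error(random_forest_eval(ds, test_prop = 0), "nonempty test")
})

test_that("random forests solve separated blobs and rank the informative feature", {
  ds <- gauss_ds(c(15, 15), p = 10, shift = 10, shifted_features = 1:2, seed = 6)
  rf <- random_forest_eval(ds, n_trees = 100, test_prop = 0.25, seed = 3)
  expect_equal(rf$metrics$accuracy, 1)

  ds2 <- gauss_ds(c(20, 20), p = 21, shift = 3, shifted_features = 1, seed = 7)
  rf2 <- random_forest_eval(ds2, n_trees = 200, test_prop = 0.2, seed = 3)
  expect_equal(rf2$coefficients$term[1], "f01")
})

test_that("prediction metrics match the exact binomial interval", {
  perfect <- matrix(c(5, 0, 0, 5), 2, 2)
  m <- prediction_metrics(perfect)
  expect_equal(m$accuracy, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$ci_high, 1)

  # 8 correct of 10: Clopper-Pearson CI (0.444, 0.975)
  m8 <- prediction_metrics(matrix(c(4, 1, 1, 4), 2, 2))
  expect_equal(m8$accuracy, 0.8)
  expect_equal(round(m8$ci_low, 3), 0.444)
  expect_equal(round(m8$ci_high, 3), 0.975)
  # independent oracle: binom.test's exact interval
  bt <- binom.test(8, 10)$conf.int
  expect_equal(m8$ci_low, bt[1], tolerance = 1e-10)
  expect_equal(m8$ci_high, bt[2], tolerance = 1e-10)

  anti <- prediction_metrics(matrix(c(0, 5, 5, 0), 2, 2))
  expect_equal(anti$accuracy, 0)
  expect_equal(anti$ci_low, 0)
  expect_error(prediction_metrics(matrix(0, 2, 2)), "empty")
  expect_error(prediction_metrics(matrix(1, 2, 3)), "square")
})

test_that("odds ratios reproduce the contingency identity and scaling law", {
  # dichotomized feature with a = 6, b = 2, c = 2, d = 6: OR = ad/bc = 9
  g <- rep(c("ctl", "case"), each = 8)
  x <- c(rep(1, 2), rep(0, 6),   # controls: 2 exposed
         rep(1, 6), rep(0, 2))   # cases: 6 exposed
  ds <- make_ds(cbind(f = x), g)
  or <- odds_ratios(ds, "f")
  expect_equal(or$odds_ratio, 9, tolerance = 1e-6)

  # doubling the feature scale halves the log odds coefficient
  ds2 <- gauss_ds(c(12, 12), p = 2, shift = 1, shifted_features = 1, seed = 8)
  or1 <- odds_ratios(ds2, "f01")
  ds2x <- ds2; ds2x$values[, "f01"] <- 2 * ds2x$values[, "f01"]
  or2 <- odds_ratios(ds2x, "f01")
  expect_equal(or2$estimate, or1$estimate / 2, tolerance = 1e-6)

  # perfect separation is flagged with a missing OR
  sep <- make_ds(cbind(f = c(1:8, 101:108)), rep(c("A", "B"), each = 8))
  expect_warning(ors <- odds_ratios(sep, "f"), "separation")
  expect_true(is.na(ors$odds_ratio))

  expect_error(odds_ratios(ds2, "nope"), "Unknown feature")
})

test_that("null odds-ratio confidence intervals cover 1 at the nominal rate", {
  cover <- vapply(1:100, function(s) {
    withr::with_seed(1000 + s, {
      ds <- make_ds(cbind(f = rnorm(40)), rep(c("A", "B"), each = 20))
      or <- odds_ratios(ds, "f")
      or$ci_low <= 1 && or$ci_high >= 1
    })
  }, logical(1))
  expect_gte(mean(cover), 0.88)
})
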