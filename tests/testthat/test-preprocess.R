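test_that("zero recoding distinguishes true zeros from missing", {
  m <- cbind(f1 = c(0, 1, 2), f2 = c(3, 0, 4), fE = c(0, 0, 5))
  ds <- make_ds(m, c("A", "A", "B"))
  out <- recode_zeros(ds)
  expect_equal(sum(is.na(out$values)), 4)

  same <- recode_zeros(ds, zeros_as_missing = FALSE)
  expect_identical(same$values, ds$values)

  ex <- recode_zeros(ds, exempt_features = "fE")
  expect_equal(sum(is.na(ex$values)), 2)
  expect_equal(unname(ex$values[, "fE"]), c(0, 0, 5))
})

test_that("missingness filter applies the every-group rule", {
  g <- rep(c("A", "B"), each = 4)
  m <- cbind(
    keep_one_side = c(NA, NA, 1, 1, 1, 1, 1, 1),   # 50% in A, 0% in B -> kept
    drop_both = c(NA, 1, 1, 1, NA, 1, 1, 1),       # 25% in both -> removed at 0.20
    all_missing = rep(NA_real_, 8),                # removed for any cutoff < 1
    clean = 1:8)
  ds <- make_ds(m, g)
  out <- filter_missing(ds, 0.20)
  expect_setequal(removed_features(out), c("drop_both", "all_missing"))
  expect_true("keep_one_side" %in% feature_ids(out))

  # rule = "any" removes as soon as one group exceeds the cutoff
  out_any <- filter_missing(ds, 0.20, rule = "any")
  expect_setequal(removed_features(out_any), c("keep_one_side", "drop_both", "all_missing"))

  # boundary cutoffs
  expect_setequal(removed_features(filter_missing(ds, 1.0)), "all_missing")
  expect_setequal(removed_features(filter_missing(ds, 0.0)),
                  c("drop_both", "all_missing"))
  expect_error(filter_missing(ds, 1.2), "cutoff")
})

test_that("missingness filter matches a brute-force per-group recount", {
  withr::with_seed(42, {
    for (i in 1:50) {
      g <- sample(rep(c("A", "B", "C"), times = c(4, 5, 3)))
      m <- matrix(rnorm(12 * 8), 12, 8, dimnames = list(NULL, paste0("f", 1:8)))
      m[runif(96) < 0.3] <- NA
      cutoff <- runif(1)
      ds <- make_ds(m, g)
      out <- filter_missing(ds, cutoff)
      brute <- colnames(m)[vapply(seq_len(ncol(m)), function(j) {
        all(vapply(unique(g), function(lv) {
          mean(is.na(m[g == lv, j])) > cutoff
        }, logical(1)))
      }, logical(1))]
      expect_setequal(removed_features(out), brute)
    }
  })
})

test_that("simple imputation methods fill per-feature summaries", {
  m <- cbind(a = c(2, 4, NA), b = c(1, 3, NA), c = c(5, NA, 7))
  ds <- make_ds(m, c("A", "A", "B"))
  expect_equal(unname(impute(ds, "half_min")$values[, "a"]), c(2, 4, 1))
  expect_equal(unname(impute(ds, "median")$values[, "b"]), c(1, 3, 2))
  expect_equal(unname(impute(ds, "mean")$values[, "c"]), c(5, 6, 7))
  expect_equal(unname(impute(ds, "min")$values[, "a"]), c(2, 4, 2))
  expect_equal(unname(impute(ds, "zero")$values[, "a"]), c(2, 4, 0))

  # all methods leave no missing cells and are idempotent
  for (meth in c("zero", "half_min", "median", "mean", "min", "knn")) {
    done <- impute(ds, meth, k = 1)
    expect_false(anyNA(done$values))
    expect_identical(impute(done, meth, k = 1)$values, done$values)
  }

  allmiss <- make_ds(cbind(a = c(NA, NA, NA), b = 1:3), c("A", "A", "B"))
  expect_error(impute(allmiss, "mean"), "entirely missing")
  expect_false(anyNA(impute(allmiss, "zero")$values))
})

test_that("knn imputation copies from an identical twin at k = 1", {
  m <- rbind(s1 = c(1, 2, 3, 4),
             s2 = c(1, 2, 3, NA),   # twin of s1 on observed features
             s3 = c(9, 9, 9, 9),
             s4 = c(8, 9, 9, 9),
             s5 = c(5, 5, 5, 5),
             s6 = c(4, 6, 5, 5))
  colnames(m) <- paste0("f", 1:4)
  ds <- make_ds(m, rep(c("A", "B"), 3))
  out <- impute(ds, "knn", k = 1)
  expect_equal(out$values["s2", "f4"], 4)
})

test_that("normalization methods match their closed forms", {
  m3 <- cbind(x = c(1, 2, 3))
  ds3 <- make_ds(m3, c("A", "A", "B"))
  expect_equal(unname(normalize(ds3, "autoscale")$values[, "x"]), c(-1, 0, 1))
  expect_equal(unname(normalize(ds3, "vast")$values[, "x"]), c(-2, 0, 2))
  ds_level <- make_ds(cbind(x = c(2, 4, 6)), c("A", "A", "B"))
  expect_equal(unname(normalize(ds_level, "level")$values[, "x"]), c(-0.5, 0, 0.5))
  expect_equal(unname(normalize(ds3, "log")$values[, "x"]), log(c(2, 3, 4)))

  lp <- normalize(ds3, "log_pareto")$values[, "x"]
  l <- log1p(c(1, 2, 3))
  expect_equal(unname(lp), (l - mean(l)) / sqrt(sd(l)))

  # scaling invariants on random data
  ds <- gauss_ds(c(6, 6), p = 12, seed = 2)
  ds$values <- abs(ds$values) + 1
  for (meth in c("autoscale", "log_scale")) {
    z <- normalize(ds, meth)$values
    expect_lt(max(abs(colMeans(z))), 1e-10)
    expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-8)
  }

  # constant features are dropped with a warning; negatives break log methods
  dsc <- make_ds(cbind(const = c(5, 5, 5), ok = c(1, 2, 3)), c("A", "A", "B"))
  expect_warning(out <- normalize(dsc, "autoscale"), "const")
  expect_equal(feature_ids(out), "ok")
  dsn <- make_ds(cbind(x = c(-1, 2, 3)), c("A", "A", "B"))
  expect_error(normalize(dsn, "log_pareto"), "Negative")
  expect_error(normalize(make_ds(cbind(x = c(1, NA, 3)), c("A", "A", "B")), "autoscale"),
               "missing")
})

test_that("the Tukey fence matches the hand-computed quartile example", {
  # distances 1,2,3,4,100: Q3 = 4, IQR = 2 -> fence 7 at x = 1.5
  expect_equal(tukey_fence(c(1, 2, 3, 4, 100), x = 1.5), 7)
  expect_equal(tukey_fence(c(1, 2, 3, 4, 100), x = 3), 10)
})

test_that("outlier detection flags a planted outlier and respects geometry", {
  ds <- generate_fixture(fixture_preset("outlier_one", seed = 4))
  proc <- normalize(ds, "log")
  res <- detect_outliers(proc)
  expect_true(fixture_truth(ds)$outlier_samples %in% outlier_ids(res))
  expect_true(all(res$samples$distance >= 0))
  expect_identical(res$samples$outlier,
                   res$samples$distance > res$samples$fence)

  # all samples identical: zero distances, zero fences, no flags
  same <- make_ds(matrix(1, 8, 5), rep(c("A", "B"), each = 4))
  res0 <- detect_outliers(same)
  expect_equal(res0$samples$distance, rep(0, 8))
  expect_false(any(res0$samples$outlier))

  # increasing x never enlarges the flag set
  flags <- lapply(c(0.5, 1, 1.5, 2, 3), function(xx) {
    outlier_ids(detect_outliers(proc, x = xx))
  })
  for (i in seq_len(length(flags) - 1)) {
    expect_true(all(flags[[i + 1]] %in% flags[[i]]))
  }

  expect_error(detect_outliers(proc, metric = "mahalanobis"))
})

test_that("outlier removal delegates to sample subsetting", {
  ds <- generate_fixture(fixture_preset("outlier_one", seed = 9))
  proc <- normalize(ds, "log")
  res <- detect_outliers(proc)
  cleaned <- remove_outliers(proc, res)
  expect_equal(n_samples(cleaned), n_samples(proc) - length(outlier_ids(res)))
  # a rerun on the reduced data yields a valid result
  res2 <- detect_outliers(cleaned)
  expect_s3_class(res2, "outlier_result")

  none <- detect_outliers(make_ds(matrix(1, 8, 4), rep(c("A", "B"), each = 4)))
  ident <- remove_outliers(proc, none)
  expect_equal(n_samples(ident), n_samples(proc))
})

test_that("a singleton group is never flagged", {
  ds <- gauss_ds(c(6, 6), p = 8, seed = 3)
  ds$samples$group <- factor(c(rep("A", 6), rep("B", 5), "C"),
                             levels = c("A", "B", "C"))
  expect_warning(res <- detect_outliers(ds), "fewer than 3")
  expect_false(res$samples$outlier[12])
})
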