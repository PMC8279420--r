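test_that("two-CSV loading honours the input contract", {
  target <- tibble::tibble(sample = c("s1", "s2", "s3"), group = c("A", "A", "B"))
  features <- tibble::as_tibble(matrix(1:12, 3, 4, dimnames = list(NULL, paste0("f", 1:4))))
  paths <- write_two_csv(target, features)
  ds <- read_omics(paths$target, paths$features)
  expect_equal(n_samples(ds), 3)
  expect_equal(n_features(ds), 4)
  expect_equal(ncol(covariates(ds)), 0)
  expect_equal(levels(groups(ds)), c("A", "B"))

  # covariates start at the third column, order preserved
  target2 <- dplyr::mutate(target, age = c(30, 40, 50), sex = c("m", "f", "f"))
  paths2 <- write_two_csv(target2, features)
  ds2 <- read_omics(paths2$target, paths2$features)
  expect_equal(names(covariates(ds2)), c("age", "sex"))

  # row-count mismatch is an alignment error
  paths3 <- write_two_csv(dplyr::bind_rows(target, tibble::tibble(sample = "s4", group = "B")),
                          features)
  expect_error(read_omics(paths3$target, paths3$features), "Row mismatch")

  # duplicate sample names refuse to load
  paths4 <- write_two_csv(dplyr::mutate(target, sample = c("s1", "s1", "s3")), features)
  expect_error(read_omics(paths4$target, paths4$features), "Duplicate")

  # a single group level loads with a warning recorded in the log
  paths5 <- write_two_csv(dplyr::mutate(target, group = "A"), features)
  expect_warning(ds5 <- read_omics(paths5$target, paths5$features), "fewer than 2")
  expect_true(any(grepl("fewer than 2 group levels", ds5$log)))
})

test_that("write/load round-trips values bit-exactly and keeps missingness", {
  ds <- generate_fixture(fixture_spec(n_per_group = c(4, 4), p_features = 10,
                                      missing_rate = 0.15, seed = 7))
  dir <- withr::local_tempdir()
  write_omics(ds, dir)
  ds2 <- read_omics(file.path(dir, "target.csv"), file.path(dir, "features.csv"))
  expect_identical(is.na(ds2$values), is.na(ds$values))
  expect_identical(ds2$values, ds$values)
  expect_identical(as.character(groups(ds2)), as.character(groups(ds)))
})

test_that("subset_samples filters consistently and validates ids", {
  ds <- gauss_ds(c(3, 3), p = 5)
  all_ids <- sample_ids(ds)
  same <- subset_samples(ds, all_ids)
  expect_identical(same$values, ds$values)
  expect_identical(same$samples, ds$samples)

  two <- subset_samples(ds, all_ids[c(2, 5)])
  expect_equal(n_samples(two), 2)
  expect_equal(length(groups(two)), 2)
  expect_identical(two$values, ds$values[c(2, 5), ])

  expect_error(subset_samples(ds, c(all_ids[1], "sampleX")), "sampleX")
})

test_that("combine_features merges constituents and reports CV", {
  m <- cbind(f1 = c(2, 4), f2 = c(4, 8), f3 = c(10, 20))
  ds <- make_ds(m, c("A", "B"))
  gmap <- tibble::tibble(feature_id = c("f1", "f2"), entity_id = "e1")
  res <- combine_features(ds, gmap, method = "mean")
  expect_equal(unname(res$values[, "e1"]), c(3, 6))
  expect_equal(unname(res$values[, "f3"]), c(10, 20))  # unmapped passthrough

  # sum method with the hand-computed CV of constituent means
  m2 <- cbind(f1 = c(1, 1), f2 = c(3, 3))
  ds2 <- make_ds(m2, c("A", "B"))
  res2 <- combine_features(ds2, tibble::tibble(feature_id = c("f1", "f2"),
                                               entity_id = "e"), method = "sum")
  expect_equal(unname(res2$values[, "e"]), c(4, 4))
  expect_equal(cv_table(res2)$cv, sd(c(1, 3)) / mean(c(1, 3)))
  expect_equal(cv_table(res2)$cv, sqrt(2) / 2, tolerance = 1e-12)

  # singleton entity: identical column, CV over that column's sample values
  res3 <- combine_features(ds, tibble::tibble(feature_id = "f3", entity_id = "solo"),
                           method = "mean")
  expect_equal(unname(res3$values[, "solo"]), c(10, 20))
  expect_equal(cv_table(res3)$n_constituents, 1L)
  expect_equal(cv_table(res3)$cv, sd(c(10, 20)) / mean(c(10, 20)))

  expect_error(combine_features(ds, tibble::tibble(feature_id = "nope", entity_id = "e"),
                                "mean"), "unknown feature")

  # missing values excluded; all-missing stays missing
  m4 <- cbind(f1 = c(2, NA), f2 = c(4, NA))
  res4 <- combine_features(make_ds(m4, c("A", "B")),
                           tibble::tibble(feature_id = c("f1", "f2"), entity_id = "e"),
                           method = "mean")
  expect_equal(unname(res4$values[, "e"]), c(3, NA))
})

test_that("singleton-entity mean combination is an identity on the matrix", {
  ds <- gauss_ds(c(4, 4), p = 6, seed = 3)
  gmap <- tibble::tibble(feature_id = feature_ids(ds), entity_id = feature_ids(ds))
  res <- combine_features(ds, gmap, method = "mean")
  expect_equal(unname(res$values[, feature_ids(ds)]), unname(ds$values))
})
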