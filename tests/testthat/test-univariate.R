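test_that("t-tests match hand computations and refuse bad designs", {
  # identical groups (non-constant values): t = 0, p = 1
  m <- cbind(f = c(1, 2, 3, 1, 2, 3))
  ds <- make_ds(m, rep(c("A", "B"), each = 3))
  tt <- ttest_all(ds)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)

  # Welch on A = 1:3 vs B = 4:6 (hand computation: |t| = 3.674, df = 4)
  ds2 <- make_ds(cbind(f = c(1, 2, 3, 4, 5, 6)), rep(c("A", "B"), each = 3))
  tt2 <- ttest_all(ds2)
  expect_equal(abs(tt2$statistic), 3.6742346, tolerance = 1e-6)
  expect_equal(tt2$df, 4)
  expect_equal(tt2$p_value, 0.021312, tolerance = 1e-4)
  expect_equal(tt2$direction, "up")

  # group means 4 and 8 give log2 fold change 1
  ds3 <- make_ds(cbind(f = c(3, 4, 5, 7, 8, 9)), rep(c("A", "B"), each = 3))
  expect_equal(ttest_all(ds3)$log2_fc, 1)

  # Welch equals Student when variances and sizes are equal
  x <- rnorm(8)
  ds4 <- make_ds(cbind(f = c(x, x + 5)), rep(c("A", "B"), each = 8))
  expect_lt(abs(ttest_all(ds4, var_equal = FALSE)$p_value -
                ttest_all(ds4, var_equal = TRUE)$p_value), 1e-12)

  # paired with zero-variance differences is degenerate: p missing + warning
  ds5 <- make_ds(cbind(f = c(1, 2, 3, 2, 3, 4)), rep(c("A", "B"), each = 3))
  expect_warning(tt5 <- ttest_all(ds5, paired = TRUE), "degenerate")
  expect_true(is.na(tt5$p_value))

  three <- make_ds(matrix(rnorm(9), 9, 1), rep(c("A", "B", "C"), each = 3))
  expect_error(ttest_all(three), "exactly 2")
  expect_error(ttest_all(make_ds(cbind(f = 1:5), c("A", "A", "A", "B", "B")),
                         paired = TRUE), "equal group sizes")
})

test_that("Mann-Whitney agrees with exact enumeration and rank properties", {
  # A = 1:3, B = 4:6: U = 0, exact two-sided p = 2 * (1/20) = 0.1
  ds <- make_ds(cbind(f = c(1, 2, 3, 4, 5, 6)), rep(c("A", "B"), each = 3))
  mw <- mannwhitney_all(ds)
  expect_equal(mw$p_value, 0.1)

  # identical groups: p near 1
  ds2 <- make_ds(cbind(f = c(1, 2, 3, 1, 2, 3)), rep(c("A", "B"), each = 3))
  expect_gt(mannwhitney_all(ds2)$p_value, 0.9)

  # invariance under strictly monotone transforms
  ds3 <- gauss_ds(c(7, 7), p = 4, seed = 5)
  ds3$values <- abs(ds3$values) + 0.1
  ds3t <- ds3; ds3t$values <- exp(ds3$values * 3)
  expect_equal(mannwhitney_all(ds3)$p_value, mannwhitney_all(ds3t)$p_value)
})

test_that("ANOVA matches hand sums of squares and the two-group t identity", {
  # groups [1,2], [5,6], [9,10]: SSB = 64, SSW = 1.5, F = 64
  ds <- make_ds(cbind(f = c(1, 2, 5, 6, 9, 10)), rep(c("A", "B", "C"), each = 2))
  a <- anova_all(ds)
  expect_equal(a$statistic, 64)
  expect_equal(a$df, 2)
  expect_equal(a$p_value, pf(64, 2, 3, lower.tail = FALSE))

  # with two groups, F equals the squared equal-variance t
  ds2 <- gauss_ds(c(6, 6), p = 5, seed = 8)
  expect_equal(anova_all(ds2)$statistic,
               ttest_all(ds2, var_equal = TRUE)$statistic^2,
               tolerance = 1e-10)
})

test_that("ANCOVA tests the group term against the covariate-only model", {
  withr::with_seed(21, {
    n <- 20
    g <- rep(c("A", "B"), each = n / 2)
    # balanced covariate, exactly orthogonal to the group indicator
    cov_bal <- rep(c(-1, 1), n / 2)
    y <- rnorm(n) + 2 * (g == "B")
    ds <- make_ds(cbind(f = y), g, covariates = tibble::tibble(z = cov_bal))
    an <- ancova_all(ds, "z")
    plain <- anova_all(ds)
    # orthogonal near-null covariate leaves the group effect essentially unchanged
    expect_equal(an$p_value, plain$p_value, tolerance = 0.5)
    expect_lt(an$p_value, 0.01)

    # group effect fully explained by a confounded covariate -> large p
    conf <- as.numeric(g == "B")
    y2 <- rnorm(n, sd = 0.2) + 3 * conf
    ds2 <- make_ds(cbind(f = y2), g, covariates = tibble::tibble(z = conf + rnorm(n, sd = 1e-3)))
    an2 <- ancova_all(ds2, "z")
    expect_gt(an2$p_value, 0.05)
    expect_lt(anova_all(ds2)$p_value, 1e-6)

    # y an exact function of the covariate, no group effect: group p large
    zc <- rnorm(n)
    y3 <- 2 * zc + rnorm(n, sd = 1e-6)
    ds3 <- make_ds(cbind(f = y3), g, covariates = tibble::tibble(z = zc))
    expect_gt(ancova_all(ds3, "z")$p_value, 0.2)

    # perfectly collinear covariate: warning, p missing
    ds4 <- make_ds(cbind(f = y), g, covariates = tibble::tibble(z = as.numeric(g == "B")))
    expect_warning(an4 <- ancova_all(ds4, "z"), "rank-deficient")
    expect_true(is.na(an4$p_value))
  })
  expect_error(ancova_all(gauss_ds(c(4, 4), p = 2), "age"), "not found")
})

test_that("Kruskal-Wallis matches the direct rank formula", {
  # groups [1,2], [3,4], [5,6]: no ties, H computed from mean ranks
  ds <- make_ds(cbind(f = 1:6), rep(c("A", "B", "C"), each = 2))
  kw <- kruskal_all(ds)
  h_hand <- 12 / (6 * 7) * (2 * 1.5^2 + 2 * 3.5^2 + 2 * 5.5^2) - 3 * 7
  expect_equal(kw$statistic, h_hand)
  expect_equal(kw$p_value, pchisq(h_hand, 2, lower.tail = FALSE))

  # all values tied: H = 0 convention, p = 1
  tied <- make_ds(cbind(f = rep(2, 6)), rep(c("A", "B"), each = 3))
  kwt <- kruskal_all(tied)
  expect_equal(kwt$statistic, 0)
  expect_equal(kwt$p_value, 1)

  # two-group Kruskal-Wallis tracks the Mann-Whitney normal approximation
  ds2 <- gauss_ds(c(20, 20), p = 10, shift = 0.8, shifted_features = 1:5, seed = 13)
  expect_equal(kruskal_all(ds2)$p_value, mannwhitney_all(ds2)$p_value,
               tolerance = 0.02)
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.3), 0.3)
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_fdr(c(0.5, NA, 0.01)), c(0.5, NA, 0.02))
  expect_error(adjust_fdr(c(0.1, 1.4)), "\\[0, 1\\]")

  # brute-force oracle: q_i = min_{j >= i} m p_(j) / j, capped at 1
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    s <- p[o]
    q <- numeric(m)
    for (i in seq_len(m)) q[o[i]] <- min(1, min(m * s[i:m] / (i:m)))
    q
  }
  withr::with_seed(99, {
    for (rep in 1:200) {
      p <- runif(sample(1:40, 1))
      expect_equal(adjust_fdr(p), bh_oracle(p), tolerance = 1e-12)
    }
  })
})

test_that("adjusted p-values never fall below raw p-values in test tables", {
  ds <- gauss_ds(c(8, 8), p = 25, shift = 1, shifted_features = 1:5, seed = 2)
  for (tab in list(ttest_all(ds), mannwhitney_all(ds), anova_all(ds), kruskal_all(ds))) {
    expect_true(all(tab$p_adjusted >= tab$p_value - 1e-12, na.rm = TRUE))
    expect_true(all(tab$p_adjusted <= 1, na.rm = TRUE))
    expect_equal(nrow(tab), n_features(ds))
  }
})
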