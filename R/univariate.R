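#' Per-feature t-tests
#'
#' Two-sample t-test per feature: Welch by default (`var_equal = FALSE`),
#' Student when `var_equal = TRUE`, paired when `paired = TRUE` (pairs
#' matched by position within group). Two-sided throughout; raw p-values
#' are Benjamini–Hochberg adjusted within the table. Fold change is
#' second group level over first (first-appearance ordering).
#'
#' @param ds an [omics_data] with exactly 2 groups, n >= 2 per group.
#' @param paired paired test (requires equal group sizes).
#' @param var_equal pool the variance (Student) instead of Welch.
#' @return A `test_table` tibble: per feature the group means, fold change,
#'   log2 fold change, statistic, degrees of freedom, `p_value`,
#'   `p_adjusted` and direction.
#' @export
ttest_all <- function(ds, paired = FALSE, var_equal = FALSE) {
  check_groups(ds, exactly = 2)
  g <- groups(ds)
  i1 <- g == levels(g)[1]; i2 <- g == levels(g)[2]
  if (sum(i1) < 2 || sum(i2) < 2) abort("Need at least 2 samples per group.")
  if (paired && sum(i1) != sum(i2)) abort("Paired tests need equal group sizes.")
  res <- purrr::map_dfr(feature_ids(ds), function(f) {
    x1 <- ds$values[i1, f]; x2 <- ds$values[i2, f]
    tt <- tryCatch(
      t.test(x2, x1, paired = paired, var.equal = var_equal),
      error = function(e) NULL)
    if (is.null(tt)) {
      warn(sprintf("Feature %s: degenerate t-test (constant data); p set to missing.", f))
    }
    tibble::tibble(
      feature = f,
      mean_1 = mean(x1, na.rm = TRUE), mean_2 = mean(x2, na.rm = TRUE),
      statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
      p_value = if (is.null(tt)) NA_real_ else tt$p.value)
  })
  finish_test_table(res, sprintf("t-test (%s%s)",
                                 if (paired) "paired" else if (var_equal) "Student" else "Welch",
                                 if (paired) "" else ", two-sample"),
                    levels(g))
}

#' Per-feature Mann-Whitney / Wilcoxon tests
#'
#' Unpaired: Mann-Whitney U (Wilcoxon rank-sum); exact p when both groups
#' have at most 8 samples and the feature has no ties, otherwise the normal
#' approximation with tie correction. Paired: Wilcoxon signed-rank on the
#' within-pair differences.
#'
#' @inheritParams ttest_all
#' @return A `test_table` tibble (group medians instead of means feed the
#'   direction call; means are still reported for fold change).
#' @export
mannwhitney_all <- function(ds, paired = FALSE) {
  check_groups(ds, exactly = 2)
  g <- groups(ds)
  i1 <- g == levels(g)[1]; i2 <- g == levels(g)[2]
  if (paired && sum(i1) != sum(i2)) abort("Paired tests need equal group sizes.")
  res <- purrr::map_dfr(feature_ids(ds), function(f) {
    x1 <- ds$values[i1, f]; x2 <- ds$values[i2, f]
    exact <- !paired && sum(i1) <= 8 && sum(i2) <= 8 && !anyDuplicated(c(x1, x2))
    wt <- tryCatch(
      suppressWarnings(wilcox.test(x2, x1, paired = paired, exact = exact)),
      error = function(e) NULL)
    tibble::tibble(
      feature = f,
      mean_1 = mean(x1), mean_2 = mean(x2),
      median_1 = median(x1), median_2 = median(x2),
      statistic = if (is.null(wt)) NA_real_ else unname(wt$statistic),
      df = NA_real_,
      p_value = if (is.null(wt)) NA_real_ else wt$p.value)
  })
  finish_test_table(res, if (paired) "Wilcoxon signed-rank" else "Mann-Whitney U", levels(g))
}

#' Per-feature one-way ANOVA
#'
#' One-way fixed-effects ANOVA per feature across all group levels (two
#' groups allowed, where F equals the squared equal-variance t).
#'
#' @param ds an [omics_data] with >= 2 groups and more samples than groups.
#' @return A `test_table` tibble with per-group means, F statistic and
#'   degrees of freedom.
#' @export
anova_all <- function(ds) {
  check_groups(ds, min_levels = 2)
  g <- groups(ds)
  if (n_samples(ds) <= nlevels(g)) abort("ANOVA needs more samples than groups.")
  res <- purrr::map_dfr(feature_ids(ds), function(f) {
    y <- ds$values[, f]
    a <- anova(lm(y ~ g))
    p <- a$`Pr(>F)`[1]
    if (is.na(p)) warn(sprintf("Feature %s: zero residual degrees of freedom; p missing.", f))
    tibble::tibble(feature = f,
                   statistic = a$`F value`[1], df = a$Df[1], df_resid = a$Df[2],
                   p_value = p)
  })
  means <- group_mean_table(ds)
  res <- dplyr::left_join(res, means, by = "feature")
  finish_test_table(res, "one-way ANOVA", levels(g), two_group_fc = nlevels(g) == 2)
}

#' Per-feature ANCOVA (group effect adjusted for covariates)
#'
#' Per feature, fits the linear model `y ~ covariates + group` and tests the
#' group term with the nested-model F-test against `y ~ covariates`.
#'
#' @param ds an [omics_data] with covariates.
#' @param covariate_names covariate columns to adjust for (default: all).
#' @return A `test_table` tibble with the group F statistic and p.
#' @export
ancova_all <- function(ds, covariate_names = NULL) {
  check_groups(ds, min_levels = 2)
  cv <- covariates(ds)
  covariate_names <- covariate_names %||% names(cv)
  missing_cv <- setdiff(covariate_names, names(cv))
  if (length(missing_cv) || !length(covariate_names)) {
    abort(paste0("Covariate(s) not found in the target file: ",
                 paste(missing_cv, collapse = ", ")))
  }
  dat <- as.data.frame(cv[covariate_names])
  for (nm in covariate_names) {
    if (is.character(dat[[nm]])) dat[[nm]] <- factor(dat[[nm]])
    if (is.factor(dat[[nm]]) && nlevels(droplevels(dat[[nm]])) < 2) {
      abort(sprintf("Categorical covariate %s has fewer than 2 levels.", nm))
    }
    if (is.numeric(dat[[nm]]) && any(!is.finite(dat[[nm]]))) {
      abort(sprintf("Covariate %s has non-finite values.", nm))
    }
  }
  dat$group <- groups(ds)
  fml_full <- stats::as.formula(paste("y ~", paste(c(covariate_names, "group"), collapse = " + ")))
  fml_red <- stats::as.formula(paste("y ~", paste(covariate_names, collapse = " + ")))
  res <- purrr::map_dfr(feature_ids(ds), function(f) {
    d <- dat; d$y <- ds$values[, f]
    full <- lm(fml_full, data = d)
    if (anyNA(coef(full))) {
      warn(sprintf("Feature %s: rank-deficient (collinear) design; p missing.", f))
      return(tibble::tibble(feature = f, statistic = NA_real_, df = NA_real_, p_value = NA_real_))
    }
    red <- lm(fml_red, data = d)
    a <- anova(red, full)
    tibble::tibble(feature = f, statistic = a$F[2], df = a$Df[2], p_value = a$`Pr(>F)`[2])
  })
  res <- dplyr::left_join(res, group_mean_table(ds), by = "feature")
  finish_test_table(res, paste0("ANCOVA (", paste(covariate_names, collapse = " + "), ")"),
                    levels(groups(ds)), two_group_fc = nlevels(groups(ds)) == 2)
}

#' Per-feature Kruskal-Wallis tests
#'
#' Rank-based comparison across all groups with tie-corrected H statistic
#' and a chi-square p-value. A feature with all values tied carries no rank
#' information: H is reported as 0 with p = 1.
#'
#' @param ds an [omics_data] with >= 2 groups.
#' @return A `test_table` tibble.
#' @export
kruskal_all <- function(ds) {
  check_groups(ds, min_levels = 2)
  g <- groups(ds)
  res <- purrr::map_dfr(feature_ids(ds), function(f) {
    y <- ds$values[, f]
    if (length(unique(y)) == 1) {
      return(tibble::tibble(feature = f, statistic = 0, df = nlevels(g) - 1, p_value = 1))
    }
    kt <- kruskal.test(y, g)
    tibble::tibble(feature = f, statistic = unname(kt$statistic),
                   df = unname(kt$parameter), p_value = kt$p.value)
  })
  res <- dplyr::left_join(res, group_mean_table(ds), by = "feature")
  finish_test_table(res, "Kruskal-Wallis", levels(g), two_group_fc = nlevels(g) == 2)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment via [stats::p.adjust()]: sort ascending,
#' `q_i = min_{j >= i} (m / j) p_(j)`, cap at 1, restore input order.
#' Missing p-values pass through unchanged and do not count toward `m`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values in the input order.
#' @export
adjust_fdr <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1].")
  out <- p
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

# ---- shared test-table plumbing --------------------------------------------

group_mean_table <- function(ds) {
  g <- groups(ds)
  out <- tibble::tibble(feature = feature_ids(ds))
  for (i in seq_along(levels(g))) {
    out[[paste0("mean_", i)]] <- colMeans(ds$values[g == levels(g)[i], , drop = FALSE])
  }
  out
}

finish_test_table <- function(res, method, group_levels, two_group_fc = TRUE) {
  if (two_group_fc && all(c("mean_1", "mean_2") %in% names(res))) {
    res$fold_change <- res$mean_2 / res$mean_1
    valid <- !is.na(res$mean_1) & !is.na(res$mean_2) & res$mean_1 > 0 & res$mean_2 > 0
    res$log2_fc <- NA_real_
    res$log2_fc[valid] <- log2(res$fold_change[valid])
    res$direction <- dplyr::case_when(
      is.na(res$p_value) ~ NA_character_,
      res$mean_2 > res$mean_1 ~ "up",
      res$mean_2 < res$mean_1 ~ "down",
      TRUE ~ "none")
  }
  res$p_adjusted <- adjust_fdr(res$p_value)
  res$method <- method
  attr(res, "group_levels") <- group_levels
  attr(res, "contrast") <- if (length(group_levels) == 2) {
    paste(group_levels[2], "vs", group_levels[1])
  } else {
    paste(group_levels, collapse = "/")
  }
  class(res) <- c("test_table", class(res))
  res
}

#' @export
print.test_table <- function(x, ...) {
  if ("method" %in% names(x) && !is.null(attr(x, "contrast"))) {
    cat("# Per-feature tests: ", x$method[1], "; contrast ", attr(x, "contrast"),
        "\n", sep = "")
  }
  NextMethod()
}
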