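#' Volcano table (t-test based)
#'
#' Per-feature two-sample t-test (Student, Welch or paired, same engine as
#' [ttest_all()]) with the log2 fold change of the second group level over
#' the first, computed on the current matrix. Where a group mean is not
#' positive (as can happen after normalization) the fold change is
#' reported missing. Features are classed `up` / `down` / `ns` by the
#' p-value and fold-change cutoffs.
#'
#' @inheritParams ttest_all
#' @param p_cutoff raw-p significance cutoff (default 0.05).
#' @param fc_cutoff absolute log2 fold-change cutoff (default 1).
#' @return A `volcano_table` tibble: `feature`, `log2_fc`, `p_value`,
#'   `neg_log10_p`, `class`.
#' @export
volcano_table <- function(ds, paired = FALSE, var_equal = FALSE,
                          p_cutoff = 0.05, fc_cutoff = 1) {
  tt <- ttest_all(ds, paired = paired, var_equal = var_equal)
  out <- tibble::tibble(
    feature = tt$feature,
    log2_fc = tt$log2_fc,
    p_value = tt$p_value,
    neg_log10_p = -log10(tt$p_value),
    class = dplyr::case_when(
      is.na(tt$p_value) | is.na(tt$log2_fc) ~ "ns",
      tt$p_value < p_cutoff & tt$log2_fc >= fc_cutoff ~ "up",
      tt$p_value < p_cutoff & tt$log2_fc <= -fc_cutoff ~ "down",
      TRUE ~ "ns"))
  attr(out, "contrast") <- attr(tt, "contrast")
  attr(out, "cutoffs") <- c(p = p_cutoff, fc = fc_cutoff)
  class(out) <- c("volcano_table", class(out))
  out
}

#' Per-feature, per-group distribution summaries
#'
#' Backs boxplot/density displays: one row per feature and group with the
#' five-number summary plus mean, sd and n (missing values excluded).
#'
#' @param ds an [omics_data].
#' @return A tibble: `feature`, `group`, `n`, `min`, `q1`, `median`, `q3`,
#'   `max`, `mean`, `sd`.
#' @export
feature_summaries <- function(ds) {
  stopifnot(is_omics_data(ds))
  as_tibble(ds) |>
    tidyr::pivot_longer(dplyr::all_of(feature_ids(ds)),
                        names_to = "feature", values_to = "value") |>
    dplyr::group_by(.data$feature, .data$group) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      min = suppressWarnings(min(.data$value, na.rm = TRUE)),
      q1 = quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
      median = median(.data$value, na.rm = TRUE),
      q3 = quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
      max = suppressWarnings(max(.data$value, na.rm = TRUE)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      .groups = "drop")
}

#' Clustered heatmap ordering
#'
#' Orders samples and/or features by agglomerative hierarchical clustering
#' (Euclidean distance, complete linkage by default) leaf order; with
#' clustering disabled the input order is kept. The returned matrix is the
#' input matrix with rows/columns permuted accordingly.
#'
#' @param ds a complete [omics_data].
#' @param cluster_samples,cluster_features cluster that margin.
#' @param distance,linkage dissimilarity and agglomeration method passed to
#'   [stats::dist()] / [stats::hclust()].
#' @return list with `matrix`, `sample_order`, `feature_order`.
#' @export
heatmap_matrix <- function(ds, cluster_samples = TRUE, cluster_features = TRUE,
                           distance = "euclidean", linkage = "complete") {
  stopifnot(is_omics_data(ds))
  if (anyNA(ds$values)) abort("Matrix has missing cells; impute first.")
  so <- seq_len(n_samples(ds))
  fo <- seq_len(n_features(ds))
  if (cluster_samples && n_samples(ds) > 2) {
    so <- hclust(dist(ds$values, method = distance), method = linkage)$order
  }
  if (cluster_features && n_features(ds) > 2) {
    fo <- hclust(dist(t(ds$values), method = distance), method = linkage)$order
  }
  list(matrix = ds$values[so, fo, drop = FALSE],
       sample_order = sample_ids(ds)[so],
       feature_order = feature_ids(ds)[fo])
}

#' Highly correlated feature pairs
#'
#' Scans all feature pairs for Pearson correlation at or beyond a
#' threshold (default `|r| >= 0.97`), a common pre-modelling redundancy
#' check.
#'
#' @param ds a complete [omics_data].
#' @param threshold absolute-correlation threshold (default 0.97).
#' @return An `edge_table` tibble of flagged pairs.
#' @export
high_correlations <- function(ds, threshold = 0.97) {
  correlation_network(ds, method = "pearson", threshold = threshold)
}

#' Automatic exploratory report
#'
#' Assembles the standard exploratory summary of a study: sample / feature /
#' covariate / group counts, total missing percentage, per-feature missing
#' counts, zero count, zero-variance features, before/after preprocessing
#' distribution summaries (k-NN imputation + log Pareto scaling defaults),
#' outlier analysis, the high-correlation scan (`|r| >= 0.97`), PCA scores
#' and the clustered-heatmap ordering — rendered to markdown. Given a
#' seed, regeneration is byte-identical.
#'
#' @param ds an [omics_data].
#' @param impute_method,normalize_method preprocessing defaults for the
#'   before/after section.
#' @param seed integer seed (report determinism contract).
#' @param path optional file to write the markdown to.
#' @return An `eda_report` list; `format()` yields the markdown lines.
#' @export
eda_report <- function(ds, impute_method = "knn", normalize_method = "log_pareto",
                       seed = NULL, path = NULL) {
  stopifnot(is_omics_data(ds))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("eda_report stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  run <- function() {
    m <- ds$values
    zero_var <- feature_ids(ds)[apply(m, 2, function(x) {
      v <- x[!is.na(x)]; length(v) > 0 && length(unique(v)) == 1
    })]
    counts <- list(samples = n_samples(ds), features = n_features(ds),
                   covariates = ncol(covariates(ds)), groups = nlevels(groups(ds)))
    missing_per_feature <- colSums(is.na(m))
    report <- list(
      counts = counts,
      missing_total_pct = 100 * sum(is.na(m)) / length(m),
      missing_per_feature = tibble::tibble(feature = feature_ids(ds),
                                           n_missing = unname(missing_per_feature)),
      n_zero = sum(m == 0, na.rm = TRUE),
      zero_variance_features = zero_var)
    report$before <- stage("summaries_before", feature_summaries(ds))
    proc <- stage("preprocess", {
      ds |> impute(impute_method) |> normalize(normalize_method)
    })
    report$after <- stage("summaries_after", feature_summaries(proc))
    report$outliers <- if (nlevels(groups(ds)) >= 1 && min(tabulate(groups(ds))) >= 3) {
      stage("outliers", detect_outliers(proc))
    } else NULL
    report$high_correlations <- stage("high_correlations", high_correlations(proc))
    report$pca <- stage("pca", pca(proc, ncomp = min(2, n_samples(proc) - 1)))
    report$heatmap <- stage("heatmap", heatmap_matrix(proc))
    report$params <- list(impute = impute_method, normalize = normalize_method, seed = seed)
    structure(report, class = "eda_report")
  }
  rep <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (!is.null(path)) writeLines(format(rep), path)
  rep
}

#' @export
format.eda_report <- function(x, ...) {
  c("# Exploratory data analysis report",
    "",
    "## Dataset",
    sprintf("- samples: %d", x$counts$samples),
    sprintf("- features: %d", x$counts$features),
    sprintf("- covariates: %d", x$counts$covariates),
    sprintf("- groups: %d", x$counts$groups),
    "",
    "## Missingness and zeros",
    sprintf("- total missing: %.1f%%", x$missing_total_pct),
    sprintf("- features with missing values: %d",
            sum(x$missing_per_feature$n_missing > 0)),
    sprintf("- zero cells: %d", x$n_zero),
    sprintf("- zero-variance features: %s",
            if (length(x$zero_variance_features)) {
              paste(x$zero_variance_features, collapse = ", ")
            } else "none"),
    "",
    sprintf("## Preprocessing (impute = %s, normalize = %s)",
            x$params$impute, x$params$normalize),
    sprintf("- distribution summaries: %d rows before, %d rows after",
            nrow(x$before), nrow(x$after)),
    "",
    "## Outliers",
    if (is.null(x$outliers)) "- skipped (groups too small)" else
      sprintf("- flagged: %s",
              if (length(outlier_ids(x$outliers))) {
                paste(outlier_ids(x$outliers), collapse = ", ")
              } else "none"),
    "",
    "## Highly correlated features (|r| >= 0.97)",
    sprintf("- pairs: %d", nrow(x$high_correlations)),
    "",
    "## PCA",
    sprintf("- explained variance: %s",
            paste(sprintf("%.1f%%", 100 * x$pca$explained_variance), collapse = ", ")),
    "",
    "## Heatmap ordering",
    sprintf("- sample order: %s", paste(x$heatmap$sample_order, collapse = ", ")),
    sprintf("- feature order: %s",
            paste(head(x$heatmap$feature_order, 20), collapse = ", ")))
}

#' @export
print.eda_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}
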