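#' Validate a pipeline configuration
#'
#' Parses a YAML file (or takes a list), checks it against the pipeline
#' schema, fills defaults, and reports *every* violation at once. Stages
#' must appear in workflow order (`preprocess`, `eda`, `univariate`,
#' `moderated`, `multivariate`, `correlation`, `predictive`, `rankprod`);
#' statistical stages on data that still contain missing values require
#' the preprocess stage first. Unknown top-level or stage keys are
#' rejected. A seed is mandatory so that every run is reproducible.
#'
#' @param config path to a YAML file, or a named list.
#' @return A validated `run_config` list with defaults filled.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("Config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || !length(config)) {
    abort(paste0("Empty or invalid config; required keys: ",
                 paste(c("input", "output_dir", "seed", "stages"), collapse = ", ")))
  }
  errors <- character()
  known_top <- c("input", "output_dir", "seed", "stages", "figures")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown)) errors <- c(errors, paste0("Unknown top-level key(s): ", paste(unknown, collapse = ", ")))
  for (key in c("input", "output_dir", "seed", "stages")) {
    if (is.null(config[[key]])) errors <- c(errors, paste0("Missing required key: ", key))
  }
  if (!is.null(config$input)) {
    for (key in c("target", "features")) {
      if (is.null(config$input[[key]])) errors <- c(errors, paste0("Missing input$", key))
    }
  }
  if (!is.null(config$seed) && (!is.numeric(config$seed) || length(config$seed) != 1)) {
    errors <- c(errors, "seed must be a single integer")
  }
  stage_order <- c("preprocess", "eda", "univariate", "moderated",
                   "multivariate", "correlation", "predictive", "rankprod")
  defaults <- list(
    preprocess = list(zeros_as_missing = TRUE, cutoff = 0.2, rule = "all",
                      impute = "knn", k = 5, normalize = "log_pareto",
                      outliers = TRUE, metric = "euclidean", coef = 1.5,
                      remove_outliers = FALSE),
    eda = list(),
    univariate = list(test = "auto", paired = FALSE, var_equal = FALSE),
    moderated = list(covariates = NULL),
    multivariate = list(method = "pca", ncomp = 2, cv = "kfold", folds = 5,
                        vip_cutoff = 1, keepX = 10, k = "auto", max_k = 10),
    correlation = list(method = "pearson", threshold = 0.7, rho = NULL),
    predictive = list(method = "lasso", alpha = 1, test_prop = 0.2,
                      nfolds = 10, n_trees = 500),
    rankprod = list(paired = FALSE, n_perm = 100, max_comparisons = 50))
  stages <- config$stages
  if (!is.null(stages)) {
    if (!is.list(stages) || is.null(names(stages)) || any(names(stages) == "")) {
      errors <- c(errors, "stages must be a named list of stage -> parameters")
      stages <- list()
    }
    bad <- setdiff(names(stages), stage_order)
    if (length(bad)) errors <- c(errors, paste0("Unknown stage(s): ", paste(bad, collapse = ", ")))
    ord <- match(intersect(names(stages), stage_order), stage_order)
    if (is.unsorted(ord, strictly = TRUE)) {
      errors <- c(errors, paste0("Stages out of workflow order; expected order: ",
                                 paste(stage_order, collapse = " -> ")))
    }
    stats_stages <- setdiff(names(stages), c("preprocess", "eda"))
    if (length(stats_stages) && !"preprocess" %in% names(stages)) {
      errors <- c(errors,
                  "Statistical stages require the preprocess stage (tests cannot run on incomplete data)")
    }
    for (nm in intersect(names(stages), stage_order)) {
      st <- stages[[nm]] %||% list()
      extra <- setdiff(names(st), names(defaults[[nm]]))
      if (length(extra)) {
        errors <- c(errors, paste0("Unknown key(s) in stage ", nm, ": ",
                                   paste(extra, collapse = ", ")))
      }
      stages[[nm]] <- modifyList(defaults[[nm]], st[intersect(names(st), names(defaults[[nm]]))])
    }
  }
  if (length(errors)) abort(paste0("Invalid config:\n- ", paste(errors, collapse = "\n- ")))
  structure(list(input = config$input, output_dir = config$output_dir,
                 seed = as.integer(config$seed), stages = stages,
                 figures = isTRUE(config$figures)),
            class = "run_config")
}

#' Run the full workflow and write a run directory
#'
#' Executes the configured stages in workflow order on the two-CSV input,
#' writing every result table as CSV, optional static figures, the
#' exploratory report as markdown, and a machine-readable `manifest.json`
#' (inputs, parameters, seed, package version, per-stage dimensions).
#' A rerun with the same config and seed — or a replay of the manifest via
#' [replay_manifest()] — reproduces the CSV outputs byte-identically.
#'
#' @param config path to YAML, a list, or a validated `run_config`.
#' @return Invisibly, the output directory path.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  out <- cfg$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  manifest <- list(package = "metabokit",
                   version = as.character(utils::packageVersion("metabokit")),
                   seed = cfg$seed, input = cfg$input, stages = list())
  ds <- read_omics(cfg$input$target, cfg$input$features)
  raw <- ds       # untouched input (EDA before/after section)
  prenorm <- ds   # imputed but not yet scaled (fold-change-based methods)
  write_table <- function(x, name) {
    readr::write_csv(tibble::as_tibble(x), file.path(out, paste0(name, ".csv")),
                     progress = FALSE)
  }
  record <- function(name, extra = list()) {
    manifest$stages[[name]] <<- c(list(n_samples = n_samples(ds),
                                       n_features = n_features(ds),
                                       params = cfg$stages[[name]]), extra)
  }
  fail <- function(name, e) {
    manifest$failed_stage <<- list(stage = name, message = conditionMessage(e))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
    abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
  }
  for (nm in names(cfg$stages)) {
    st <- cfg$stages[[nm]]
    tryCatch({
      switch(nm,
        preprocess = {
          ds <- recode_zeros(ds, st$zeros_as_missing)
          ds <- filter_missing(ds, cutoff = st$cutoff, rule = st$rule)
          write_table(tibble::tibble(feature = removed_features(ds)), "removed_features")
          ds <- impute(ds, st$impute, k = st$k)
          prenorm <- ds
          ds <- normalize(ds, st$normalize)
          if (isTRUE(st$outliers)) {
            ores <- detect_outliers(ds, metric = st$metric, x = st$coef)
            write_table(ores$samples, "outliers")
            if (isTRUE(st$remove_outliers)) {
              ds <- remove_outliers(ds, ores)
              prenorm <- subset_samples(prenorm, sample_ids(ds))
            }
          }
          write_omics(ds, out, prefix = "processed_")
          record("preprocess")
        },
        eda = {
          rep <- eda_report(raw, seed = cfg$seed, path = file.path(out, "eda_report.md"))
          write_table(feature_summaries(ds), "feature_summaries")
          if (nlevels(groups(ds)) == 2) write_table(volcano_table(ds), "volcano")
          record("eda")
        },
        univariate = {
          test <- st$test
          if (test == "auto") test <- if (nlevels(groups(ds)) == 2) "ttest" else "anova"
          tab <- switch(test,
            ttest = ttest_all(ds, paired = st$paired, var_equal = st$var_equal),
            mw = mannwhitney_all(ds, paired = st$paired),
            anova = anova_all(ds),
            ancova = ancova_all(ds),
            kw = kruskal_all(ds),
            abort(paste0("Unknown univariate test: ", test)))
          write_table(tab, paste0("univariate_", test))
          record("univariate", list(test = test))
        },
        moderated = {
          res <- limma_pipeline(ds, st$covariates)
          write_table(res$without_covariates, "moderated_without_covariates")
          write_table(res$with_covariates, "moderated_with_covariates")
          record("moderated")
        },
        multivariate = {
          mod <- switch(st$method,
            pca = pca(ds, ncomp = st$ncomp),
            plsda = plsda(ds, ncomp = st$ncomp, cv = st$cv, folds = st$folds,
                          vip_cutoff = st$vip_cutoff, seed = cfg$seed),
            splsda = splsda(ds, ncomp = st$ncomp, keepX = st$keepX, cv = st$cv,
                            folds = st$folds, seed = cfg$seed),
            abort(paste0("Unknown multivariate method: ", st$method)))
          write_table(mod$scores, paste0(st$method, "_scores"))
          write_table(mod$loadings, paste0(st$method, "_loadings"))
          if (!is.null(mod$vip)) write_table(mod$vip, "vip")
          cl <- kmeans_clusters(ds, k = st$k, max_k = min(st$max_k, n_samples(ds) - 1),
                                seed = cfg$seed)
          write_table(cl$assignments, "kmeans_assignments")
          write_table(cl$wss, "kmeans_wss")
          record("multivariate", list(k_chosen = cl$k))
        },
        correlation = {
          write_table(correlation_network(ds, method = st$method,
                                          threshold = st$threshold), "correlation_edges")
          if (!is.null(st$rho)) {
            gg <- ggm_network(ds, rho = st$rho)
            write_table(gg$edges, "ggm_edges")
          }
          record("correlation")
        },
        predictive = {
          pe <- switch(st$method,
            lasso = , elasticnet = , ridge =
              regularized_logistic(ds, alpha = st$alpha, test_prop = st$test_prop,
                                   nfolds = st$nfolds, seed = cfg$seed),
            rf = random_forest_eval(ds, n_trees = st$n_trees,
                                    test_prop = st$test_prop, seed = cfg$seed),
            abort(paste0("Unknown predictive method: ", st$method)))
          write_table(pe$coefficients, paste0("predictive_", st$method, "_coefficients"))
          if (!is.null(pe$metrics)) write_table(pe$metrics, paste0("predictive_", st$method, "_metrics"))
          record("predictive")
        },
        rankprod = {
          rp <- rank_products(prenorm, paired = st$paired, n_perm = st$n_perm,
                              max_comparisons = st$max_comparisons, seed = cfg$seed)
          write_table(rp$table, "rank_products")
          record("rankprod", list(n_comparisons = rp$n_comparisons))
        })
    }, error = function(e) fail(nm, e))
  }
  if (cfg$figures) write_figures(ds, cfg, out)
  manifest$config <- unclass(cfg)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(out)
}

# Static figures are best-effort: on a device-less system the tables and
# manifest are still the contract.
write_figures <- function(ds, cfg, out) {
  tryCatch({
    if (!capabilities("png")) {
      warn("No png device available; figures skipped.")
      return(invisible(NULL))
    }
    if (nlevels(groups(ds)) == 2) {
      ggplot2::ggsave(file.path(out, "volcano.png"), plot_volcano(volcano_table(ds)),
                      width = 6, height = 5, dpi = 120)
    }
    ggplot2::ggsave(file.path(out, "pca.png"),
                    ggplot2::autoplot(pca(ds, ncomp = min(2, n_samples(ds) - 1))),
                    width = 6, height = 5, dpi = 120)
  }, error = function(e) warn(paste0("Figure generation failed: ", conditionMessage(e))))
  invisible(NULL)
}

#' Replay a run from its manifest
#'
#' Re-executes the pipeline from the config embedded in a `manifest.json`,
#' reproducing the CSV outputs byte-identically.
#'
#' @param manifest_path path to a manifest written by [run_pipeline()].
#' @param output_dir optional new output directory (defaults to the one in
#'   the manifest).
#' @return Invisibly, the output directory.
#' @export
replay_manifest <- function(manifest_path, output_dir = NULL) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  cfg <- man$config
  if (is.null(cfg)) abort("Manifest has no embedded config (failed run?).")
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  # drop filled defaults' names back through validation for type safety
  run_pipeline(cfg)
}
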