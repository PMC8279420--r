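#' The central dataset container
#'
#' An `omics_data` object holds a samples-by-features intensity matrix joined
#' to the sample metadata (group label plus optional covariates) and an
#' append-only log of the processing steps applied so far. It is the object
#' every verb in the package takes first, so analyses chain with the pipe:
#' `ds |> impute("knn") |> normalize("log_pareto") |> ttest_all()`.
#'
#' Group levels are ordered by first appearance in the target file; every
#' two-group contrast in the package is *second level versus first level*.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#'   Dimnames are taken as sample and feature ids when present.
#' @param samples data frame with one row per sample: column 1 the sample id,
#'   column 2 the group label, further columns covariates (order preserved).
#' @param log character vector of applied-step descriptors.
#'
#' @return An object of class `omics_data`.
#' @export
#' @examples
#' m <- matrix(rnorm(12, 10), 3, 4, dimnames = list(paste0("s", 1:3), paste0("f", 1:4)))
#' ds <- omics_data(m, data.frame(sample = paste0("s", 1:3), group = c("A", "A", "B")))
#' ds
omics_data <- function(values, samples, log = character()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  samples <- tibble::as_tibble(samples)
  if (ncol(samples) < 2) {
    abort("`samples` needs at least a sample-id and a group column.")
  }
  sample_ids <- as.character(samples[[1]])
  if (anyDuplicated(sample_ids)) {
    abort(paste0("Duplicate sample ids: ",
                 paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  }
  if (nrow(values) != nrow(samples)) {
    abort(sprintf(
      "Row mismatch: features table has %d rows but target has %d. The order and number of rows in both files must be the same.",
      nrow(values), nrow(samples)))
  }
  if (is.null(colnames(values))) colnames(values) <- paste0("feature", seq_len(ncol(values)))
  if (anyDuplicated(colnames(values))) abort("Feature ids must be unique.")
  rownames(values) <- sample_ids
  names(samples)[1:2] <- c("sample_id", "group")
  samples$sample_id <- sample_ids
  grp <- as.character(samples$group)
  samples$group <- factor(grp, levels = unique(grp))
  if (nlevels(samples$group) < 2) {
    warn("Group column has fewer than 2 levels; group-contrast analyses will refuse to run.")
    log <- c(log, "warning: fewer than 2 group levels in target")
  }
  structure(
    list(values = values, samples = samples, log = log),
    class = "omics_data")
}

#' Read the two-CSV input (target + features)
#'
#' The target file carries the sample names in column 1 and the group label
#' in column 2; columns 3 and onward (when present) are covariates used by
#' the covariate-aware analyses. The features file is a pure numeric block,
#' one quantified feature per column and no sample-id column; its rows must
#' be in the same order as the target file. Empty cells and the literal
#' string `NA` are read as missing.
#'
#' @param target_path path to the target (metadata) CSV.
#' @param features_path path to the features CSV.
#' @return An [omics_data] object.
#' @export
read_omics <- function(target_path, features_path) {
  for (p in c(target_path, features_path)) {
    if (!file.exists(p)) abort(paste0("File not found: ", p))
  }
  target <- readr::read_csv(target_path, col_types = readr::cols(.default = readr::col_guess()),
                            na = c("", "NA"), progress = FALSE, show_col_types = FALSE)
  # parse as text and convert via base R for correctly rounded doubles
  feats <- readr::read_csv(features_path, col_types = readr::cols(.default = readr::col_character()),
                           na = c("", "NA"), progress = FALSE, show_col_types = FALSE)
  feats <- dplyr::mutate(feats, dplyr::across(dplyr::everything(), as.numeric))
  if (ncol(target) < 2) abort("Target file needs at least two columns (sample id, group).")
  if (ncol(feats) < 1) abort("Features file has no columns.")
  if (nrow(target) != nrow(feats)) {
    abort(sprintf("Row mismatch: target has %d rows, features has %d. The order and number of rows in both files must be the same.",
                  nrow(target), nrow(feats)))
  }
  m <- as.matrix(feats)
  rownames(m) <- as.character(target[[1]])
  omics_data(m, target,
             log = sprintf("load: %d samples x %d features, %d covariate(s)",
                           nrow(m), ncol(m), ncol(target) - 2L))
}

#' Write an omics_data object back to target/features CSV files
#'
#' Inverse of [read_omics()]: numeric values round-trip bit-exactly.
#'
#' @param ds an [omics_data] object.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Invisibly, the two paths written.
#' @export
write_omics <- function(ds, dir, prefix = "") {
  stopifnot(is_omics_data(ds))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tp <- file.path(dir, paste0(prefix, "target.csv"))
  fp <- file.path(dir, paste0(prefix, "features.csv"))
  readr::write_csv(ds$samples, tp, progress = FALSE)
  # print with 17 significant digits so finite doubles round-trip bit-exactly
  feats <- tibble::as_tibble(ds$values) |>
    dplyr::mutate(dplyr::across(dplyr::everything(),
                                ~ ifelse(is.na(.x), NA_character_, sprintf("%.17g", .x))))
  readr::write_csv(feats, fp, na = "NA", progress = FALSE)
  invisible(c(target = tp, features = fp))
}

#' @export
print.omics_data <- function(x, ...) {
  cat(sprintf("<omics_data> %d samples x %d features\n", nrow(x$values), ncol(x$values)))
  cat("  groups: ", paste(sprintf("%s (n=%d)", levels(x$samples$group),
                                  tabulate(x$samples$group)), collapse = ", "), "\n", sep = "")
  cv <- covariates(x)
  if (ncol(cv)) cat("  covariates: ", paste(names(cv), collapse = ", "), "\n", sep = "")
  nmiss <- sum(is.na(x$values))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", nmiss, 100 * nmiss / length(x$values)))
  if (length(x$log)) cat("  log: ", paste(x$log, collapse = " | "), "\n", sep = "")
  invisible(x)
}

#' @rdname omics_data
#' @param x,ds an object.
#' @export
is_omics_data <- function(x) inherits(x, "omics_data")

#' @rdname omics_data
#' @export
sample_ids <- function(ds) ds$samples$sample_id

#' @rdname omics_data
#' @export
feature_ids <- function(ds) colnames(ds$values)

#' @rdname omics_data
#' @export
groups <- function(ds) ds$samples$group

#' @rdname omics_data
#' @export
covariates <- function(ds) ds$samples[, -(1:2), drop = FALSE]

#' @rdname omics_data
#' @export
n_samples <- function(ds) nrow(ds$values)

#' @rdname omics_data
#' @export
n_features <- function(ds) ncol(ds$values)

append_log <- function(ds, msg) {
  ds$log <- c(ds$log, msg)
  ds
}

#' Tidy view of the intensity matrix
#'
#' @param x an [omics_data] object.
#' @param ... ignored.
#' @return A tibble with one row per sample and one column per feature,
#'   preceded by the sample metadata columns.
#' @exportS3Method tibble::as_tibble
as_tibble.omics_data <- function(x, ...) {
  dplyr::bind_cols(x$samples, tibble::as_tibble(x$values))
}

#' Subset samples by id
#'
#' @param ds an [omics_data] object.
#' @param keep character vector of sample ids to retain (non-empty subset of
#'   `sample_ids(ds)`).
#' @return A filtered [omics_data]; unused group levels are dropped.
#' @export
subset_samples <- function(ds, keep) {
  stopifnot(is_omics_data(ds))
  keep <- as.character(keep)
  if (!length(keep)) abort("`keep` must be non-empty.")
  unknown <- setdiff(keep, sample_ids(ds))
  if (length(unknown)) {
    abort(paste0("Unknown sample id(s): ", paste(unknown, collapse = ", ")))
  }
  idx <- match(keep, sample_ids(ds))
  out <- ds
  out$values <- ds$values[idx, , drop = FALSE]
  out$samples <- ds$samples[idx, , drop = FALSE]
  out$samples$group <- droplevels(out$samples$group)
  append_log(out, sprintf("subset_samples: kept %d of %d samples", length(idx), n_samples(ds)))
}

#' Combine features belonging to the same entity
#'
#' Collapses groups of features (for instance multiple transitions of one
#' metabolite, or peptides of one protein) into a single feature per entity,
#' and reports a coefficient-of-variation table measuring the agreement of
#' the merged constituents. Missing values are excluded from the summary;
#' an all-missing row stays missing. Features absent from the grouping map
#' pass through unchanged.
#'
#' The CV for an entity with two or more constituents is sd/mean of the
#' constituent features' per-feature mean intensities; a singleton entity
#' reports sd/mean over that single column's sample values.
#'
#' @param ds an [omics_data] object.
#' @param grouping data frame with columns `feature_id`, `entity_id`; each
#'   feature may appear at most once.
#' @param method how constituent values are merged: `"mean"`, `"median"` or
#'   `"sum"`.
#' @return An [omics_data] with combined features; the CV table is attached
#'   and retrieved with [cv_table()].
#' @export
combine_features <- function(ds, grouping, method = c("mean", "median", "sum")) {
  stopifnot(is_omics_data(ds))
  method <- rlang::arg_match(method)
  grouping <- tibble::as_tibble(grouping)
  if (!nrow(grouping)) abort("`grouping` must be non-empty.")
  names(grouping)[1:2] <- c("feature_id", "entity_id")
  grouping$feature_id <- as.character(grouping$feature_id)
  grouping$entity_id <- as.character(grouping$entity_id)
  if (anyDuplicated(grouping$feature_id)) {
    abort("Each feature may be mapped to at most one entity.")
  }
  unknown <- setdiff(grouping$feature_id, feature_ids(ds))
  if (length(unknown)) {
    abort(paste0("Grouping references unknown feature(s): ", paste(unknown, collapse = ", ")))
  }
  fun <- switch(method,
    mean = function(x) mean(x, na.rm = TRUE),
    median = function(x) median(x, na.rm = TRUE),
    sum = function(x) sum(x, na.rm = TRUE))
  entities <- unique(grouping$entity_id)
  comb <- matrix(NA_real_, n_samples(ds), length(entities),
                 dimnames = list(sample_ids(ds), entities))
  cv <- numeric(length(entities))
  n_const <- integer(length(entities))
  for (i in seq_along(entities)) {
    fids <- grouping$feature_id[grouping$entity_id == entities[i]]
    block <- ds$values[, fids, drop = FALSE]
    comb[, i] <- apply(block, 1, function(r) if (all(is.na(r))) NA_real_ else fun(r))
    n_const[i] <- length(fids)
    if (length(fids) >= 2) {
      fmeans <- colMeans(block, na.rm = TRUE)
      cv[i] <- sd(fmeans) / mean(fmeans)
    } else {
      v <- block[, 1]
      cv[i] <- sd(v, na.rm = TRUE) / mean(v, na.rm = TRUE)
    }
  }
  passthrough <- setdiff(feature_ids(ds), grouping$feature_id)
  out <- ds
  out$values <- cbind(comb, ds$values[, passthrough, drop = FALSE])
  out <- append_log(out, sprintf(
    "combine_features(method=%s): %d features -> %d entities (+%d passthrough)",
    method, nrow(grouping), length(entities), length(passthrough)))
  attr(out, "cv_table") <- tibble::tibble(
    entity_id = entities, n_constituents = n_const, cv = cv)
  out
}

#' @rdname combine_features
#' @param x an object returned by [combine_features()].
#' @return `cv_table()` returns the per-entity tibble with `entity_id`,
#'   `n_constituents` and `cv` columns.
#' @export
cv_table <- function(x) attr(x, "cv_table")
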