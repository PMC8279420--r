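#' Broom-style tidiers
#'
#' `tidy()` returns the per-unit (feature or sample) table of a fitted
#' object; `glance()` returns its one-row model summary.
#'
#' @param x a fitted metabokit object.
#' @param ... ignored.
#' @name metabokit-tidiers
NULL

#' @rdname metabokit-tidiers
#' @exportS3Method generics::tidy
tidy.latent_model <- function(x, ...) {
  out <- tidyr::pivot_longer(x$loadings, -"feature",
                             names_to = "component", values_to = "value")
  if (!is.null(x$vip)) out <- dplyr::left_join(out, x$vip, by = "feature")
  out
}

#' @rdname metabokit-tidiers
#' @exportS3Method generics::glance
glance.latent_model <- function(x, ...) {
  tibble::tibble(
    method = x$method, ncomp = x$ncomp,
    explained_variance_total = sum(x$explained_variance),
    cv_error_min = if (is.null(x$cv)) NA_real_ else min(x$cv$error, na.rm = TRUE),
    n_selected = if (!is.null(x$vip)) sum(x$vip$selected)
                 else if (!is.null(x$selected)) length(unique(unlist(x$selected)))
                 else NA_integer_)
}

#' @rdname metabokit-tidiers
#' @exportS3Method generics::tidy
tidy.moderated_fit <- function(x, ...) x$table

#' @rdname metabokit-tidiers
#' @exportS3Method generics::glance
glance.moderated_fit <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$table),
                 df_prior = x$df_prior, var_prior = x$var_prior)
}

#' @rdname metabokit-tidiers
#' @exportS3Method generics::tidy
tidy.outlier_result <- function(x, ...) x$samples

#' @rdname metabokit-tidiers
#' @exportS3Method generics::glance
glance.outlier_result <- function(x, ...) {
  tibble::tibble(metric = x$metric, x = x$x, ndim = x$ndim,
                 n_samples = nrow(x$samples), n_outliers = sum(x$samples$outlier))
}

#' @rdname metabokit-tidiers
#' @exportS3Method generics::tidy
tidy.predictive_eval <- function(x, ...) x$coefficients

#' @rdname metabokit-tidiers
#' @exportS3Method generics::glance
glance.predictive_eval <- function(x, ...) {
  base <- tibble::tibble(method = x$method,
                         n_train = length(x$split$train_ids))
  if (is.null(x$metrics)) {
    base$n_test <- length(x$split$test_ids)
    base
  } else {
    dplyr::bind_cols(base, x$metrics)
  }
}

#' @rdname metabokit-tidiers
#' @exportS3Method generics::tidy
tidy.rank_product_result <- function(x, ...) x$table

#' @rdname metabokit-tidiers
#' @exportS3Method generics::glance
glance.rank_product_result <- function(x, ...) {
  tibble::tibble(n_comparisons = x$n_comparisons, n_perm = x$n_perm,
                 paired = x$paired, exact = x$exact)
}

#' @rdname metabokit-tidiers
#' @exportS3Method generics::tidy
tidy.cluster_result <- function(x, ...) x$assignments

#' @rdname metabokit-tidiers
#' @exportS3Method generics::glance
glance.cluster_result <- function(x, ...) {
  tibble::tibble(k = x$k, wss = x$wss$wss[x$k], total_ss = x$wss$wss[1])
}
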