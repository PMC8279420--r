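#' Multivariate group-dependent outlier detection
#'
#' An ad hoc multivariate detector: compute the sample–sample distance
#' matrix, embed the samples in a low-dimensional principal coordinate
#' space (classical multidimensional scaling, 2-D by default), and within
#' each study group measure every sample's Euclidean distance to its own
#' group centroid (the coordinate mean). A sample is flagged when that
#' distance exceeds the classical univariate Tukey fence
#' `Q3 + x * IQR` computed over its group's distances — the higher `x`,
#' the less sensitive the method. Quartiles use linear interpolation
#' between order statistics (R's default quantile type 7).
#'
#' @param ds a complete [omics_data].
#' @param metric distance between samples: `"euclidean"` (default),
#'   `"maximum"`, `"manhattan"`, `"canberra"` or `"minkowski"`.
#' @param x positive fence multiplier (default 1.5, the classical Tukey
#'   value).
#' @param ndim dimension of the principal coordinate embedding (default 2).
#' @param minkowski_p exponent for the Minkowski metric (default 2).
#' @return An `outlier_result`: tibbles of per-sample coordinates and
#'   centroid distances with fences and flags, plus per-group centroids.
#'   `tidy()` returns the per-sample table; `autoplot()` draws the embedding.
#' @export
detect_outliers <- function(ds, metric = c("euclidean", "maximum", "manhattan",
                                           "canberra", "minkowski"),
                            x = 1.5, ndim = 2, minkowski_p = 2) {
  stopifnot(is_omics_data(ds))
  metric <- rlang::arg_match(metric)
  stopifnot(x > 0, ndim >= 1)
  if (anyNA(ds$values)) abort("Matrix has missing cells; impute before detect_outliers().")
  g <- groups(ds)
  sizes <- tabulate(g)
  if (any(sizes < 3)) {
    warn("Groups with fewer than 3 samples: their fences are unreliable; size-1 groups are never flagged.")
  }
  d <- dist(ds$values, method = metric, p = minkowski_p)
  co <- classical_mds(d, ndim = ndim)
  coords <- as.matrix(co[, -1])
  n <- n_samples(ds)
  dist_to_centroid <- numeric(n)
  fence <- numeric(n)
  centroids <- matrix(NA_real_, nlevels(g), ndim,
                      dimnames = list(levels(g), colnames(coords)))
  for (lv in levels(g)) {
    idx <- which(g == lv)
    cen <- colMeans(coords[idx, , drop = FALSE])
    centroids[lv, ] <- cen
    dd <- sqrt(rowSums((coords[idx, , drop = FALSE] -
                          matrix(cen, length(idx), ndim, byrow = TRUE))^2))
    dist_to_centroid[idx] <- dd
    fence[idx] <- if (length(idx) == 1) Inf else tukey_fence(dd, x)
  }
  flags <- dist_to_centroid > fence
  res <- structure(list(
    samples = tibble::tibble(
      sample_id = sample_ids(ds), group = g,
      axis1 = coords[, 1],
      axis2 = if (ndim >= 2) coords[, 2] else 0,
      distance = dist_to_centroid, fence = fence, outlier = flags),
    coords = co,
    centroids = tibble::as_tibble(centroids, rownames = "group"),
    metric = metric, x = x, ndim = ndim),
    class = "outlier_result")
  res
}

#' Tukey upper fence
#'
#' `Q3 + x * IQR` of a numeric vector, with quartiles by linear
#' interpolation between order statistics (quantile type 7).
#'
#' @param d numeric vector (e.g. distances to a group centroid).
#' @param x positive fence multiplier.
#' @return The fence value.
#' @export
#' @examples
#' tukey_fence(c(1, 2, 3, 4, 100))  # Q3 = 4, IQR = 2 -> 7
tukey_fence <- function(d, x = 1.5) {
  q <- quantile(d, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] + x * (q[2] - q[1])
}

#' @export
print.outlier_result <- function(x, ...) {
  cat(sprintf("<outlier_result> metric=%s, x=%g, ndim=%d\n", x$metric, x$x, x$ndim))
  n_out <- sum(x$samples$outlier)
  cat(sprintf("  %d of %d sample(s) flagged", n_out, nrow(x$samples)))
  if (n_out) cat(": ", paste(x$samples$sample_id[x$samples$outlier], collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' @rdname detect_outliers
#' @param result an `outlier_result` from [detect_outliers()].
#' @return `outlier_ids()` returns the flagged sample ids.
#' @export
outlier_ids <- function(result) {
  stopifnot(inherits(result, "outlier_result"))
  result$samples$sample_id[result$samples$outlier]
}

#' Remove flagged outlier samples
#'
#' @param ds the [omics_data] the detection ran on.
#' @param result an `outlier_result` from [detect_outliers()].
#' @return The dataset restricted to unflagged samples.
#' @export
remove_outliers <- function(ds, result) {
  stopifnot(is_omics_data(ds), inherits(result, "outlier_result"))
  keep <- setdiff(sample_ids(ds), outlier_ids(result))
  if (!length(keep)) abort("All samples flagged as outliers; refusing to empty the dataset.")
  if (length(keep) == n_samples(ds)) return(append_log(ds, "remove_outliers: no outliers flagged"))
  out <- subset_samples(ds, keep)
  append_log(out, sprintf("remove_outliers: removed %s",
                          paste(outlier_ids(result), collapse = ", ")))
}
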