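#' Recode exact zeros as missing values
#'
#' Instrument output often conflates "not detected" with "truly absent".
#' For endogenous compounds a reported zero usually means below the limit of
#' detection, so the recommended default treats zeros as missing before
#' imputation. Exogenous compounds (e.g. drugs) whose absence is real can be
#' exempted and keep their zeros.
#'
#' @param ds an [omics_data] object.
#' @param zeros_as_missing if `FALSE` the matrix is returned unchanged.
#' @param exempt_features feature ids whose zeros are kept as true zeros.
#' @return An [omics_data].
#' @export
recode_zeros <- function(ds, zeros_as_missing = TRUE, exempt_features = character()) {
  stopifnot(is_omics_data(ds))
  unknown <- setdiff(exempt_features, feature_ids(ds))
  if (length(unknown)) abort(paste0("Unknown exempt feature(s): ", paste(unknown, collapse = ", ")))
  if (!zeros_as_missing) return(append_log(ds, "recode_zeros: disabled, matrix unchanged"))
  target <- setdiff(feature_ids(ds), exempt_features)
  sub <- ds$values[, target, drop = FALSE]
  nz <- sum(sub == 0, na.rm = TRUE)
  sub[!is.na(sub) & sub == 0] <- NA_real_
  ds$values[, target] <- sub
  append_log(ds, sprintf("recode_zeros: %d zero cell(s) recoded as missing (%d feature(s) exempt)",
                         nz, length(exempt_features)))
}

#' Filter features by group-wise missingness
#'
#' A feature is removed when its within-group missing fraction exceeds
#' `cutoff` in *every* study group (`rule = "all"`, the default — a feature
#' still well measured in at least one group is kept). `rule = "any"` removes
#' a feature as soon as a single group exceeds the cutoff.
#'
#' @param ds an [omics_data] object.
#' @param cutoff allowed missing fraction per group, in `[0, 1]`; default 0.20.
#' @param rule `"all"` or `"any"` (which groups must exceed the cutoff).
#' @return The filtered [omics_data]; removed feature ids are attached and
#'   read with [removed_features()].
#' @export
filter_missing <- function(ds, cutoff = 0.20, rule = c("all", "any")) {
  stopifnot(is_omics_data(ds))
  rule <- rlang::arg_match(rule)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || is.na(cutoff) || cutoff < 0 || cutoff > 1) {
    abort("`cutoff` must be a single number in [0, 1].")
  }
  g <- groups(ds)
  frac <- vapply(levels(g), function(lv) {
    colMeans(is.na(ds$values[g == lv, , drop = FALSE]))
  }, numeric(n_features(ds)))
  if (is.null(dim(frac))) frac <- matrix(frac, nrow = 1)  # single feature
  exceeds <- frac > cutoff
  drop <- if (rule == "all") apply(exceeds, 1, all) else apply(exceeds, 1, any)
  # an entirely missing feature can never be imputed: removed at any cutoff
  drop <- drop | colSums(!is.na(ds$values)) == 0
  removed <- feature_ids(ds)[drop]
  out <- ds
  out$values <- ds$values[, !drop, drop = FALSE]
  out <- append_log(out, sprintf("filter_missing(cutoff=%g, rule=%s): removed %d feature(s)",
                                 cutoff, rule, length(removed)))
  attr(out, "removed_features") <- removed
  out
}

#' @rdname filter_missing
#' @param x an object returned by [filter_missing()].
#' @export
removed_features <- function(x) attr(x, "removed_features")

#' Impute remaining missing values
#'
#' Six methods, applied per feature on its observed values:
#' \describe{
#'   \item{zero}{missing cells set to 0.}
#'   \item{half_min}{half the feature's observed minimum (a proxy for
#'     below-limit-of-quantification signals).}
#'   \item{median, mean, min}{the corresponding per-feature summary.}
#'   \item{knn}{each missing cell is the mean of the feature's values in the
#'     `k` nearest samples; nearness is Euclidean distance over mutually
#'     observed, per-feature standardized features, excluding the feature
#'     being imputed.}
#' }
#'
#' @param ds an [omics_data] object.
#' @param method imputation method.
#' @param k number of neighbours for `knn` (default 5).
#' @return A complete [omics_data] (no missing cells).
#' @export
impute <- function(ds, method = c("knn", "zero", "half_min", "median", "mean", "min"),
                   k = 5) {
  stopifnot(is_omics_data(ds))
  method <- rlang::arg_match(method)
  stopifnot(k >= 1)
  m <- ds$values
  all_missing <- colSums(!is.na(m)) == 0
  if (any(all_missing) && method != "zero") {
    abort(paste0("Cannot impute entirely missing feature(s): ",
                 paste(feature_ids(ds)[all_missing], collapse = ", "),
                 ". Run filter_missing() first or use method = \"zero\"."))
  }
  n_miss <- sum(is.na(m))
  if (method == "knn") {
    if (n_samples(ds) < k + 1) abort("knn imputation needs at least k + 1 samples.")
    m <- impute_knn(m, k)
  } else {
    fill <- switch(method,
      zero = function(x) 0,
      half_min = function(x) min(x) / 2,
      median = function(x) median(x),
      mean = function(x) mean(x),
      min = function(x) min(x))
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- if (all(nas)) 0 else fill(m[!nas, j])
    }
  }
  ds$values <- m
  append_log(ds, sprintf("impute(method=%s%s): %d cell(s) imputed",
                         method, if (method == "knn") paste0(", k=", k) else "", n_miss))
}

# k-nearest-neighbour imputation on the raw matrix; distances use
# standardized features so high-intensity features do not dominate.
impute_knn <- function(m, k) {
  mu <- colMeans(m, na.rm = TRUE)
  sdv <- apply(m, 2, sd, na.rm = TRUE)
  sdv[is.na(sdv) | sdv == 0] <- 1
  z <- sweep(sweep(m, 2, mu), 2, sdv, "/")
  out <- m
  for (i in which(rowSums(is.na(m)) > 0)) {
    for (j in which(is.na(m[i, ]))) {
      cand <- which(!is.na(m[, j]))
      if (!length(cand)) { out[i, j] <- mu[j]; next }
      d <- vapply(cand, function(s) {
        shared <- which(!is.na(z[i, ]) & !is.na(z[s, ]))
        shared <- setdiff(shared, j)
        if (!length(shared)) return(Inf)
        sqrt(mean((z[i, shared] - z[s, shared])^2))
      }, numeric(1))
      ord <- order(d)
      nn <- cand[ord[is.finite(d[ord])]]
      if (!length(nn)) nn <- cand  # no shared observed features: use all donors
      out[i, j] <- mean(m[head(nn, k), j])
    }
  }
  out
}

#' Normalize (transform and scale) the intensity matrix
#'
#' Six per-feature methods; with sample mean `m`, sample sd `s`
#' (n − 1 denominator) of feature values `x`:
#' \describe{
#'   \item{autoscale}{`(x - m)/s` — mean 0, sd 1 (unit variance scaling).}
#'   \item{level}{`(x - m)/m` — changes relative to the mean response.}
#'   \item{log}{`ln(x + 1)` — log transformation only; the +1 offset keeps
#'     zero intensities finite.}
#'   \item{log_scale}{autoscaling of `ln(x + 1)`.}
#'   \item{vast}{`((x - m)/s) * (m/s)` — autoscaling weighted by 1/CV,
#'     up-weighting stable features.}
#'   \item{log_pareto}{`(ln(x+1) - m') / sqrt(s')` with `m'`, `s'` the mean
#'     and sd of `ln(x + 1)` — a compromise between no scaling and
#'     autoscaling.}
#' }
#' Features with zero variance (or zero mean, for level scaling) carry no
#' information under a scaling method and are dropped with a logged warning.
#' Log-family methods require a non-negative matrix.
#'
#' @param ds a complete [omics_data] (run [impute()] first).
#' @param method normalization method.
#' @return An [omics_data] on the normalized scale.
#' @export
normalize <- function(ds, method = c("log_pareto", "autoscale", "level", "log",
                                     "log_scale", "vast")) {
  stopifnot(is_omics_data(ds))
  method <- rlang::arg_match(method)
  m <- ds$values
  if (anyNA(m)) abort("Matrix has missing cells; run impute() before normalize().")
  if (method %in% c("log", "log_scale", "log_pareto") && any(m < 0)) {
    abort("Negative values are incompatible with log-family normalization.")
  }
  if (method %in% c("log", "log_scale", "log_pareto")) m <- log1p(m)
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  drop <- switch(method,
    log = rep(FALSE, ncol(m)),
    level = mu == 0,
    sdv == 0)
  if (any(drop)) {
    warn(paste0("Dropping constant/degenerate feature(s) under ", method, " scaling: ",
                paste(colnames(m)[drop], collapse = ", ")))
    m <- m[, !drop, drop = FALSE]; mu <- mu[!drop]; sdv <- sdv[!drop]
  }
  m <- switch(method,
    autoscale = sweep(sweep(m, 2, mu), 2, sdv, "/"),
    level = sweep(sweep(m, 2, mu), 2, mu, "/"),
    log = m,
    log_scale = sweep(sweep(m, 2, mu), 2, sdv, "/"),
    vast = sweep(sweep(sweep(m, 2, mu), 2, sdv, "/"), 2, mu / sdv, "*"),
    log_pareto = sweep(sweep(m, 2, mu), 2, sqrt(sdv), "/"))
  ds$values <- m
  append_log(ds, sprintf("normalize(method=%s)%s", method,
                         if (any(drop)) sprintf(": dropped %d constant feature(s)", sum(drop)) else ""))
}
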