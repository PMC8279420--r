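#' Principal component analysis
#'
#' Column-centred singular value decomposition of the intensity matrix
#' (no rescaling inside — normalize upstream if desired).
#'
#' @param ds a complete [omics_data].
#' @param ncomp number of components, at most `min(n - 1, p)`.
#' @return A `latent_model` with scores, loadings and per-component
#'   explained-variance fractions. Use [tidy()] / [glance()] / `autoplot()`.
#' @export
pca <- function(ds, ncomp = 2) {
  stopifnot(is_omics_data(ds))
  if (anyNA(ds$values)) abort("Matrix has missing cells; impute first.")
  rmax <- min(n_samples(ds) - 1L, n_features(ds))
  if (ncomp > rmax) abort(sprintf("ncomp must be <= min(n - 1, p) = %d.", rmax))
  fit <- prcomp(ds$values, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  new_latent_model(
    method = "pca", ncomp = ncomp,
    scores = score_tibble(fit$x[, seq_len(ncomp), drop = FALSE], ds),
    loadings = loading_tibble(fit$rotation[, seq_len(ncomp), drop = FALSE]),
    explained_variance = ev[seq_len(ncomp)])
}

#' Classical multidimensional scaling (principal coordinates)
#'
#' Embeds a distance matrix by double-centring `-0.5 * J D^2 J` and
#' eigendecomposition; coordinates are eigenvectors scaled by the square
#' root of their eigenvalues. Axes with non-positive eigenvalues are
#' truncated at zero (zero coordinates).
#'
#' @param d a `dist` object or a symmetric, zero-diagonal, non-negative
#'   matrix.
#' @param ndim number of coordinates to return (default 2).
#' @return A tibble: `sample_id` (names when available) and `axis1..axisk`.
#' @export
classical_mds <- function(d, ndim = 2) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d), tol = 1e-8)) abort("Distance matrix must be symmetric.")
    if (any(diag(d) != 0)) abort("Distance matrix must have a zero diagonal.")
    if (any(d < 0)) abort("Distances must be non-negative.")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  fit <- cmdscale(d, k = min(ndim, n - 1), eig = TRUE)
  pts <- fit$points
  if (is.null(pts) || ncol(pts) < ndim) {
    # degenerate configurations span fewer axes; pad with zero coordinates
    pad <- matrix(0, n, ndim - if (is.null(pts)) 0 else ncol(pts))
    pts <- cbind(pts, pad)
  }
  ids <- attr(d, "Labels") %||% as.character(seq_len(n))
  colnames(pts) <- paste0("axis", seq_len(ncol(pts)))
  dplyr::bind_cols(tibble::tibble(sample_id = ids), tibble::as_tibble(pts))
}

#' Partial least squares discriminant analysis
#'
#' PLS2 fitted by NIPALS on the column-centred matrix against the centred
#' one-hot group indicator matrix. Reports per-feature VIP scores
#' (variable importance in the projection; the mean squared VIP is 1 by
#' construction) and a cross-validated classification error per number of
#' components, predicting by the nearest group centroid in latent-score
#' space.
#'
#' @param ds a complete [omics_data] with at least 2 groups.
#' @param ncomp number of latent components (default 2).
#' @param cv `"loo"` for leave-one-out, `"kfold"`, or `"none"` to skip
#'   cross-validation.
#' @param folds number of folds for `cv = "kfold"` (default 5).
#' @param vip_cutoff features with VIP at or above this are marked selected
#'   (default 1).
#' @param seed integer seed driving fold assignment (required for kfold).
#' @return A `latent_model` with scores, weights/loadings, VIP, and a
#'   per-ncomp CV error table.
#' @export
plsda <- function(ds, ncomp = 2, cv = c("loo", "kfold", "none"), folds = 5,
                  vip_cutoff = 1, seed = NULL) {
  stopifnot(is_omics_data(ds))
  cv <- rlang::arg_match(cv)
  check_groups(ds, min_levels = 2)
  if (anyNA(ds$values)) abort("Matrix has missing cells; impute first.")
  rmax <- min(n_samples(ds) - 1L, n_features(ds))
  if (ncomp > rmax) abort(sprintf("ncomp must be <= min(n - 1, p) = %d.", rmax))
  fit <- nipals_pls(ds$values, one_hot(groups(ds)), ncomp, keepX = NULL)
  vip <- pls_vip(fit)
  cv_err <- pls_cv(ds, ncomp, keepX = NULL, cv = cv, folds = folds, seed = seed)
  new_latent_model(
    method = "plsda", ncomp = ncomp,
    scores = score_tibble(fit$scores, ds),
    loadings = loading_tibble(fit$weights, value_name = "weight"),
    explained_variance = fit$ssy_explained / sum(fit$ssy_explained),
    vip = tibble::tibble(feature = rownames(fit$weights), vip = vip,
                         selected = vip >= vip_cutoff),
    cv = cv_err, fit = fit)
}

#' Sparse PLS discriminant analysis
#'
#' As [plsda()], with per-component soft-thresholding of the X-weight
#' vector so that only the `keepX[a]` largest-magnitude weights stay
#' nonzero on component `a` (ties broken by feature order). With
#' `keepX = p` for every component the model equals PLS-DA.
#'
#' @inheritParams plsda
#' @param keepX integer vector (recycled to `ncomp`): nonzero weights kept
#'   per component.
#' @return A `latent_model`; `$selected` lists the retained features per
#'   component.
#' @export
splsda <- function(ds, ncomp = 2, keepX, cv = c("loo", "kfold", "none"), folds = 5,
                   seed = NULL) {
  stopifnot(is_omics_data(ds))
  cv <- rlang::arg_match(cv)
  check_groups(ds, min_levels = 2)
  if (anyNA(ds$values)) abort("Matrix has missing cells; impute first.")
  keepX <- rep_len(as.integer(keepX), ncomp)
  if (any(keepX <= 0)) abort("keepX entries must be positive.")
  if (any(keepX > n_features(ds))) abort("keepX cannot exceed the number of features.")
  fit <- nipals_pls(ds$values, one_hot(groups(ds)), ncomp, keepX = keepX)
  selected <- lapply(seq_len(ncomp), function(a) {
    rownames(fit$weights)[fit$weights[, a] != 0]
  })
  names(selected) <- paste0("comp", seq_len(ncomp))
  cv_err <- pls_cv(ds, ncomp, keepX = keepX, cv = cv, folds = folds, seed = seed)
  new_latent_model(
    method = "splsda", ncomp = ncomp,
    scores = score_tibble(fit$scores, ds),
    loadings = loading_tibble(fit$weights, value_name = "weight"),
    explained_variance = fit$ssy_explained / sum(fit$ssy_explained),
    keepX = keepX, selected = selected, cv = cv_err, fit = fit)
}

# ---- PLS internals ---------------------------------------------------------

one_hot <- function(g) {
  y <- model.matrix(~ g - 1)
  colnames(y) <- levels(g)
  y
}

# NIPALS PLS2 with optional per-component keepX soft-thresholding of the
# X-weight vector. X and Y are centred inside; sstot_y is the centred Y SS.
nipals_pls <- function(x, y, ncomp, keepX = NULL, tol = 1e-9, max_iter = 500) {
  xm <- colMeans(x); ym <- colMeans(y)
  X <- sweep(as.matrix(x), 2, xm)
  Y <- sweep(as.matrix(y), 2, ym)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  W <- matrix(0, p, ncomp, dimnames = list(colnames(x), NULL))
  P <- matrix(0, p, ncomp, dimnames = list(colnames(x), NULL))
  Q <- matrix(0, q, ncomp)
  TT <- matrix(0, n, ncomp, dimnames = list(rownames(x), NULL))
  ssy_explained <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    u <- Y[, which.max(colSums(Y^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(X, u)) / drop(crossprod(u))
      if (!is.null(keepX) && keepX[a] < p) {
        aw <- abs(w)
        # threshold at the largest excluded magnitude; earliest features win ties
        keep_idx <- order(-aw, seq_along(aw))[seq_len(keepX[a])]
        lambda <- max(aw[-keep_idx], 0)
        w_new <- sign(w) * pmax(aw - lambda, 0)
        w_new[-keep_idx] <- 0
        w <- w_new
      }
      nw <- sqrt(sum(w^2))
      if (nw == 0) abort("PLS weight vector collapsed to zero; data may be constant.")
      w <- w / nw
      tt <- drop(X %*% w)
      qv <- drop(crossprod(Y, tt)) / drop(crossprod(tt))
      u <- drop(Y %*% qv) / drop(crossprod(qv))
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    pv <- drop(crossprod(X, tt)) / drop(crossprod(tt))
    ssy_explained[a] <- drop(crossprod(tt)) * drop(crossprod(qv))
    X <- X - tcrossprod(tt, pv)
    Y <- Y - tcrossprod(tt, qv)
    W[, a] <- w; P[, a] <- pv; Q[, a] <- qv; TT[, a] <- tt
  }
  colnames(TT) <- colnames(W) <- colnames(P) <- colnames(Q) <- paste0("comp", seq_len(ncomp))
  # rotation for projecting new samples: t_new = (x_new - xm) W (P'W)^{-1}
  rotation <- W %*% solve(crossprod(P, W))
  list(weights = W, loadings = P, y_loadings = Q, scores = TT,
       x_center = xm, y_center = ym, rotation = rotation,
       ssy_explained = ssy_explained)
}

# VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a), w normalized per component
pls_vip <- function(fit) {
  w2 <- sweep(fit$weights^2, 2, colSums(fit$weights^2), "/")
  ssy <- fit$ssy_explained
  unname(drop(sqrt(nrow(fit$weights) * (w2 %*% ssy) / sum(ssy))))
}

make_folds <- function(g, folds, seed) {
  assign_one <- function() {
    id <- integer(length(g))
    for (lv in levels(g)) {
      idx <- which(g == lv)
      id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    id
  }
  if (is.null(seed)) assign_one() else withr::with_seed(seed, assign_one())
}

# CV classification error per number of components; nearest train-group
# centroid in latent-score space. Folds are stratified by group.
pls_cv <- function(ds, ncomp, keepX, cv, folds, seed) {
  if (cv == "none") return(NULL)
  g <- groups(ds)
  n <- n_samples(ds)
  fold_id <- if (cv == "loo") seq_len(n) else make_folds(g, folds, seed)
  nfold <- max(fold_id)
  err <- matrix(NA_real_, nfold, ncomp)
  for (f in seq_len(nfold)) {
    test <- which(fold_id == f)
    train <- setdiff(seq_len(n), test)
    if (nlevels(droplevels(g[train])) < nlevels(g)) {
      warn(sprintf("CV fold %d lost a whole group; skipped.", f))
      next
    }
    ft <- nipals_pls(ds$values[train, , drop = FALSE], one_hot(droplevels(g[train])),
                     ncomp, keepX = keepX)
    te_scores <- sweep(ds$values[test, , drop = FALSE], 2, ft$x_center) %*% ft$rotation
    for (a in seq_len(ncomp)) {
      cen <- rowsum(ft$scores[, 1:a, drop = FALSE], g[train])
      cen <- cen / as.vector(table(g[train])[rownames(cen)])
      pred <- apply(te_scores[, 1:a, drop = FALSE], 1, function(s) {
        rownames(cen)[which.min(colSums((t(cen) - s)^2))]
      })
      err[f, a] <- mean(pred != as.character(g[test]))
    }
  }
  # overall error = misclassified / classified, weighting folds by size
  wt <- as.vector(table(factor(fold_id, levels = seq_len(nfold))))
  ok <- !is.na(err[, 1])
  tibble::tibble(
    ncomp = seq_len(ncomp),
    error = colSums(err[ok, , drop = FALSE] * wt[ok]) / sum(wt[ok]),
    scheme = if (cv == "loo") "loo" else sprintf("%d-fold", folds))
}

# ---- k-means with elbow selection ------------------------------------------

#' k-means clustering with elbow selection and MDS projection
#'
#' Lloyd-type k-means (via [stats::kmeans()]) with `n_init` random restarts
#' per k. With `k = "auto"` the within-cluster sum of squares (WSS) is
#' scanned over `1..max_k` and k chosen at the maximal second difference of
#' the WSS curve (the sharpest elbow). Each k additionally warm-starts from
#' the k−1 solution with its widest cluster split, which guarantees the
#' reported WSS curve is non-increasing. A 2-D classical-MDS projection of
#' the samples is attached for plotting.
#'
#' @param ds a complete [omics_data].
#' @param k number of clusters, or `"auto"`.
#' @param max_k largest k scanned (must be below the number of samples).
#' @param n_init random restarts per k (default 20).
#' @param seed integer seed for the restarts.
#' @return A `cluster_result`: chosen `k`, per-sample `assignments`
#'   tibble (with MDS coordinates), and the WSS scan table.
#' @export
kmeans_clusters <- function(ds, k = "auto", max_k = 10, n_init = 20, seed = NULL) {
  stopifnot(is_omics_data(ds))
  if (anyNA(ds$values)) abort("Matrix has missing cells; impute first.")
  n <- n_samples(ds)
  if (identical(k, "auto") && max_k >= n) {
    abort("max_k must be smaller than the number of samples.")
  }
  if (!identical(k, "auto") && k > n) abort("k cannot exceed the number of samples.")
  run <- function() {
    scan_max <- if (identical(k, "auto")) max_k else k
    wss <- numeric(scan_max)
    fits <- vector("list", scan_max)
    for (kk in seq_len(scan_max)) {
      best <- kmeans(ds$values, centers = 1, nstart = 1, iter.max = 50)
      if (kk > 1) {
        best <- kmeans(ds$values, centers = kk, nstart = n_init, iter.max = 50)
        # warm start from the k-1 solution: split its widest cluster
        prev <- fits[[kk - 1]]
        wid <- which.max(prev$withinss)
        far <- which(prev$cluster == wid)
        far <- far[which.max(rowSums((ds$values[far, , drop = FALSE] -
                 matrix(prev$centers[wid, ], length(far), ncol(ds$values), byrow = TRUE))^2))]
        centers <- rbind(prev$centers, ds$values[far, ])
        warm <- suppressWarnings(kmeans(ds$values, centers = centers, iter.max = 50))
        if (warm$tot.withinss < best$tot.withinss) best <- warm
      }
      fits[[kk]] <- best
      wss[kk] <- best$tot.withinss
    }
    list(wss = wss, fits = fits)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  wss <- res$wss
  if (identical(k, "auto")) {
    if (max_k < 3) abort("k = \"auto\" needs max_k >= 3 for the elbow scan.")
    # second difference of log(WSS): relative curvature, so the sharpest
    # bend wins regardless of the curve's absolute scale
    lw <- log(pmax(wss, 1e-12 * max(wss[1], 1)))
    d2 <- lw[1:(max_k - 2)] - 2 * lw[2:(max_k - 1)] + lw[3:max_k]
    k <- which.max(d2) + 1L
  }
  fit <- res$fits[[k]]
  co <- classical_mds(dist(ds$values), ndim = 2)
  structure(list(
    k = as.integer(k),
    assignments = dplyr::bind_cols(
      tibble::tibble(sample_id = sample_ids(ds), group = groups(ds),
                     cluster = fit$cluster),
      co[, -1]),
    wss = tibble::tibble(k = seq_along(wss), wss = wss),
    seed = seed),
    class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d\n", x$k))
  print(table(cluster = x$assignments$cluster, group = x$assignments$group))
  invisible(x)
}

# ---- latent_model plumbing -------------------------------------------------

new_latent_model <- function(...) {
  structure(list(...), class = "latent_model")
}

score_tibble <- function(scores, ds) {
  colnames(scores) <- paste0("comp", seq_len(ncol(scores)))
  dplyr::bind_cols(tibble::tibble(sample_id = sample_ids(ds), group = groups(ds)),
                   tibble::as_tibble(scores))
}

loading_tibble <- function(l, value_name = "loading") {
  out <- tibble::as_tibble(l, rownames = "feature")
  out
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("<latent_model> method=%s, ncomp=%d\n", x$method, x$ncomp))
  cat("  explained variance: ",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "), "\n", sep = "")
  if (!is.null(x$cv)) {
    cat("  CV error (", x$cv$scheme[1], "): ",
        paste(sprintf("%.3f", x$cv$error), collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$vip)) {
    cat(sprintf("  %d feature(s) at/above the VIP cutoff\n", sum(x$vip$selected)))
  }
  invisible(x)
}

check_groups <- function(ds, min_levels = 2, exactly = NULL) {
  k <- nlevels(groups(ds))
  if (!is.null(exactly) && k != exactly) {
    abort(sprintf("This analysis needs exactly %d groups (found %d)%s.",
                  exactly, k,
                  if (k > exactly) "; use an ANOVA-family method for more groups" else ""))
  }
  if (k < min_levels) {
    abort(sprintf("This analysis needs at least %d groups (found %d).", min_levels, k))
  }
  invisible(TRUE)
}
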