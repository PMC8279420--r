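#' Pairwise feature correlations
#'
#' All unordered feature pairs with the chosen correlation coefficient and a
#' two-sided p-value: the t approximation on `n - 2` degrees of freedom for
#' Pearson and Spearman, and the tie-corrected normal approximation for
#' Kendall. Constant features yield missing coefficients with a warning.
#'
#' @param ds a complete [omics_data] with n >= 3 samples.
#' @param method `"pearson"`, `"spearman"` or `"kendall"`.
#' @param by_group also compute the coefficients within each study group
#'   (one row set per group, `group` column added).
#' @return An `edge_table` tibble: `feature_i < feature_j`, `r`, `p_value`,
#'   `method` (and `group` when stratified).
#' @export
pairwise_correlations <- function(ds, method = c("pearson", "spearman", "kendall"),
                                  by_group = FALSE) {
  stopifnot(is_omics_data(ds))
  method <- rlang::arg_match(method)
  if (anyNA(ds$values)) abort("Matrix has missing cells; impute first.")
  if (n_samples(ds) < 3) abort("Correlation needs at least 3 samples.")
  if (!by_group) return(cor_table(ds$values, method))
  g <- groups(ds)
  purrr::map_dfr(levels(g), function(lv) {
    out <- cor_table(ds$values[g == lv, , drop = FALSE], method)
    out$group <- lv
    out
  })
}

cor_table <- function(m, method) {
  n <- nrow(m)
  const <- apply(m, 2, function(x) length(unique(x)) == 1)
  if (any(const)) {
    warn(paste0("Constant feature(s), correlations reported as missing: ",
                paste(colnames(m)[const], collapse = ", ")))
  }
  if (method == "kendall") {
    idx <- which(upper.tri(diag(ncol(m))), arr.ind = TRUE)
    res <- purrr::map_dfr(seq_len(nrow(idx)), function(k) {
      i <- idx[k, 1]; j <- idx[k, 2]
      if (const[i] || const[j]) {
        return(tibble::tibble(feature_i = colnames(m)[i], feature_j = colnames(m)[j],
                              r = NA_real_, p_value = NA_real_))
      }
      ct <- suppressWarnings(stats::cor.test(m[, i], m[, j], method = "kendall", exact = FALSE))
      tibble::tibble(feature_i = colnames(m)[i], feature_j = colnames(m)[j],
                     r = unname(ct$estimate), p_value = ct$p.value)
    })
  } else {
    r <- suppressWarnings(cor(m, method = method))
    r[const, ] <- NA; r[, const] <- NA
    idx <- which(upper.tri(r), arr.ind = TRUE)
    rv <- r[idx]
    tstat <- rv * sqrt((n - 2) / pmax(1 - rv^2, .Machine$double.eps))
    res <- tibble::tibble(
      feature_i = colnames(m)[idx[, 1]], feature_j = colnames(m)[idx[, 2]],
      r = rv, p_value = 2 * pt(-abs(tstat), df = n - 2))
  }
  res$method <- method
  class(res) <- c("edge_table", class(res))
  res
}

#' Threshold correlation network
#'
#' Keeps the feature pairs whose absolute correlation reaches `threshold`
#' (edges of the correlation network / entries a correlogram would
#' highlight).
#'
#' @inheritParams pairwise_correlations
#' @param threshold minimum `|r|` for an edge.
#' @return An `edge_table` tibble of retained edges.
#' @export
correlation_network <- function(ds, method = c("pearson", "spearman", "kendall"),
                                threshold = 0.7) {
  tab <- pairwise_correlations(ds, method)
  out <- dplyr::filter(tab, !is.na(.data$r), abs(.data$r) >= threshold)
  class(out) <- c("edge_table", setdiff(class(out), "edge_table"))
  out
}

#' Gaussian graphical model via the graphical lasso
#'
#' Estimates a sparse inverse correlation matrix by L1-penalized Gaussian
#' maximum likelihood (graphical lasso, blockwise coordinate descent).
#' Features are standardized first so the penalty `rho` is scale-free; at
#' `rho = 0` the estimate is the exact inverse of the sample correlation
#' matrix (requires n > p). Edges are pairs with nonzero partial
#' correlation `-Omega_ij / sqrt(Omega_ii * Omega_jj)` (numerical zero
#' tolerance 1e-8).
#'
#' @param ds a complete [omics_data] with n >= 3 samples.
#' @param rho non-negative L1 regularization parameter.
#' @param max_iter,tol outer-loop iteration cap and convergence tolerance
#'   (mean absolute change of the working covariance).
#' @return A list of class `ggm_network`: `precision` matrix, `edges`
#'   tibble of partial correlations, `rho`.
#' @export
ggm_network <- function(ds, rho, max_iter = 200, tol = 1e-6) {
  stopifnot(is_omics_data(ds))
  if (!is.numeric(rho) || length(rho) != 1 || is.na(rho) || rho < 0) {
    abort("`rho` must be a single non-negative number.")
  }
  if (anyNA(ds$values)) abort("Matrix has missing cells; impute first.")
  if (n_samples(ds) < 3) abort("GGM estimation needs at least 3 samples.")
  z <- scale(ds$values)
  if (any(!is.finite(z))) abort("Constant features cannot enter the GGM; drop them first.")
  S <- cor(ds$values)
  omega <- if (rho == 0) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10) {
      abort("Sample correlation matrix is (near-)singular; use rho > 0.")
    }
    solve(S)
  } else {
    glasso_cd(S, rho, max_iter = max_iter, tol = tol)
  }
  dimnames(omega) <- list(colnames(S), colnames(S))
  dsq <- sqrt(diag(omega))
  pc <- -omega / tcrossprod(dsq)
  idx <- which(upper.tri(pc), arr.ind = TRUE)
  pcv <- pc[idx]
  keep <- abs(pcv) > 1e-8
  edges <- tibble::tibble(
    feature_i = colnames(S)[idx[keep, 1]],
    feature_j = colnames(S)[idx[keep, 2]],
    partial_cor = pcv[keep])
  structure(list(precision = omega, edges = edges, rho = rho),
            class = "ggm_network")
}

#' @export
print.ggm_network <- function(x, ...) {
  p <- ncol(x$precision)
  cat(sprintf("<ggm_network> rho = %g: %d of %d possible edges\n",
              x$rho, nrow(x$edges), p * (p - 1) / 2))
  invisible(x)
}

# Graphical lasso by blockwise coordinate descent (penalized diagonal:
# W is initialized at S + rho I). Inner problem per column is a lasso
# solved by cyclic coordinate descent.
glasso_cd <- function(S, rho, max_iter = 200, tol = 1e-6) {
  p <- ncol(S)
  W <- S + rho * diag(p)
  B <- matrix(0, p - 1, p)  # lasso coefficients per column
  off <- mean(abs(S[upper.tri(S)]))
  thr <- tol * max(off, 1e-12)
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- B[, j]
      for (inner in 1:200) {
        beta_old <- beta
        for (k in seq_len(p - 1)) {
          r <- s12[k] - sum(W11[k, ] * beta) + W11[k, k] * beta[k]
          beta[k] <- sign(r) * max(abs(r) - rho, 0) / W11[k, k]
        }
        if (max(abs(beta - beta_old)) < 1e-9) break
      }
      B[, j] <- beta
      w12 <- drop(W11 %*% beta)
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (mean(abs(W - W_old)) < thr) {
      # recover the precision matrix from the final working covariance
      omega <- matrix(0, p, p)
      for (j in seq_len(p)) {
        idx <- setdiff(seq_len(p), j)
        o22 <- 1 / (W[j, j] - sum(W[idx, j] * B[, j]))
        omega[j, j] <- o22
        omega[idx, j] <- -B[, j] * o22
      }
      return((omega + t(omega)) / 2)
    }
  }
  abort(sprintf(
    "Graphical lasso did not converge in %d outer iterations (last mean |dW| = %.3g, tol = %.3g).",
    max_iter, mean(abs(W - W_old)), thr))
}
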