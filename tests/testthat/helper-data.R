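# Small in-code constructors used across the test files.

# Dataset from an explicit matrix and group vector.
make_ds <- function(values, group, covariates = NULL, ids = NULL) {
  values <- as.matrix(values)
  ids <- ids %||% rownames(values) %||% sprintf("s%02d", seq_len(nrow(values)))
  samples <- tibble::tibble(sample_id = ids, group = group)
  if (!is.null(covariates)) samples <- dplyr::bind_cols(samples, covariates)
  omics_data(values, samples)
}

# Two-group Gaussian dataset with optional mean shift on chosen features.
gauss_ds <- function(n_per_group = c(10, 10), p = 20, shift = 0,
                     shifted_features = integer(), sd = 1, seed = 1) {
  withr::with_seed(seed, {
    n <- sum(n_per_group)
    m <- matrix(rnorm(n * p, 0, sd), n, p,
                dimnames = list(sprintf("s%02d", 1:n), sprintf("f%02d", 1:p)))
    g <- rep(c("A", "B"), n_per_group)
    m[g == "B", shifted_features] <- m[g == "B", shifted_features] + shift
    make_ds(m, g)
  })
}

write_two_csv <- function(target, features, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  tp <- file.path(dir, "target.csv"); fp <- file.path(dir, "features.csv")
  readr::write_csv(target, tp, progress = FALSE)
  readr::write_csv(features, fp, na = "NA", progress = FALSE)
  list(target = tp, features = fp, dir = dir)
}

`%||%` <- rlang::`%||%`

# the 6 permutations of three cluster labels
perms3 <- function() {
  rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
}
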