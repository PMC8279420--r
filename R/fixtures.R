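#' Specify a synthetic two-CSV study
#'
#' Describes a simulated quantified-omics experiment with known ground
#' truth: log-normal intensities, a multiplicative group effect on a chosen
#' set of informative features, optional correlated feature blocks (shared
#' latent factor on the log scale), missing-completely-at-random cells,
#' injected zeros, an optional shifted outlier sample, and covariates.
#'
#' Defaults mimic intensity-scale metabolomics data: log-normal with
#' `meanlog = 10`, `sdlog = 0.5`. Informative features receive a
#' multiplicative effect `exp(effect_size * sdlog)` in the second group,
#' i.e. `effect_size` is measured in within-group standard deviations on
#' the log scale. One seed governs all randomness.
#'
#' @param n_per_group integer vector, samples per group (one entry per group).
#' @param p_features number of features.
#' @param n_informative number of group-affected features (the first
#'   `n_informative` feature columns).
#' @param effect_size effect in units of the log-scale within-group sd.
#' @param meanlog,sdlog log-normal base distribution parameters.
#' @param missing_rate MCAR missing-cell fraction in `[0, 1]`.
#' @param zero_rate fraction of cells set to exact zero (after missingness).
#' @param outlier `NULL`, or a list with `sample` (index), `shift` (in sd
#'   units) and `fraction` (of features shifted).
#' @param correlation_blocks list of lists with `size` and `r` (target
#'   within-block correlation); blocks are carved from the tail (non-informative)
#'   features.
#' @param covariates list of covariate specs: `list(name=, type="numeric")`
#'   or `list(name=, type="categorical", levels=)`.
#' @param seed mandatory integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_per_group = c(20, 20), p_features = 100,
                         n_informative = 5, effect_size = 2,
                         meanlog = 10, sdlog = 0.5,
                         missing_rate = 0, zero_rate = 0,
                         outlier = NULL, correlation_blocks = list(),
                         covariates = list(), seed) {
  if (missing(seed)) abort("A seed is mandatory for fixture generation.")
  stopifnot(missing_rate >= 0, missing_rate <= 1, zero_rate >= 0, zero_rate <= 1,
            n_informative <= p_features, all(n_per_group >= 1))
  if (!is.null(outlier) && (outlier$sample < 1 || outlier$sample > sum(n_per_group))) {
    abort("Outlier sample index out of range.")
  }
  structure(list(
    n_per_group = n_per_group, p_features = p_features,
    n_informative = n_informative, effect_size = effect_size,
    meanlog = meanlog, sdlog = sdlog,
    missing_rate = missing_rate, zero_rate = zero_rate,
    outlier = outlier, correlation_blocks = correlation_blocks,
    covariates = covariates, seed = as.integer(seed)),
    class = "fixture_spec")
}

#' Generate a synthetic dataset with known ground truth
#'
#' @param spec a [fixture_spec()].
#' @param dir optional directory; when given, `target.csv`, `features.csv`
#'   and `truth.json` are written there (byte-identical for a given spec).
#' @return An [omics_data] object; the ground-truth record (informative
#'   features, outlier sample id, block membership) is attached and read
#'   with [fixture_truth()].
#' @export
generate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    n <- sum(spec$n_per_group)
    p <- spec$p_features
    grp <- factor(rep(paste0("G", seq_along(spec$n_per_group)), spec$n_per_group))
    logm <- matrix(rnorm(n * p, spec$meanlog, spec$sdlog), n, p)
    # correlated blocks share a latent factor on the log scale
    block_members <- list()
    free <- setdiff(seq_len(p), seq_len(spec$n_informative))
    for (b in spec$correlation_blocks) {
      if (b$size > length(free)) abort("Correlation block larger than remaining features.")
      idx <- free[seq_len(b$size)]
      free <- setdiff(free, idx)
      z <- rnorm(n)
      for (j in idx) {
        logm[, j] <- spec$meanlog +
          spec$sdlog * (sqrt(b$r) * z + sqrt(1 - b$r) * (logm[, j] - spec$meanlog) / spec$sdlog)
      }
      block_members[[length(block_members) + 1]] <- idx
    }
    inform <- seq_len(spec$n_informative)
    if (spec$n_informative > 0 && length(spec$n_per_group) >= 2) {
      in_g2 <- grp == levels(grp)[2]
      logm[in_g2, inform] <- logm[in_g2, inform] + spec$effect_size * spec$sdlog
    }
    if (!is.null(spec$outlier)) {
      jset <- sample(p, round(spec$outlier$fraction * p))
      logm[spec$outlier$sample, jset] <- logm[spec$outlier$sample, jset] +
        spec$outlier$shift * spec$sdlog
    }
    m <- exp(logm)
    if (spec$missing_rate > 0) {
      miss <- runif(n * p) < spec$missing_rate
      m[miss] <- NA_real_
    }
    if (spec$zero_rate > 0) {
      obs <- which(!is.na(m))
      nz <- round(spec$zero_rate * length(m))
      m[sample(obs, min(nz, length(obs)))] <- 0
    }
    dimnames(m) <- list(sprintf("sample%02d", seq_len(n)), sprintf("f%03d", seq_len(p)))
    samples <- tibble::tibble(sample_id = rownames(m), group = as.character(grp))
    for (cv in spec$covariates) {
      samples[[cv$name]] <- if (identical(cv$type, "categorical")) {
        sample(cv$levels, n, replace = TRUE)
      } else {
        round(rnorm(n), 6)
      }
    }
    ds <- omics_data(m, samples, log = sprintf("fixture: seed %d", spec$seed))
    truth <- list(
      informative_features = colnames(m)[inform],
      outlier_samples = if (is.null(spec$outlier)) character() else rownames(m)[spec$outlier$sample],
      blocks = lapply(block_members, function(i) colnames(m)[i]),
      spec = spec)
    attr(ds, "truth") <- truth
    if (!is.null(dir)) {
      write_omics(ds, dir)
      jsonlite::write_json(truth[c("informative_features", "outlier_samples", "blocks")],
                           file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
    }
    ds
  })
}

#' @rdname generate_fixture
#' @param ds a dataset returned by [generate_fixture()].
#' @export
fixture_truth <- function(ds) attr(ds, "truth")

#' Standard fixture presets
#'
#' Named study designs used throughout the package's tests and examples:
#' \describe{
#'   \item{two_group_basic}{20 + 20 samples, 100 features, 5 informative at
#'     effect 2 sd.}
#'   \item{three_group}{3 x 15 samples, 80 features, no informative features.}
#'   \item{outlier_one}{the two-group base plus one sample shifted 6 sd in
#'     60\% of features; no group effect so the outlier is the only signal.}
#'   \item{null_global}{20 + 20 samples, 150 features, no effects anywhere.}
#' }
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return A [fixture_spec()].
#' @export
fixture_preset <- function(name = c("two_group_basic", "three_group",
                                    "outlier_one", "null_global"), seed) {
  name <- rlang::arg_match(name)
  switch(name,
    two_group_basic = fixture_spec(n_per_group = c(20, 20), p_features = 100,
                                   n_informative = 5, effect_size = 2, seed = seed),
    three_group = fixture_spec(n_per_group = c(15, 15, 15), p_features = 80,
                               n_informative = 0, effect_size = 0, seed = seed),
    outlier_one = fixture_spec(n_per_group = c(20, 20), p_features = 100,
                               n_informative = 0, effect_size = 0,
                               outlier = list(sample = 1, shift = 6, fraction = 0.6),
                               seed = seed),
    null_global = fixture_spec(n_per_group = c(20, 20), p_features = 150,
                               n_informative = 0, effect_size = 0, seed = seed))
}
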