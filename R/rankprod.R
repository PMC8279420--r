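#' Rank product test for two-group differential abundance
#'
#' A non-parametric test on the ranks of fold changes. For each of K
#' pairwise comparisons (paired: the matched sample pairs; unpaired: a
#' seeded disjoint random matching of group-1 to group-2 samples, capped at
#' `max_comparisons`, so comparisons stay independent as the permutation
#' null assumes), the
#' per-feature log2 fold change (second group level over first) is ranked
#' across features — descending for the up-regulation statistic, ascending
#' for down-regulation, ties receiving average ranks. The rank product is
#' the geometric mean of a feature's ranks across comparisons; a small RP
#' means consistent regulation. Significance comes from within-comparison
#' rank permutations: per feature and direction,
#' `p = (1 + #\{permuted RP <= observed\}) / (1 + n_perm)`. The estimated
#' proportion of false positives at a feature's position is
#' `PFP = p * p_features / rank_position`.
#'
#' Fold changes need positive intensities, so run this on the raw
#' (pre-scaling) matrix; scaling destroys ratio meaning.
#'
#' @param ds an [omics_data] with exactly 2 groups and strictly positive
#'   values.
#' @param paired matched pairs by position within group (equal sizes
#'   required).
#' @param n_perm number of rank permutations (default 100).
#' @param max_comparisons cap on the number of unpaired comparisons
#'   (default 50).
#' @param seed integer seed (subsampling + permutations).
#' @param exact if `TRUE`, enumerate all `(p!)^K` equally likely rank
#'   configurations instead of sampling permutations (tiny instances only:
#'   requires `p! ^ K <= 1e6`); p-values are then exact and unsmoothed.
#' @return A `rank_product_result`: per-feature tibble with `rp_up`,
#'   `rp_down`, `p_up`, `p_down`, `pfp_up`, `pfp_down` and a `direction`
#'   call, plus the comparison count K.
#' @export
rank_products <- function(ds, paired = FALSE, n_perm = 100, max_comparisons = 50,
                          seed = NULL, exact = FALSE) {
  check_groups(ds, exactly = 2)
  g <- groups(ds)
  i1 <- which(g == levels(g)[1]); i2 <- which(g == levels(g)[2])
  if (!length(i1) || !length(i2)) abort("Both groups need at least one sample.")
  if (anyNA(ds$values)) abort("Matrix has missing cells; impute first.")
  if (any(ds$values <= 0)) {
    abort("Rank products need strictly positive intensities for log fold changes; add an offset or use the pre-normalization matrix.")
  }
  p <- n_features(ds)
  run <- function() {
    if (paired) {
      if (length(i1) != length(i2)) abort("Paired rank products need equal group sizes.")
      pairs <- cbind(i1, i2)
    } else {
      # disjoint random matching: each sample enters at most one comparison,
      # keeping the K comparisons independent as the rank-permutation null
      # assumes (all cross pairs would reuse samples and overdisperse RP)
      K0 <- min(length(i1), length(i2), max_comparisons)
      pairs <- cbind(sample(i1)[seq_len(K0)], sample(i2)[seq_len(K0)])
    }
    K <- nrow(pairs)
    # per-comparison feature log fold changes, features x K
    lfc <- vapply(seq_len(K), function(k) {
      log2(ds$values[pairs[k, 2], ] / ds$values[pairs[k, 1], ])
    }, numeric(p))
    ranks_down <- apply(lfc, 2, rank)            # most down-regulated = rank 1
    ranks_up <- apply(-lfc, 2, rank)             # most up-regulated = rank 1
    rp_obs <- function(r) unname(exp(rowMeans(log(r))))
    rp_up <- rp_obs(ranks_up); rp_down <- rp_obs(ranks_down)
    if (exact) {
      if (factorial(p)^K > 1e6) abort("Exact enumeration is limited to (p!)^K <= 1e6.")
      all_rp <- enumerate_rank_products(ranks_up)   # same configuration space both directions
      p_up <- vapply(rp_up, function(o) mean(all_rp <= o + 1e-12), numeric(1))
      p_down <- vapply(rp_down, function(o) mean(all_rp <= o + 1e-12), numeric(1))
    } else {
      cnt_up <- cnt_down <- integer(p)
      for (b in seq_len(n_perm)) {
        perm_u <- vapply(seq_len(K), function(k) sample(ranks_up[, k]), numeric(p))
        perm_d <- vapply(seq_len(K), function(k) sample(ranks_down[, k]), numeric(p))
        cnt_up <- cnt_up + (rp_obs(perm_u) <= rp_up + 1e-12)
        cnt_down <- cnt_down + (rp_obs(perm_d) <= rp_down + 1e-12)
      }
      p_up <- (1 + cnt_up) / (1 + n_perm)
      p_down <- (1 + cnt_down) / (1 + n_perm)
    }
    tab <- tibble::tibble(
      feature = feature_ids(ds),
      rp_up = rp_up, rp_down = rp_down,
      p_up = p_up, p_down = p_down,
      pfp_up = p_up * p / rank(rp_up, ties.method = "average"),
      pfp_down = p_down * p / rank(rp_down, ties.method = "average"),
      direction = ifelse(rp_up < rp_down, "up", ifelse(rp_down < rp_up, "down", "none")))
    structure(list(table = tab, n_comparisons = K, n_perm = if (exact) NA_integer_ else n_perm,
                   paired = paired, seed = seed, exact = exact),
              class = "rank_product_result")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# All (p!)^K rank-product values over independent permutations of the
# observed per-comparison rank vectors (preserves tie structure).
enumerate_rank_products <- function(ranks) {
  p <- nrow(ranks); K <- ncol(ranks)
  perms <- permutations(p)
  grids <- rep(list(seq_len(nrow(perms))), K)
  combos <- as.matrix(expand.grid(grids))
  out <- numeric(nrow(combos) * p)
  for (i in seq_len(nrow(combos))) {
    r <- vapply(seq_len(K), function(k) ranks[perms[combos[i, k], ], k], numeric(p))
    out[((i - 1) * p + 1):(i * p)] <- exp(rowMeans(log(r)))
  }
  out
}

permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' @export
print.rank_product_result <- function(x, ...) {
  cat(sprintf("<rank_product_result> K = %d comparisons (%s), %s\n",
              x$n_comparisons, if (x$paired) "paired" else "unpaired",
              if (x$exact) "exact enumeration" else sprintf("%d permutations", x$n_perm)))
  cat(sprintf("  features with p_up < 0.05: %d; p_down < 0.05: %d\n",
              sum(x$table$p_up < 0.05), sum(x$table$p_down < 0.05)))
  invisible(x)
}
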