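test_that("PCA satisfies the SVD identities", {
  # perfectly collinear features: one component carries all variance
  m <- cbind(f1 = c(1, 2, 3, 4), f2 = 2 * c(1, 2, 3, 4))
  ds <- make_ds(m, rep(c("A", "B"), each = 2))
  mod <- pca(ds, ncomp = 2)
  expect_equal(mod$explained_variance[1], 1)

  ds2 <- gauss_ds(c(5, 5), p = 6, seed = 11)
  mod2 <- pca(ds2, ncomp = 6)
  sc <- as.matrix(mod2$scores[, -(1:2)])
  expect_lt(max(abs(colMeans(sc))), 1e-10)  # centred scores

  # full-rank reconstruction reproduces the centred matrix
  lo <- as.matrix(mod2$loadings[, -1])
  recon <- sc %*% t(lo)
  centred <- scale(ds2$values, scale = FALSE)
  expect_lt(max(abs(recon - centred)), 1e-8)

  expect_error(pca(ds2, ncomp = 10), "ncomp")
})

test_that("classical MDS solves small geometries exactly", {
  # two points at distance d embed at +/- d/2
  d2 <- matrix(c(0, 3, 3, 0), 2, 2)
  co <- classical_mds(d2, ndim = 1)
  expect_equal(sort(co$axis1), c(-1.5, 1.5))

  # equilateral triangle, side 1: all embedded distances 1
  d3 <- matrix(1, 3, 3) - diag(3)
  co3 <- classical_mds(d3, ndim = 2)
  pts <- as.matrix(co3[, -1])
  expect_equal(as.vector(dist(pts)), rep(1, 3), tolerance = 1e-8)

  # Euclidean distances of a point cloud are reproduced at full rank
  withr::with_seed(8, {
    x <- matrix(rnorm(7 * 3), 7, 3)
    co7 <- classical_mds(dist(x), ndim = 3)
    expect_equal(as.vector(dist(as.matrix(co7[, -1]))), as.vector(dist(x)),
                 tolerance = 1e-8)
  })

  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("MDS of Euclidean distances matches PCA scores up to sign", {
  ds <- gauss_ds(c(6, 6), p = 10, seed = 14)
  mod <- pca(ds, ncomp = 2)
  co <- classical_mds(dist(ds$values), ndim = 2)
  for (k in 1:2) {
    a <- mod$scores[[paste0("comp", k)]]
    b <- co[[paste0("axis", k)]]
    expect_lt(min(sum((a - b)^2), sum((a + b)^2)), 1e-6)
  }
})

test_that("PLS-DA obeys the VIP identity and separates a planted feature", {
  ds <- gauss_ds(c(10, 10), p = 20, seed = 19)
  mod <- plsda(ds, ncomp = 2, cv = "none")
  expect_equal(mean(mod$vip$vip^2), 1, tolerance = 1e-10)
  expect_true(all(mod$vip$vip >= 0))

  # one feature carries a 10-sd separation: top VIP and zero LOO error
  ds2 <- gauss_ds(c(10, 10), p = 20, shift = 10, shifted_features = 1, seed = 20)
  mod2 <- plsda(ds2, ncomp = 2, cv = "loo")
  expect_equal(which.max(mod2$vip$vip), 1L)
  expect_equal(mod2$cv$error[1], 0)

  # first-component ranking equals |cov(x_j, y)| on centred data
  ds3 <- gauss_ds(c(8, 8), p = 15, shift = 1, shifted_features = 1:4, seed = 21)
  mod3 <- plsda(ds3, ncomp = 1, cv = "none")
  w1 <- abs(mod3$loadings$comp1)
  y <- as.numeric(groups(ds3) == "B")
  covs <- abs(apply(scale(ds3$values, scale = FALSE), 2, function(x) cov(x, y)))
  expect_equal(order(w1), order(unname(covs)))
})

test_that("permuted labels drive the PLS-DA CV error to chance", {
  ds <- gauss_ds(c(10, 10), p = 20, shift = 3, shifted_features = 1:5, seed = 30)
  errs <- vapply(1:20, function(s) {
    perm <- ds
    perm$samples$group <- withr::with_seed(s, sample(groups(ds)))
    min(plsda(perm, ncomp = 2, cv = "kfold", folds = 5, seed = s)$cv$error)
  }, numeric(1))
  expect_lt(abs(mean(errs) - 0.5), 0.15)
})

test_that("sparse PLS reduces to PLS-DA at keepX = p and respects keepX", {
  ds <- gauss_ds(c(8, 8), p = 12, shift = 1.5, shifted_features = 1:3, seed = 22)
  full <- plsda(ds, ncomp = 2, cv = "none")
  sp <- splsda(ds, ncomp = 2, keepX = 12, cv = "none")
  expect_equal(as.matrix(sp$loadings[, -1]), as.matrix(full$loadings[, -1]),
               tolerance = 1e-8)

  sp1 <- splsda(ds, ncomp = 2, keepX = 1, cv = "none")
  expect_equal(colSums(as.matrix(sp1$loadings[, -1]) != 0), c(comp1 = 1, comp2 = 1))
  expect_equal(lengths(sp1$selected), c(comp1 = 1L, comp2 = 1L))
  expect_error(splsda(ds, ncomp = 1, keepX = 0), "positive")
  expect_error(splsda(ds, ncomp = 1, keepX = 50), "exceed")
})

test_that("PLS-DA weights agree with the mixOmics reference", {
  skip_if_not_installed("mixOmics")
  ds <- gauss_ds(c(10, 10), p = 8, shift = 2, shifted_features = 1:2, seed = 25)
  mod <- plsda(ds, ncomp = 2, cv = "none")
  ref <- mixOmics::plsda(ds$values, groups(ds), ncomp = 2, scale = FALSE)
  for (k in 1:2) {
    a <- mod$loadings[[paste0("comp", k)]]
    b <- unname(ref$loadings$X[, k])
    expect_gt(abs(cor(a, b)), 1 - 1e-6)
  }
})

test_that("k-means scan picks well-separated blobs and a monotone WSS curve", {
  withr::with_seed(40, {
    centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
    m <- do.call(rbind, lapply(1:3, function(i) {
      sweep(matrix(rnorm(10 * 2), 10, 2), 2, centers[i, ], "+")
    }))
    colnames(m) <- c("f1", "f2")
    ds <- make_ds(m, rep(c("A", "B"), length.out = 30))
    cl <- kmeans_clusters(ds, k = "auto", max_k = 6, seed = 1)
    expect_equal(cl$k, 3L)
    planted <- rep(1:3, each = 10)
    agreement <- max(vapply(seq_len(6), function(i) {
      perm <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))[i, ]
      mean(perm[planted] == cl$assignments$cluster)
    }, numeric(1)))
    expect_gte(agreement, 0.95)
    expect_true(all(diff(cl$wss$wss) <= 1e-8))
  })

  ds2 <- gauss_ds(c(5, 5), p = 4, seed = 2)
  one <- kmeans_clusters(ds2, k = 1, seed = 1)
  total_ss <- sum(scale(ds2$values, scale = FALSE)^2)
  expect_equal(one$wss$wss[1], total_ss)
  expect_error(kmeans_clusters(ds2, k = 99, seed = 1), "exceed")
  expect_error(kmeans_clusters(ds2, max_k = 10, seed = 1), "max_k")
})
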