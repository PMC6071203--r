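# build a small stack of fake ec_map objects from a matrix of values
ec_maps_from_matrix <- function(X, mask, meta = NULL) {
  lapply(seq_len(nrow(X)), function(i) {
    structure(list(values = X[i, ], lambda = 1, n_iter = 1, flagged = integer(0),
                   mask = mask,
                   subject_id = if (is.null(meta)) sprintf("S%02d", (i + 1) %/% 2)
                                else meta$subject_id[i],
                   condition = if (is.null(meta)) c("rest", "task")[(i - 1) %% 2 + 1]
                               else meta$condition[i]),
              class = "ec_map")
  })
}

test_that("stacking z-scores rows then demeans columns, keeping metadata", {
  mask <- flat_mask(50)
  set.seed(1)
  X <- matrix(abs(rnorm(8 * 50)), 8, 50)
  maps <- ec_maps_from_matrix(X, mask)
  em <- stack_ec_maps(maps, mask)
  expect_equal(dim(em$X), c(8, 50))
  expect_equal(colMeans(em$X), rep(0, 50), tolerance = 1e-12)
  # rows were z-scored before the column demeaning
  Z <- t(scale(t(X)))
  expect_equal(em$X, scale(Z, center = TRUE, scale = FALSE),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(em$meta$condition, rep(c("rest", "task"), 4))

  ident <- ec_maps_from_matrix(matrix(rep(X[1, ], 4), 4, byrow = TRUE), mask)
  em0 <- stack_ec_maps(ident, mask)
  expect_equal(max(abs(em0$X)), 0)
})

test_that("spatial ICA recovers planted super-Gaussian sources and weights", {
  atl <- generate_network_maps(c(16, 16, 10), 3, seed = 3)
  S <- hubcent:::atlas_matrix(atl)
  set.seed(4)
  A <- matrix(rnorm(30 * 3), 30, 3)
  X <- A %*% S + matrix(rnorm(30 * ncol(S), sd = 0.02), 30)
  dec <- fit_spatial_ica(X, K = 3, seed = 1)
  m <- match_components(dec$spatial_maps, S)
  expect_true(all(m$abs_cor > 0.95))
  for (i in seq_len(3))
    expect_gt(abs(cor(dec$weights[, m$est[i]], A[, m$ref[i]])), 0.9)

  # identical seed, identical fit
  dec2 <- fit_spatial_ica(X, K = 3, seed = 1)
  expect_identical(dec$spatial_maps, dec2$spatial_maps)

  expect_error(fit_spatial_ica(X, K = 40, seed = 1),
               class = "hubcent_dim_error")
})

test_that("rank-one data is identified by a single component", {
  atl <- generate_network_maps(c(14, 14, 8), 1, seed = 5)
  s <- hubcent:::atlas_matrix(atl)[1, ]
  a <- rnorm(10)
  X <- outer(a, s)
  dec <- fit_spatial_ica(X, K = 1, seed = 2)
  expect_gt(abs(cor(dec$spatial_maps[1, ], s)), 0.999)
})

test_that("ICA reconstruction is as good as the PCA(K) truncation", {
  set.seed(6)
  X <- matrix(rnorm(20 * 200), 20, 200) +
    matrix(rnorm(20 * 4), 20, 4) %*% matrix(abs(rnorm(4 * 200))^2, 4, 200)
  K <- 4
  dec <- fit_spatial_ica(X, K = K, seed = 1)
  resid_ica <- sum((X - reconstruct(dec))^2)
  Xc <- X - rowMeans(X)
  sv <- svd(Xc)
  pca_K <- sv$u[, 1:K] %*% diag(sv$d[1:K]) %*% t(sv$v[, 1:K])
  resid_pca <- sum((Xc + rowMeans(X) - (pca_K + rowMeans(X)))^2)
  expect_lte(resid_ica, resid_pca + 1e-6)
})

test_that("canonicalization fixes signs, is idempotent, preserves fit", {
  atl <- generate_network_maps(c(14, 14, 8), 3, seed = 7)
  S <- hubcent:::atlas_matrix(atl)
  set.seed(8)
  X <- matrix(rnorm(24 * 3), 24, 3) %*% S + matrix(rnorm(24 * ncol(S), sd = 0.02), 24)
  dec <- fit_spatial_ica(X, K = 3, seed = 1)
  can <- canonicalize_components(dec)
  skews <- apply(can$spatial_maps, 1, function(s) mean((s - mean(s))^3))
  expect_true(all(skews > 0))        # blob maps are right-skewed
  expect_equal(reconstruct(can), reconstruct(dec), tolerance = 1e-10)
  again <- canonicalize_components(can)
  expect_identical(again$spatial_maps, can$spatial_maps)
  expect_identical(again$weights, can$weights)
})

test_that("artifact components are excluded by reference matching", {
  atl <- generate_network_maps(c(18, 18, 10), 8, seed = 9)
  M <- hubcent:::atlas_matrix(atl)
  signal <- M[1:6, , drop = FALSE]
  artifact <- M[7:8, , drop = FALSE]
  set.seed(10)
  A <- matrix(rnorm(40 * 8), 40, 8)
  X <- A %*% M + matrix(rnorm(40 * ncol(M), sd = 0.02), 40)
  dec <- fit_spatial_ica(X, K = 8, seed = 1)
  dec <- classify_artifact_components(dec, signal, artifact)
  expect_equal(sum(dec$retained), 6)
  # retained components are exactly those matching signal references
  m <- match_components(dec$spatial_maps, M)
  expect_setequal(m$est[m$ref <= 6], which(dec$retained))

  expect_warning(d2 <- classify_artifact_components(dec), "no reference")
  expect_true(all(d2$retained))
})

test_that("weight clustering groups components by weight correlation", {
  set.seed(11)
  n <- 60
  g1 <- rnorm(n); g2 <- rnorm(n)
  W <- cbind(g1 + rnorm(n, sd = 0.3), g1 + rnorm(n, sd = 0.3),
             g2 + rnorm(n, sd = 0.3), g2 + rnorm(n, sd = 0.3))
  dec <- structure(list(weights = W, retained = rep(TRUE, 4), K = 4,
                        spatial_maps = matrix(rnorm(4 * 10), 4),
                        meta = NULL), class = "ec_decomposition")
  cl <- component_weight_clustering(dec, cut_k = 2)
  expect_true(isSymmetric(cl$correlation))
  expect_equal(diag(cl$correlation), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cl$labels[[1]], cl$labels[[2]])
  expect_equal(cl$labels[[3]], cl$labels[[4]])
  expect_false(cl$labels[[1]] == cl$labels[[3]])

  # perfectly correlated weights merge first at distance 0
  W2 <- cbind(g1, g1, g2)
  dec2 <- dec; dec2$weights <- W2; dec2$K <- 3; dec2$retained <- rep(TRUE, 3)
  cl2 <- component_weight_clustering(dec2, cut_k = 2)
  expect_equal(cl2$hclust$height[1], 0, tolerance = 1e-12)
  expect_setequal(abs(cl2$hclust$merge[1, ]), c(1, 2))

  dec3 <- dec; dec3$weights[, 2] <- 5
  expect_error(component_weight_clustering(dec3),
               class = "hubcent_data_error")
  dec4 <- dec; dec4$retained <- c(TRUE, rep(FALSE, 3))
  expect_error(component_weight_clustering(dec4),
               class = "hubcent_data_error")
})

test_that("downstream statistics ignore ICA scale ambiguity", {
  cfg <- test_cohort_config(n_subjects = 8, seed = 12)
  co <- generate_cohort(cfg)
  ec <- lapply(co$runs, compute_ec_map, mask = co$mask)
  dec <- canonicalize_components(
    fit_spatial_ica(stack_ec_maps(ec, co$mask), K = 4, seed = 1))
  st1 <- component_statistics(dec, co$subjects)
  dec2 <- dec
  for (k in seq_len(dec2$K)) {
    c_k <- k + 0.5
    dec2$spatial_maps[k, ] <- dec2$spatial_maps[k, ] * c_k
    dec2$weights[, k] <- dec2$weights[, k] / c_k
  }
  st2 <- component_statistics(dec2, co$subjects)
  expect_equal(st1$t, st2$t, tolerance = 1e-8)
  expect_equal(st1$p, st2$p, tolerance = 1e-8)
})
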