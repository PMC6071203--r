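test_that("preprocessing detrends, standardizes, and flags dead voxels", {
  set.seed(1)
  Tn <- 40
  X <- cbind(2 * seq_len(Tn) + sin(seq_len(Tn)),
             rnorm(Tn),
             rep(3, Tn))                      # constant voxel
  run <- run_from_matrix(X)
  cfg <- ecm_config(highpass_hz = NULL)
  expect_warning(Z <- preprocess_timeseries(run, flat_mask(3), cfg),
                 "zero-variance")
  expect_identical(attr(Z, "flagged"), 3L)
  expect_identical(attr(Z, "voxel_index"), 1:2)
  expect_equal(colMeans(Z), c(0, 0), tolerance = 1e-9)
  expect_equal(apply(Z, 2, var), c(1, 1), tolerance = 1e-9)
  # standardized column dotted with itself equals T - 1 (sample-SD convention)
  expect_equal(sum(Z[, 1]^2), Tn - 1, tolerance = 1e-9)

  allconst <- run_from_matrix(matrix(1, Tn, 2))
  expect_error(suppressWarnings(
    preprocess_timeseries(allconst, flat_mask(2), cfg)),
    class = "hubcent_data_error")
})

test_that("high-pass filtering removes slow drift", {
  Tn <- 100
  slow <- sin(2 * pi * 0.002 * (seq_len(Tn)) * 3)       # 0.002 Hz, TR 3
  fast <- sin(2 * pi * 0.05 * (seq_len(Tn)) * 3)
  run <- run_from_matrix(cbind(slow + fast, rnorm(Tn)))
  Z <- preprocess_timeseries(run, flat_mask(2), ecm_config(highpass_hz = 0.01))
  # the slow component is gone: residual correlates with the fast part only
  expect_gt(abs(cor(Z[, 1], fast)), 0.95)
  expect_lt(abs(cor(Z[, 1], slow)), 0.4)
})

test_that("|corr| matvec weighs positive and negative correlations equally", {
  set.seed(2)
  x <- scale(rnorm(20))[, 1]           # mean 0, sample SD 1
  X <- cbind(x, x, -x)
  y <- abs_corr_matvec(X, c(0, 1, 0))
  expect_equal(y[1], 1, tolerance = 1e-12)     # identical series
  y2 <- abs_corr_matvec(X, c(0, 0, 1))
  expect_equal(y2[1], 1, tolerance = 1e-12)    # perfectly anti-correlated

  expect_error(abs_corr_matvec(X, c(1, 2)), class = "hubcent_dim_error")
})

test_that("blockwise matvec equals the dense |corr| product for any block size", {
  set.seed(42)
  X <- scale(matrix(rnorm(30 * 10), 30, 10))   # mean 0, sample SD 1
  A <- abs(cor(X))
  for (rep in 1:5) {
    v <- rnorm(10)
    dense <- as.numeric(A %*% v)
    for (b in c(1L, 3L, 10L, 64L)) {
      expect_equal(abs_corr_matvec(X, v, block_rows = b), dense,
                   tolerance = 1e-10)
    }
  }
})

test_that("power iteration solves analytic and random symmetric cases", {
  m <- matrix(c(2, 1, 1, 2), 2)
  r <- power_iteration(function(v) as.numeric(m %*% v), 2)
  expect_equal(r$vector, rep(1 / sqrt(2), 2), tolerance = 1e-6)
  expect_equal(r$lambda, 3, tolerance = 1e-6)

  ones <- matrix(1, 5, 5)
  r <- power_iteration(function(v) as.numeric(ones %*% v), 5)
  expect_equal(r$vector, rep(1 / sqrt(5), 5), tolerance = 1e-8)
  expect_equal(r$lambda, 5, tolerance = 1e-8)

  set.seed(3)
  for (rep in 1:5) {
    B <- matrix(runif(144), 12); A <- (B + t(B)) / 2
    r <- power_iteration(function(v) as.numeric(A %*% v), 12,
                         ecm_config(tolerance = 1e-12))
    e <- eigen(A, symmetric = TRUE)
    ev <- e$vectors[, 1] * sign(sum(e$vectors[, 1]))
    expect_gt(cosine(r$vector, ev), 1 - 1e-9)
    expect_equal(r$lambda, e$values[1], tolerance = 1e-6)
  }

  slow <- matrix(c(2, 1, 1, 1), 2)    # uniform start is not the eigenvector
  expect_error(
    power_iteration(function(v) as.numeric(slow %*% v), 2,
                    ecm_config(tolerance = 1e-14, max_iterations = 2L)),
    class = "hubcent_convergence_error")
})

test_that("EC maps are nonnegative, unit-norm, and match the dense oracle", {
  set.seed(11)
  cfg <- ecm_config(highpass_hz = NULL, tolerance = 1e-10)
  for (rep in 1:5) {
    V <- sample(10:40, 1)
    X <- matrix(rnorm(30 * V), 30, V)
    run <- run_from_matrix(X)
    ec <- compute_ec_map(run, flat_mask(V), cfg)
    expect_true(all(ec$values >= 0))
    expect_equal(sqrt(sum(ec$values^2)), 1, tolerance = 1e-9)
    expect_gt(ec$lambda, 0)
    Z <- preprocess_timeseries(run, flat_mask(V), cfg)
    expect_gt(cosine(ec$values, dense_ec_oracle(Z)$vector), 1 - 1e-9)
  }
})

test_that("near-identical voxel series give a near-uniform EC map", {
  set.seed(5)
  base <- rnorm(40)
  X <- sapply(1:12, function(i) base + rnorm(40, sd = 1e-4))
  ec <- compute_ec_map(run_from_matrix(X), flat_mask(12),
                       ecm_config(highpass_hz = NULL))
  expect_equal(ec$values, rep(1 / sqrt(12), 12), tolerance = 1e-4)
})

test_that("keeping or zeroing the |corr| diagonal leaves EC unchanged", {
  set.seed(21)
  for (rep in 1:5) {
    X <- matrix(rnorm(25 * 10), 25, 10)
    run <- run_from_matrix(X)
    e1 <- compute_ec_map(run, flat_mask(10),
                         ecm_config(highpass_hz = NULL, keep_diagonal = TRUE,
                                    tolerance = 1e-10))
    e2 <- compute_ec_map(run, flat_mask(10),
                         ecm_config(highpass_hz = NULL, keep_diagonal = FALSE,
                                    tolerance = 1e-10))
    expect_equal(e1$values, e2$values, tolerance = 1e-9)
    expect_equal(e1$lambda - 1, e2$lambda, tolerance = 1e-6)
  }
})

test_that("EC is equivariant under voxel permutation", {
  set.seed(31)
  X <- matrix(rnorm(30 * 15), 30, 15)
  perm <- sample(15)
  cfg <- ecm_config(highpass_hz = NULL, tolerance = 1e-10)
  e1 <- compute_ec_map(run_from_matrix(X), flat_mask(15), cfg)
  e2 <- compute_ec_map(run_from_matrix(X[, perm]), flat_mask(15), cfg)
  expect_equal(e2$values, e1$values[perm], tolerance = 1e-7)
})

test_that("zero-variance voxels get EC zero and the rest stays unit norm", {
  set.seed(41)
  X <- cbind(matrix(rnorm(30 * 8), 30, 8), rep(1, 30))
  ec <- suppressWarnings(
    compute_ec_map(run_from_matrix(X), flat_mask(9),
                   ecm_config(highpass_hz = NULL)))
  expect_equal(ec$values[9], 0)
  expect_equal(sqrt(sum(ec$values^2)), 1, tolerance = 1e-9)
})

test_that("an exactly reducible correlation graph raises a diagnostics error", {
  # two orthogonal blocks: group 1 follows one pattern, group 2 another
  p1 <- rep(c(1, -1), 10)
  p2 <- rep(c(1, 1, -1, -1), 5)
  X <- cbind(p1, p1, p2, p2)
  expect_error(compute_ec_map(run_from_matrix(X), flat_mask(4),
                              ecm_config(highpass_hz = NULL, detrend = FALSE)),
               class = "hubcent_reducible_error")
})

test_that("a planted hub network has higher EC inside its voxels", {
  cfg <- test_cohort_config(n_subjects = 1, seed = 13)
  co <- generate_cohort(cfg)
  ec <- compute_ec_map(co$runs[[2]], co$mask)   # task run, strong coupling
  M <- hubcent:::atlas_matrix(co$atlas)
  hub <- M[1, ] > 0.5
  expect_gt(mean(ec$values[hub]), mean(ec$values[!hub]))
})
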