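#' TFCE parameters
#'
#' @param E cluster-extent exponent.
#' @param H cluster-height exponent.
#' @param n_steps threshold integration steps.
#' @param connectivity 6, 18, or 26-neighbourhood.
#' @return object of class `tfce_params`.
#' @export
tfce_params <- function(E = 0.5, H = 2.0, n_steps = 100L, connectivity = 6L) {
  if (E <= 0 || H <= 0) stop_hubcent("E and H must be > 0",
                                     class = "hubcent_config_error")
  if (n_steps < 10L) stop_hubcent("n_steps must be >= 10",
                                  class = "hubcent_config_error")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop_hubcent("connectivity must be 6, 18 or 26",
                 class = "hubcent_config_error")
  structure(list(E = E, H = H, n_steps = as.integer(n_steps),
                 connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

#' Per-subject task-minus-rest EC difference maps
#'
#' @param ec_task,ec_rest lists of `ec_map` objects; subjects are paired by
#'   `subject_id`, unpaired subjects dropped with a warning.
#' @return subjects x voxels matrix of difference maps (rownames =
#'   subject ids).
#' @export
voxelwise_difference <- function(ec_task, ec_rest) {
  tid <- vapply(ec_task, function(m) m$subject_id, character(1))
  rid <- vapply(ec_rest, function(m) m$subject_id, character(1))
  common <- intersect(tid, rid)
  dropped <- setdiff(union(tid, rid), common)
  if (length(dropped) > 0L)
    warn_hubcent("unpaired subject(s) dropped from difference maps: %s",
                 paste(dropped, collapse = ", "))
  if (length(common) == 0L)
    stop_hubcent("no paired subjects", class = "hubcent_data_error")
  D <- t(vapply(common, function(s) {
    ec_task[[match(s, tid)]]$values - ec_rest[[match(s, rid)]]$values
  }, numeric(length(ec_task[[1]]$values))))
  rownames(D) <- common
  D
}

#' Voxel-wise group-level t map
#'
#' Either a one-sample t test across subjects at every voxel, or an OLS
#' regression of the voxel values on age adjusting for sex (intercept
#' included). Voxels with zero residual variance get t = 0 and are flagged.
#'
#' @param maps subjects x voxels matrix.
#' @param covariates data.frame with `age` and `sex` (regression only).
#' @param test `"one_sample"` or `"regression"`.
#' @return object of class `voxel_tmap`: `t` (length V), `flagged`, `df`,
#'   `test`.
#' @export
voxelwise_glm <- function(maps, covariates = NULL,
                          test = c("one_sample", "regression")) {
  test <- match.arg(test)
  Y <- as.matrix(maps)
  n <- nrow(Y)
  if (n < 3L) stop_hubcent("need >= 3 maps", class = "hubcent_data_error")
  if (test == "one_sample") {
    m <- colMeans(Y)
    s <- sqrt((colSums(Y^2) - n * m^2) / (n - 1))
    s[s < 0 | !is.finite(s)] <- 0
    flagged <- which(s == 0)
    tv <- numeric(ncol(Y))
    ok <- s > 0
    tv[ok] <- m[ok] / (s[ok] / sqrt(n))
    df <- n - 1
  } else {
    if (is.null(covariates) || anyNA(covariates) ||
        !all(c("age", "sex") %in% names(covariates)))
      stop_hubcent("regression needs complete covariates with age and sex",
                   class = "hubcent_data_error")
    X <- cbind(1, covariates$sex, covariates$age)
    if (nrow(X) != n) stop_hubcent("covariate rows do not match maps",
                                   class = "hubcent_dim_error")
    qrX <- qr(X)
    B <- qr.coef(qrX, Y)
    R <- Y - X %*% B
    df <- n - ncol(X)
    sigma2 <- colSums(R^2) / df
    cjj <- chol2inv(qr.R(qrX))[3, 3]
    se <- sqrt(sigma2 * cjj)
    flagged <- which(se == 0 | !is.finite(se))
    tv <- numeric(ncol(Y))
    ok <- !(seq_len(ncol(Y)) %in% flagged)
    tv[ok] <- B[3, ok] / se[ok]
  }
  structure(list(t = tv, flagged = flagged, df = df, test = test),
            class = "voxel_tmap")
}

#' Threshold-free cluster enhancement
#'
#' Integrates `extent(h)^E * h^H` over `n_steps` thresholds from 0 to the map
#' maximum (midpoint rule), where `extent(h)` is the size of the voxel's
#' connected supra-threshold cluster. Only the positive part is enhanced;
#' two-tailed use enhances the map and its negation separately (see
#' [permutation_fwe()]).
#'
#' @param stat_map 3-D array on the grid, or vector over in-mask voxels.
#' @param mask `brain_mask`.
#' @param params `tfce_params`.
#' @return enhanced map in the same form as the input.
#' @export
tfce <- function(stat_map, mask, params = tfce_params()) {
  as_vec <- !is.array(stat_map)
  if (as_vec) {
    if (length(stat_map) != length(mask$idx))
      stop_hubcent("map length does not match mask", class = "hubcent_dim_error")
    full <- numeric(prod(mask$dims))
    full[mask$idx] <- stat_map
  } else {
    if (!identical(dim(stat_map), as.integer(mask$dims)))
      stop_hubcent("map grid does not match mask", class = "hubcent_grid_error")
    full <- as.numeric(stat_map)
  }
  if (any(!is.finite(full[mask$idx])))
    stop_hubcent("non-finite values in map", class = "hubcent_data_error")
  out <- tfce_cpp(full, as.integer(mask$dims), as.logical(mask$array),
                  params$E, params$H, params$n_steps, params$connectivity)
  if (as_vec) out[mask$idx] else array(out, dim = mask$dims)
}

#' Permutation-based FWE-corrected voxel-wise inference with TFCE
#'
#' One-sample tests use random sign flips of the subject maps; regressions
#' use the Freedman-Lane scheme (residualize on intercept + sex, permute
#' residuals, refit the full model). Every permutation's t map is enhanced
#' with TFCE on both the map and its negation, and the maximum over both
#' signs and all voxels forms the null distribution, giving two-tailed
#' family-wise error control:
#' `p(v) = (1 + #\{perm max >= observed TFCE(v)\}) / (n_perm + 1)`.
#'
#' @param maps subjects x voxels matrix (difference maps or condition maps).
#' @param mask `brain_mask`.
#' @param covariates data.frame with `age` and `sex` (regression only).
#' @param test `"one_sample"` or `"regression"`.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed; results are deterministic given the seed.
#' @param params `tfce_params`.
#' @param alpha nominal level used only to warn when `n_perm` is too small
#'   to resolve it.
#' @return object of class `voxel_stat`: `t` map, `tfce_obs` (two-tailed
#'   enhanced magnitudes), `p_fwe`, `max_null` (permutation max
#'   distribution), `n_perm`, `seed`, `params`, `df`.
#' @export
permutation_fwe <- function(maps, mask, covariates = NULL,
                            test = c("one_sample", "regression"),
                            n_perm = 500L, seed = 1L,
                            params = tfce_params(), alpha = 0.05) {
  test <- match.arg(test)
  if (n_perm < 100L)
    stop_hubcent("n_perm must be >= 100", class = "hubcent_config_error")
  if (1 / (n_perm + 1) > alpha)
    warn_hubcent("n_perm = %d cannot resolve alpha = %g", n_perm, alpha)
  Y <- as.matrix(maps)
  n <- nrow(Y); V <- ncol(Y)
  obs <- voxelwise_glm(Y, covariates, test)
  enh_two <- function(tv) {
    pmax(tfce(tv, mask, params), tfce(-tv, mask, params))
  }
  tfce_obs <- enh_two(obs$t)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  max_null <- numeric(n_perm)
  if (test == "one_sample") {
    ss <- colSums(Y^2)                       # invariant under sign flips
    for (b in seq_len(n_perm)) {
      eps <- sample(c(-1, 1), n, replace = TRUE)
      m <- as.numeric(crossprod(eps, Y)) / n
      s2 <- (ss - n * m^2) / (n - 1)
      tv <- ifelse(s2 > 0, m / sqrt(s2 / n), 0)
      max_null[b] <- max(enh_two(tv))
    }
  } else {
    Z <- cbind(1, covariates$sex)
    X <- cbind(1, covariates$sex, covariates$age)
    qrZ <- qr(Z); qrX <- qr(X)
    Ry <- Y - Z %*% qr.coef(qrZ, Y)          # residualize on nuisance
    cjj <- chol2inv(qr.R(qrX))[3, 3]
    df <- n - ncol(X)
    for (b in seq_len(n_perm)) {
      Yp <- Ry[sample.int(n), , drop = FALSE]
      B <- qr.coef(qrX, Yp)
      R <- Yp - X %*% B
      se <- sqrt(colSums(R^2) / df * cjj)
      tv <- ifelse(se > 0, B[3, ] / se, 0)
      max_null[b] <- max(enh_two(tv))
    }
  }
  p_fwe <- (1 + vapply(tfce_obs, function(o) sum(max_null >= o),
                       numeric(1))) / (n_perm + 1)
  structure(list(t = obs$t, tfce_obs = tfce_obs, p_fwe = p_fwe,
                 max_null = max_null, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), params = params, df = obs$df,
                 flagged = obs$flagged, test = test),
            class = "voxel_stat")
}

#' @export
print.voxel_stat <- function(x, ...) {
  cat(sprintf("<voxel_stat> %s test, %d voxels, %d permutations; %d voxels FWE-significant at 0.05\n",
              x$test, length(x$t), x$n_perm, sum(x$p_fwe <= 0.05)))
  invisible(x)
}
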