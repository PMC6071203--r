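#' ECM configuration
#'
#' @param tolerance relative L2-change convergence threshold of the power
#'   iteration.
#' @param max_iterations iteration cap.
#' @param block_rows rows per block in the blockwise |correlation|
#'   matrix-vector product; peak memory is O(block_rows x V).
#' @param highpass_hz optional high-pass cutoff in Hz (DCT-basis removal);
#'   `NULL` disables filtering.
#' @param keep_diagonal keep the unit diagonal of the |correlation| matrix.
#'   Immaterial to the eigenvector (shifts every eigenvalue by 1); kept by
#'   default so the reported leading eigenvalue matches the full graph.
#' @param detrend remove a linear trend before filtering.
#' @param cache_voxels when the working voxel count is at or below this, the
#'   |correlation| matrix is materialized once and reused across iterations;
#'   above it, every product is recomputed blockwise so memory stays
#'   O(block_rows x V).
#' @return object of class `ecm_config`.
#' @export
ecm_config <- function(tolerance = 1e-6, max_iterations = 1000L,
                       block_rows = 512L, highpass_hz = 0.01,
                       keep_diagonal = TRUE, detrend = TRUE,
                       cache_voxels = 4000L) {
  if (tolerance <= 0) stop_hubcent("tolerance must be > 0",
                                   class = "hubcent_config_error")
  if (max_iterations < 1L) stop_hubcent("max_iterations must be >= 1",
                                        class = "hubcent_config_error")
  structure(list(tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 block_rows = as.integer(block_rows),
                 highpass_hz = highpass_hz,
                 keep_diagonal = isTRUE(keep_diagonal),
                 detrend = isTRUE(detrend),
                 cache_voxels = as.integer(cache_voxels)),
            class = "ecm_config")
}

#' Detrend, filter and standardize in-mask voxel time series
#'
#' Each in-mask voxel series is linearly detrended, high-pass filtered by
#' regressing out discrete-cosine drift terms below the cutoff, and
#' standardized to zero mean and unit variance (sample SD, denominator T-1,
#' so a standardized column dotted with itself equals T-1). Voxels with zero
#' variance are flagged, removed from the working set, and reported with a
#' warning.
#'
#' @param run `bold_run` (or any list with a 4-D `data` array and
#'   `tr_seconds`).
#' @param mask `brain_mask` on the same grid.
#' @param config `ecm_config`.
#' @return T x V_kept standardized matrix with attributes `voxel_index`
#'   (positions of kept voxels within the mask index) and `flagged`
#'   (positions of removed zero-variance voxels).
#' @export
preprocess_timeseries <- function(run, mask, config = ecm_config()) {
  d <- dim(run$data)
  if (!identical(d[1:3], as.integer(mask$dims)))
    stop_hubcent("run grid %s does not match mask grid %s",
                 paste(d[1:3], collapse = "x"),
                 paste(mask$dims, collapse = "x"),
                 class = "hubcent_grid_error")
  Tn <- d[4]
  if (Tn < 8L) stop_hubcent("run must have >= 8 timepoints",
                            class = "hubcent_data_error")
  X <- matrix(run$data, prod(d[1:3]), Tn)[mask$idx, , drop = FALSE]
  X <- t(X)                                  # T x V
  # nuisance basis: intercept (+ linear trend) (+ DCT drift terms < cutoff)
  basis <- matrix(1, Tn, 1)
  if (config$detrend) basis <- cbind(basis, seq_len(Tn) - (Tn + 1) / 2)
  if (!is.null(config$highpass_hz) && config$highpass_hz > 0) {
    run_sec <- Tn * run$tr_seconds
    n_dct <- floor(2 * run_sec * config$highpass_hz)
    if (n_dct >= 1) {
      t0 <- seq_len(Tn) - 0.5
      for (j in seq_len(n_dct))
        basis <- cbind(basis, cos(pi * j * t0 / Tn))
    }
  }
  scale0 <- apply(X, 2, function(v) sd(v) + abs(mean(v)))  # pre-filter scale
  X <- stats::lm.fit(basis, X)$residuals
  s <- apply(X, 2, sd)
  # a voxel whose residual variance is zero at working precision (constant or
  # pure-drift series) carries no signal for the correlation graph
  flagged <- which(!is.finite(s) | s <= 1e-10 * (scale0 + 1))
  keep <- setdiff(seq_len(ncol(X)), flagged)
  if (length(keep) == 0L)
    stop_hubcent("all in-mask voxels have zero variance",
                 class = "hubcent_data_error")
  if (length(flagged) > 0L)
    warn_hubcent("%d zero-variance voxel(s) removed from ECM working set",
                 length(flagged))
  X <- sweep(X[, keep, drop = FALSE], 2, s[keep], "/")
  attr(X, "voxel_index") <- keep
  attr(X, "flagged") <- flagged
  X
}

#' Blockwise |correlation|-graph matrix-vector product
#'
#' Computes `y_i = sum_j |r_ij| v_j` where `r_ij` is the Pearson correlation
#' of voxels i and j, taking the absolute value so positive and negative
#' correlations carry equal weight. The V x V matrix is never materialized:
#' rows are processed in blocks of `block_rows`.
#'
#' @param X T x V matrix with standardized columns
#'   (see [preprocess_timeseries()]).
#' @param v numeric vector of length V.
#' @param block_rows rows per block.
#' @param keep_diagonal keep the unit self-correlation on the diagonal.
#' @return numeric vector of length V; identical (to ~1e-10) for any
#'   `block_rows`.
#' @export
abs_corr_matvec <- function(X, v, block_rows = 512L, keep_diagonal = TRUE) {
  V <- ncol(X)
  if (length(v) != V)
    stop_hubcent("v has length %d, X has %d columns", length(v), V,
                 class = "hubcent_dim_error")
  Tn <- nrow(X)
  y <- numeric(V)
  start <- 1L
  while (start <= V) {
    end <- min(start + block_rows - 1L, V)
    Rb <- crossprod(X[, start:end, drop = FALSE], X) / (Tn - 1)
    y[start:end] <- abs(Rb) %*% v
    start <- end + 1L
  }
  if (!keep_diagonal) y <- y - v
  y
}

#' Power iteration for the leading eigenpair
#'
#' Iterates `v <- normalize(matvec(v))` from the uniform positive vector
#' until the relative L2 change drops below the tolerance. For the action of
#' a nonnegative symmetric matrix the iterate stays nonnegative and converges
#' to the Perron-Frobenius eigenvector.
#'
#' @param matvec function of one V-vector returning the matrix action.
#' @param V dimension.
#' @param config `ecm_config` (tolerance, max_iterations).
#' @return list with `vector` (nonnegative, unit L2 norm), `lambda`
#'   (Rayleigh-quotient eigenvalue), `n_iter`.
#' @export
power_iteration <- function(matvec, V, config = ecm_config()) {
  v <- rep(1 / sqrt(V), V)
  resid <- Inf
  for (it in seq_len(config$max_iterations)) {
    w <- matvec(v)
    lambda <- sum(v * w)
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop_hubcent("matvec returned the zero vector",
                              class = "hubcent_numeric_error")
    w <- w / nw
    resid <- sqrt(sum((w - v)^2))
    v <- w
    if (resid < config$tolerance)
      return(list(vector = v, lambda = lambda, n_iter = it))
  }
  stop_hubcent("power iteration did not converge in %d iterations (last relative change %.3g)",
               config$max_iterations, resid, class = "hubcent_convergence_error")
}

# Reachability diagnostic: with continuous data |r| > 0 almost surely, but a
# synthetic run can yield an exactly block-diagonal |corr| graph, where the
# leading eigenvector would silently pick one component. Spread an indicator
# from voxel 1 through the off-diagonal graph; entries that never receive
# weight above tolerance are unreachable.
check_irreducible <- function(matvec, V, keep_diagonal, tol = 1e-10,
                              max_sweeps = 50L) {
  x <- numeric(V); x[1] <- 1
  for (i in seq_len(max_sweeps)) {
    y <- matvec(x)
    if (keep_diagonal) y <- y - x   # remove self-weight
    reached <- (y > tol) | (x > 0)
    if (all(reached)) return(invisible(TRUE))
    if (sum(reached) == sum(x > 0)) break  # no growth: disconnected
    x <- as.numeric(reached)
  }
  stop_hubcent("correlation graph is reducible: %d of %d voxels unreachable",
               V - sum(x > 0), V, class = "hubcent_reducible_error")
}

#' Voxel-wise eigenvector centrality of one run
#'
#' Composes preprocessing, the blockwise |correlation| product, and power
#' iteration into one EC map per run: each voxel's centrality is its entry in
#' the leading eigenvector of the absolute full-correlation graph over in-mask
#' voxels. Zero-variance voxels receive EC 0. The map is nonnegative with
#' unit Euclidean norm.
#'
#' @param run `bold_run`.
#' @param mask `brain_mask`.
#' @param config `ecm_config`.
#' @return object of class `ec_map`: `values` (length = in-mask voxels),
#'   `lambda`, `n_iter`, `flagged`, plus run metadata.
#' @export
compute_ec_map <- function(run, mask, config = ecm_config()) {
  X <- preprocess_timeseries(run, mask, config)
  keep <- attr(X, "voxel_index"); flagged <- attr(X, "flagged")
  V <- ncol(X); Tn <- nrow(X)
  if (V <= config$cache_voxels) {
    A <- abs(crossprod(X) / (Tn - 1))
    if (!config$keep_diagonal) diag(A) <- 0
    matvec <- function(v) as.numeric(A %*% v)
  } else {
    matvec <- function(v) abs_corr_matvec(X, v, config$block_rows,
                                          config$keep_diagonal)
  }
  check_irreducible(matvec, V, config$keep_diagonal)
  pw <- power_iteration(matvec, V, config)
  values <- numeric(length(mask$idx))
  values[keep] <- pw$vector
  structure(list(values = values, lambda = pw$lambda, n_iter = pw$n_iter,
                 flagged = flagged, mask = mask,
                 subject_id = run$subject_id %||% NA_character_,
                 condition = run$condition %||% NA_character_),
            class = "ec_map")
}

#' @export
print.ec_map <- function(x, ...) {
  cat(sprintf("<ec_map> %s/%s: %d voxels, lambda %.2f, %d iterations, %d flagged\n",
              x$subject_id, x$condition, length(x$values), x$lambda,
              x$n_iter, length(x$flagged)))
  invisible(x)
}

#' @export
summary.ec_map <- function(object, ...) {
  v <- object$values[object$values > 0]
  cat(sprintf("EC map (%s, %s)\n", object$subject_id, object$condition))
  cat(sprintf("  voxels: %d (%d flagged zero-variance)\n",
              length(object$values), length(object$flagged)))
  cat(sprintf("  leading eigenvalue: %.3f after %d iterations\n",
              object$lambda, object$n_iter))
  cat(sprintf("  EC range: [%.4g, %.4g], norm %.6f\n",
              min(v), max(v), sqrt(sum(object$values^2))))
  invisible(object)
}
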