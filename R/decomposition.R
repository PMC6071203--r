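#' Stack EC maps into a runs x voxels matrix
#'
#' Each EC map becomes one row, z-scored across voxels; each voxel column is
#' then demeaned across runs, the usual normalization before group spatial
#' ICA. Row metadata (subject, condition) is preserved.
#'
#' @param ec_maps list of `ec_map` objects sharing one mask.
#' @param mask `brain_mask`; must match the maps' mask.
#' @return object of class `ec_matrix`: `X` (runs x voxels), `meta`
#'   (data.frame `subject_id`, `condition`), `mask`.
#' @export
stack_ec_maps <- function(ec_maps, mask) {
  if (length(ec_maps) == 0L)
    stop_hubcent("no EC maps supplied", class = "hubcent_data_error")
  for (m in ec_maps) {
    if (!identical(m$mask$idx, mask$idx))
      stop_hubcent("EC map for %s/%s is on a different mask",
                   m$subject_id, m$condition, class = "hubcent_mask_error")
  }
  X <- t(vapply(ec_maps, function(m) m$values, numeric(length(mask$idx))))
  X <- t(scale(t(X)))                      # row z-score across voxels
  X <- scale(X, center = TRUE, scale = FALSE)  # column demean across runs
  meta <- data.frame(
    subject_id = vapply(ec_maps, function(m) m$subject_id, character(1)),
    condition = vapply(ec_maps, function(m) m$condition, character(1)),
    stringsAsFactors = FALSE)
  structure(list(X = unclass(X), meta = meta, mask = mask),
            class = "ec_matrix")
}

#' Spatial ICA of stacked EC maps
#'
#' PCA-whitens the rows to `K` dimensions and runs symmetric fixed-point ICA
#' with the logcosh contrast to estimate `K` spatially independent source
#' maps over voxels, together with per-run mixing weights. Deterministic
#' given the seed.
#'
#' @param ecmat `ec_matrix` from [stack_ec_maps()], or a plain runs x voxels
#'   matrix.
#' @param K number of components; must not exceed the number of rows.
#' @param seed RNG seed for the initial unmixing rotation.
#' @param max_iter,tol fixed-point iteration cap and convergence tolerance
#'   (on the change of the unmixing rotation).
#' @return object of class `ec_decomposition`: `spatial_maps` (K x V, unit
#'   variance rows), `weights` (runs x K mixing coefficients), `retained`
#'   flags, `pca_explained_variance`, `row_center`, `meta`, `mask`.
#' @export
fit_spatial_ica <- function(ecmat, K, seed = 1L, max_iter = 500L, tol = 1e-9) {
  X <- if (inherits(ecmat, "ec_matrix")) ecmat$X else as.matrix(ecmat)
  meta <- if (inherits(ecmat, "ec_matrix")) ecmat$meta else NULL
  mask <- if (inherits(ecmat, "ec_matrix")) ecmat$mask else NULL
  n <- nrow(X); V <- ncol(X)
  if (K > n || K > V)
    stop_hubcent("K = %d exceeds data dimensions (%d runs, %d voxels)",
                 K, n, V, class = "hubcent_dim_error")
  row_center <- rowMeans(X)
  Xc <- X - row_center
  sv <- svd(Xc, nu = K, nv = 0)
  if (sv$d[K] < 1e-12 * sv$d[1])
    stop_hubcent("data rank below K = %d", K, class = "hubcent_dim_error")
  # whitened spatial signals: K rows, unit variance over voxels
  Z <- sqrt(V) * diag(1 / sv$d[1:K], K) %*% t(sv$u) %*% Xc
  if (K == 1L) {
    W <- matrix(1, 1, 1)
  } else {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    W0 <- matrix(rnorm(K * K), K, K)
    W <- sym_decorrelate(W0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      WZ <- W %*% Z
      G <- tanh(WZ)
      W1 <- G %*% t(Z) / V - diag(rowMeans(1 - G^2), K) %*% W
      W1 <- sym_decorrelate(W1)
      delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
      W <- W1
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
      stop_hubcent("fixed-point ICA did not converge in %d iterations (last change %.3g)",
                   max_iter, delta, class = "hubcent_convergence_error")
  }
  S <- W %*% Z                                   # K x V sources
  A <- Xc %*% t(S) %*% solve(S %*% t(S))         # runs x K mixing
  ev <- sv$d^2 / sum(svd(Xc, nu = 0, nv = 0)$d^2)
  structure(list(spatial_maps = S, weights = A, K = K,
                 retained = rep(TRUE, K),
                 pca_explained_variance = ev[1:K],
                 row_center = row_center, meta = meta, mask = mask,
                 seed = seed),
            class = "ec_decomposition")
}

sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(e$values), nrow(W)) %*% t(e$vectors) %*% W
}

#' Reconstruct the stacked matrix from a decomposition
#' @param dec `ec_decomposition`.
#' @return runs x voxels matrix `row_center + weights %*% spatial_maps`.
#' @export
reconstruct <- function(dec) {
  dec$row_center + dec$weights %*% dec$spatial_maps
}

#' @export
print.ec_decomposition <- function(x, ...) {
  cat(sprintf("<ec_decomposition> %d components over %d runs x %d voxels (%d retained)\n",
              x$K, nrow(x$weights), ncol(x$spatial_maps), sum(x$retained)))
  invisible(x)
}

#' @export
summary.ec_decomposition <- function(object, ...) {
  print(object)
  cat(sprintf("  PCA explained variance (first %d dims): %s\n", object$K,
              paste(sprintf("%.3f", object$pca_explained_variance),
                    collapse = " ")))
  if (!all(object$retained))
    cat(sprintf("  excluded as artifact: %s\n",
                paste(which(!object$retained), collapse = ", ")))
  invisible(object)
}

#' Canonicalize component signs and order
#'
#' ICA leaves each (map, weight-column) pair defined up to sign. Components
#' are flipped so their spatial maps have positive skewness (tie broken by
#' the sign of the largest-|value| voxel), weights flipped in compensation,
#' and components are reordered by descending explained variance. The
#' reconstruction is unchanged.
#'
#' @param dec `ec_decomposition`.
#' @return canonicalized `ec_decomposition`.
#' @export
canonicalize_components <- function(dec) {
  S <- dec$spatial_maps; A <- dec$weights
  for (k in seq_len(dec$K)) {
    s <- S[k, ]
    sk <- mean((s - mean(s))^3)
    flip <- if (sk != 0) sk < 0 else s[which.max(abs(s))] < 0
    if (flip) { S[k, ] <- -s; A[, k] <- -A[, k] }
  }
  contrib <- colSums(A^2) * rowSums(S^2)
  ord <- order(contrib, decreasing = TRUE)
  dec$spatial_maps <- S[ord, , drop = FALSE]
  dec$weights <- A[, ord, drop = FALSE]
  dec$retained <- dec$retained[ord]
  dec
}

#' Flag artifact components by reference-map matching
#'
#' The anatomical exclusion of white-matter/CSF components is emulated for
#' synthetic data by spatial matching: a component is retained iff its best
#' absolute spatial correlation against the signal reference maps exceeds its
#' best against the artifact references.
#'
#' @param dec `ec_decomposition`.
#' @param signal_maps matrix (n_signal x V) of signal reference maps, e.g.
#'   the planted atlas networks restricted to the mask.
#' @param artifact_maps matrix (n_artifact x V) of artifact reference maps.
#' @return the decomposition with updated `retained` flags. With no
#'   references, all components are retained with a warning.
#' @export
classify_artifact_components <- function(dec, signal_maps = NULL,
                                         artifact_maps = NULL) {
  if (is.null(signal_maps) || is.null(artifact_maps)) {
    warn_hubcent("no reference maps supplied; all components retained")
    dec$retained <- rep(TRUE, dec$K)
    return(dec)
  }
  signal_maps <- as.matrix(signal_maps)
  artifact_maps <- as.matrix(artifact_maps)
  cs <- abs(cor(t(dec$spatial_maps), t(signal_maps)))
  ca <- abs(cor(t(dec$spatial_maps), t(artifact_maps)))
  dec$retained <- apply(cs, 1, max) > apply(ca, 1, max)
  dec
}

#' Hierarchical clustering of components by weight correlation
#'
#' Computes the Pearson correlation of subject-weight columns across all runs
#' (rest and task) for the retained components and clusters them
#' agglomeratively with distance 1 - r and average linkage, mirroring the
#' standard netmat-style summary of component relationships.
#'
#' @param dec `ec_decomposition` with >= 2 retained components.
#' @param cut_k number of flat clusters to return.
#' @return list with `hclust` (merge tree), `labels` (flat cluster labels
#'   named by component index), `correlation` (weight correlation matrix).
#' @export
component_weight_clustering <- function(dec, cut_k = 2L) {
  keep <- which(dec$retained)
  if (length(keep) < 2L)
    stop_hubcent("need >= 2 retained components to cluster",
                 class = "hubcent_data_error")
  W <- dec$weights[, keep, drop = FALSE]
  wsd <- apply(W, 2, sd)
  if (any(wsd == 0))
    stop_hubcent("component(s) %s have zero weight variance",
                 paste(keep[wsd == 0], collapse = ", "),
                 class = "hubcent_data_error")
  C <- cor(W)
  dimnames(C) <- list(keep, keep)
  h <- hclust(stats::as.dist(1 - C), method = "average")
  labels <- stats::cutree(h, k = min(cut_k, length(keep)))
  names(labels) <- keep
  list(hclust = h, labels = labels, correlation = C)
}
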