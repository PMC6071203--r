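#' @useDynLib hubcent, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef convolve cor cov dgamma dist dt hclust lm median
#'   pnorm pt qnorm quantile rbinom rnorm runif sd setNames var
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_hubcent <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "hubcent_error")))
}

warn_hubcent <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' One-to-one maximum-|correlation| component matching
#'
#' Solves the linear assignment problem that pairs each estimated component
#' with one reference component so that the summed absolute spatial
#' correlation is maximal (Hungarian algorithm, shortest augmenting paths).
#' Used throughout the validation tests to resolve ICA permutation ambiguity.
#'
#' @param cost numeric matrix; `cost[i, j]` is the cost of assigning row
#'   item `i` to column item `j`. Must have `nrow <= ncol`.
#' @return integer vector `a` of length `nrow(cost)`, `a[i]` the column
#'   assigned to row `i`, minimizing `sum(cost[cbind(seq_len(n), a)])`.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) stop_hubcent("assignment needs nrow <= ncol", class = "hubcent_dim_error")
  INF <- .Machine$double.xmax / 4
  # potentials over rows (u) and columns (v); way[j] = predecessor column
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1)  # p[j] = row matched to column j (0 = none)
  for (i in seq_len(n)) {
    p[m + 1] <- i
    j0 <- m + 1
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    way <- integer(m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0
      for (j in seq_len(m)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(m + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0) ans[p[j]] <- j
  ans
}

#' Match estimated components to reference components
#'
#' Pairs columns (or rows) of two map sets by maximum absolute Pearson
#' correlation under a one-to-one constraint.
#'
#' @param est,ref matrices with components in rows and voxels in columns;
#'   `nrow(est) <= nrow(ref)` is not required — the smaller set is matched
#'   into the larger.
#' @return data.frame with columns `est`, `ref`, `abs_cor`, `cor`.
#' @export
match_components <- function(est, ref) {
  est <- as.matrix(est); ref <- as.matrix(ref)
  cc <- cor(t(est), t(ref))           # n_est x n_ref
  swapped <- FALSE
  if (nrow(cc) > ncol(cc)) { cc <- t(cc); swapped <- TRUE }
  a <- solve_assignment(-abs(cc))
  idx <- cbind(seq_len(nrow(cc)), a)
  out <- data.frame(est = idx[, 1], ref = idx[, 2],
                    abs_cor = abs(cc[idx]), cor = cc[idx])
  if (swapped) names(out)[1:2] <- c("ref", "est")
  out[, c("est", "ref", "abs_cor", "cor")]
}

# FNV-1a 64-bit-ish hash over serialized object, returned as hex string.
# Used for provenance manifests only (not cryptographic).
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  # skip serialization header (R version stamp) so hashes are stable
  bytes <- bytes[-seq_len(14)]
  h1 <- 216613626; h2 <- 40389
  for (b in bytes) {
    h1 <- (bitwXor(h1 %% 2^30, b) * 16777619) %% 2^30
    h2 <- (h2 * 31 + b) %% 2^30
  }
  sprintf("%08x%08x", h1, h2)
}
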