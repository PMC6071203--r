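# shared fixture builders -----------------------------------------------------

# wrap a T x V matrix as a bold_run on a flat V x 1 x 1 grid
run_from_matrix <- function(X, tr = 3, subject_id = "sim", condition = "rest") {
  V <- ncol(X)
  structure(list(data = array(t(X), dim = c(V, 1L, 1L, nrow(X))),
                 tr_seconds = tr, subject_id = subject_id,
                 condition = condition),
            class = "bold_run")
}

flat_mask <- function(V) as_brain_mask(array(TRUE, c(V, 1L, 1L)))

# small cohort config used across tests; overrides via ...
test_cohort_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 6, grid_dims = c(14L, 14L, 8L), k_networks = 3L,
         k_artifacts = 1L, n_timepoints_rest = 60L, n_timepoints_task = 124L,
         seed = 1),
    list(...))
  do.call(cohort_config, args)
}

# dense-oracle EC: explicit |corr| eigendecomposition on standardized data
dense_ec_oracle <- function(X) {
  A <- abs(cor(X))
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, 1]
  v <- v * sign(sum(v))
  list(vector = v, lambda = e$values[1])
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
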