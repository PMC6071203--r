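#' Double-gamma hemodynamic response function
#'
#' Canonical double-gamma HRF: a gamma density peaking near 6 s minus a
#' later undershoot gamma (peak near 16 s) at 1/6 amplitude, scaled to unit
#' peak.
#'
#' @param t time in seconds (vector).
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t) {
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h / max(dgamma(seq(0, 32, by = 0.01), shape = 6, rate = 1))
}

#' HRF-convolved block regressor
#'
#' Builds a boxcar from onset/duration pairs on a fine time grid, convolves
#' it with the double-gamma HRF, and samples the result at volume acquisition
#' times `(i - 1) * tr`.
#'
#' @param onsets,durations vectors of event onsets and durations (seconds).
#' @param n_timepoints number of volumes.
#' @param tr repetition time (seconds).
#' @param dt fine-grid resolution for the convolution (seconds).
#' @return numeric vector of length `n_timepoints`.
#' @export
hrf_regressor <- function(onsets, durations, n_timepoints, tr, dt = 0.1) {
  run_sec <- n_timepoints * tr
  if (length(onsets) == 0L) return(numeric(n_timepoints))
  if (any(onsets < 0) || any(onsets + durations > run_sec))
    stop_hubcent("event at %.1fs extends beyond run end (%.1fs)",
                 max(onsets + durations), run_sec,
                 class = "hubcent_design_error")
  tgrid <- seq(0, run_sec + 32, by = dt)
  box <- numeric(length(tgrid))
  for (i in seq_along(onsets)) {
    on <- onsets[i]; off <- onsets[i] + durations[i]
    box[tgrid >= on & tgrid < off] <- 1
  }
  h <- hrf_double_gamma(seq(0, 32, by = dt)) * dt
  h <- h / sum(h)    # sustained-block response plateaus at 1
  y <- numeric(length(tgrid))
  for (i in seq_along(h)) {
    n <- length(tgrid) - i + 1L
    if (n > 0) y[i:length(tgrid)] <- y[i:length(tgrid)] + h[i] * box[1:n]
  }
  y[round((seq_len(n_timepoints) - 1L) * tr / dt) + 1L]
}

#' Build the n-back GLM design matrix
#'
#' HRF-convolved indicator columns for the 0-, 1-, and 2-back blocks plus
#' instruction periods and response events as nuisance regressors, and an
#' intercept. Regressors with no events are dropped with a warning.
#'
#' @param design `task_design`.
#' @param n_timepoints number of volumes.
#' @param tr_seconds repetition time.
#' @return matrix of class `design_matrix` with named columns; attribute
#'   `condition_cols` names the three load-level columns.
#' @export
build_design_matrix <- function(design, n_timepoints, tr_seconds) {
  cols <- list()
  for (key in c("0back", "1back", "2back")) {
    ons <- design$onsets[[key]]
    cols[[key]] <- hrf_regressor(ons, rep(design$block_seconds, length(ons)),
                                 n_timepoints, tr_seconds)
  }
  cols[["instructions"]] <- hrf_regressor(
    design$instruction_onsets,
    rep(design$instruction_seconds, length(design$instruction_onsets)),
    n_timepoints, tr_seconds)
  cols[["responses"]] <- hrf_regressor(
    design$response_onsets,
    rep(design$response_seconds, length(design$response_onsets)),
    n_timepoints, tr_seconds)
  empty <- vapply(cols, function(x) all(x == 0), logical(1))
  if (any(empty)) {
    warn_hubcent("empty regressor(s) dropped from design: %s",
                 paste(names(cols)[empty], collapse = ", "))
    cols <- cols[!empty]
  }
  X <- cbind(do.call(cbind, cols), intercept = 1)
  colnames(X) <- c(names(cols), "intercept")
  if (qr(X)$rank < ncol(X))
    stop_hubcent("design matrix is rank deficient",
                 class = "hubcent_design_error")
  structure(X, class = c("design_matrix", "matrix"),
            condition_cols = intersect(c("0back", "1back", "2back"),
                                       colnames(X)))
}

#' Component time series by spatial regression (dual regression, stage 1)
#'
#' Regresses each spatially demeaned volume on all retained, spatially
#' demeaned component maps simultaneously; the per-volume coefficients form
#' one time series per component. Demeaning makes the series invariant to a
#' constant spatial offset in the data.
#'
#' @param run `bold_run`.
#' @param spatial_maps K x V matrix of component maps on the mask (retained
#'   components only).
#' @param mask `brain_mask`.
#' @return T x K matrix of component time series.
#' @export
dual_regression_timeseries <- function(run, spatial_maps, mask) {
  spatial_maps <- as.matrix(spatial_maps)
  d <- dim(run$data)
  if (!identical(d[1:3], as.integer(mask$dims)))
    stop_hubcent("run grid does not match mask", class = "hubcent_grid_error")
  if (ncol(spatial_maps) != length(mask$idx))
    stop_hubcent("maps have %d voxels, mask has %d", ncol(spatial_maps),
                 length(mask$idx), class = "hubcent_dim_error")
  M <- t(spatial_maps)                         # V x K
  M <- sweep(M, 2, colMeans(M))
  qrM <- qr(M)
  if (qrM$rank < ncol(M))
    stop_hubcent("component maps are collinear after demeaning (rank %d < %d)",
                 qrM$rank, ncol(M), class = "hubcent_dim_error")
  Y <- matrix(run$data, prod(d[1:3]), d[4])[mask$idx, , drop = FALSE]  # V x T
  Y <- sweep(Y, 2, colMeans(Y))                # demean each volume
  t(qr.coef(qrM, Y))                           # T x K
}

#' Ordinary least-squares GLM for one component time series
#'
#' @param series numeric vector (length T).
#' @param dm `design_matrix` with T rows.
#' @return list of class `component_betas`: named `betas`, `sigma2`
#'   (residual variance), `df` (T - P), `se` per coefficient.
#' @export
fit_component_glm <- function(series, dm) {
  X <- unclass(dm)
  if (length(series) != nrow(X))
    stop_hubcent("series length %d does not match design rows %d",
                 length(series), nrow(X), class = "hubcent_dim_error")
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop_hubcent("singular design matrix", class = "hubcent_design_error")
  beta <- qr.coef(qrX, series)
  res <- series - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  structure(list(betas = setNames(as.numeric(beta), colnames(X)),
                 sigma2 = sigma2, df = df,
                 se = sqrt(sigma2 * diag(XtXinv))),
            class = "component_betas")
}

#' n-back activation contrast
#'
#' The working-memory engagement contrast: mean of the 1-back and 2-back
#' betas minus the 0-back beta.
#'
#' @param betas `component_betas` (or any list with a named `betas` vector).
#' @return scalar contrast value.
#' @export
activation_contrast <- function(betas) {
  b <- if (is.list(betas)) betas$betas else betas
  need <- c("0back", "1back", "2back")
  if (!all(need %in% names(b)))
    stop_hubcent("betas missing condition column(s): %s",
                 paste(setdiff(need, names(b)), collapse = ", "),
                 class = "hubcent_data_error")
  (b[["1back"]] + b[["2back"]]) / 2 - b[["0back"]]
}

#' Signal-detection behaviour scores
#'
#' Hit rate, false-alarm rate, and d-prime
#' (`qnorm(hit_rate) - qnorm(fp_rate)`). Rates are clamped to
#' `[1/(2n), 1 - 1/(2n)]` of their respective trial counts before the
#' z-transform so perfect scores give finite d-prime.
#'
#' @param hits,false_alarms counts (vectors allowed).
#' @param n_targets,n_nontargets trial counts.
#' @return data.frame with `hit_rate`, `fp_rate`, `dprime`.
#' @export
behavior_scores <- function(hits, false_alarms, n_targets, n_nontargets) {
  if (any(hits < 0) || any(hits > n_targets) ||
      any(false_alarms < 0) || any(false_alarms > n_nontargets))
    stop_hubcent("counts exceed trial counts", class = "hubcent_data_error")
  hr <- clamp(hits / n_targets, 1 / (2 * n_targets), 1 - 1 / (2 * n_targets))
  fr <- clamp(false_alarms / n_nontargets, 1 / (2 * n_nontargets),
              1 - 1 / (2 * n_nontargets))
  data.frame(hit_rate = hr, fp_rate = fr, dprime = qnorm(hr) - qnorm(fr))
}
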