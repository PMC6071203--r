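#' Synthetic cohort configuration
#'
#' Parameters of the synthetic multi-subject, two-condition (rest / n-back)
#' fMRI cohort. The generator plants a known network structure: smooth
#' nonnegative spatial maps whose time courses follow a hub-centred star
#' covariance, with each partner network's coupling to the hub modulated by
#' condition, age, and a subject-level engagement trait that also drives
#' in-scanner behaviour.
#'
#' @param n_subjects number of subjects (two runs each).
#' @param grid_dims integer vector of 3 voxel extents.
#' @param tr_seconds sampling interval in seconds.
#' @param n_timepoints_rest,n_timepoints_task volumes per run.
#' @param k_networks number of planted signal networks. Network 1 is the
#'   task-positive hub, network `k_networks` the task-negative sensory
#'   network, the rest background.
#' @param k_artifacts number of planted artifact sources (structured noise
#'   with run-varying amplitude and no cross-network coupling).
#' @param noise_sd i.i.d. Gaussian voxel noise standard deviation.
#' @param task_coupling_delta per-network change under task: entry 1 is the
#'   increase of the hub time-course amplitude (also subtracted from the
#'   task-negative sensory network's amplitude), entries 2..k change each
#'   partner network's coupling to the hub (correlation units). A scalar `x`
#'   expands to hub amplitude `+x`, sensory amplitude `-x`, couplings
#'   unchanged.
#' @param age_slope per-network linear age modulation (per year): entry 1 on
#'   the hub amplitude, entries 2..k on partner couplings. A scalar applies
#'   to all, so the hub's overall cross-network covariance grows with age in
#'   both conditions.
#' @param behavior_link coefficient tying the hub-coupling trait to the
#'   hit-rate logit.
#' @param behavior_intercept,behavior_age_slope intercept and per-year age
#'   term of the hit-rate logit (age centred at the range midpoint).
#' @param fa_intercept intercept of the false-alarm logit.
#' @param hub_coupling_sd standard deviation of the subject-level hub
#'   engagement trait, added to the hub amplitude in task runs only.
#' @param rho_base baseline coupling of every partner network to the hub
#'   process (correlation units; the covariance is a hub-centred star:
#'   `corr(hub, k) = a_k`, `corr(j, k) = a_j a_k`).
#' @param hub_amp_base baseline hub time-course amplitude (SD multiplier) at
#'   rest for a mid-range-age subject; task engagement, age and the subject
#'   trait add to it.
#' @param task_amplitude scale of the HRF-convolved activation added to task
#'   network time courses (units of time-course SD).
#' @param age_range_years length-2 ascending age range.
#' @param seed RNG seed for the whole cohort.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 40,
                          grid_dims = c(20L, 20L, 12L),
                          tr_seconds = 3.0,
                          n_timepoints_rest = 120L,
                          n_timepoints_task = 124L,
                          k_networks = 6L,
                          k_artifacts = 2L,
                          noise_sd = 0.5,
                          task_coupling_delta = 0.3,
                          age_slope = 0.03,
                          behavior_link = 2.5,
                          behavior_intercept = 0.8,
                          behavior_age_slope = 0.06,
                          fa_intercept = -2,
                          hub_coupling_sd = 0.3,
                          rho_base = 0.30,
                          hub_amp_base = 0.55,
                          task_amplitude = 0.5,
                          age_range_years = c(8, 22),
                          seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              grid_dims = as.integer(grid_dims),
              tr_seconds = tr_seconds,
              n_timepoints_rest = as.integer(n_timepoints_rest),
              n_timepoints_task = as.integer(n_timepoints_task),
              k_networks = as.integer(k_networks),
              k_artifacts = as.integer(k_artifacts),
              noise_sd = noise_sd,
              task_coupling_delta = task_coupling_delta,
              age_slope = age_slope,
              behavior_link = behavior_link,
              behavior_intercept = behavior_intercept,
              behavior_age_slope = behavior_age_slope,
              fa_intercept = fa_intercept,
              hub_coupling_sd = hub_coupling_sd,
              rho_base = rho_base,
              hub_amp_base = hub_amp_base,
              task_amplitude = task_amplitude,
              age_range_years = as.numeric(age_range_years),
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (n_subjects < 1L || k_networks < 1L || k_artifacts < 0L ||
        n_timepoints_rest < 1L || n_timepoints_task < 1L)
      stop_hubcent("all counts must be >= 1", class = "hubcent_config_error")
    if (length(grid_dims) != 3L || any(grid_dims < 1L))
      stop_hubcent("grid_dims must be 3 positive extents", class = "hubcent_config_error")
    if (noise_sd <= 0)
      stop_hubcent("noise_sd must be > 0", class = "hubcent_config_error")
    if (diff(age_range_years) <= 0)
      stop_hubcent("age_range_years must be ascending", class = "hubcent_config_error")
    if (prod(grid_dims) < 8L * k_networks)
      stop_hubcent("grid volume %d too small for %d networks (need >= 8 voxels each)",
                   prod(grid_dims), k_networks, class = "hubcent_sizing_error")
  })
  invisible(cfg)
}

# expand scalar per-network parameters over the star structure;
# entry 1 is the hub (amplitude modulation), entry k the sensory network
# (amplitude drop under task), background networks between.
# scalar task delta x: hub amplitude +x, sensory amplitude -x, background 0;
# scalar age slope x: hub amplitude and every partner coupling grow by x/year.
expand_network_param <- function(x, k, all_networks = FALSE) {
  if (length(x) == k) return(as.numeric(x))
  if (length(x) != 1L)
    stop_hubcent("per-network parameter must have length 1 or %d", k,
                 class = "hubcent_config_error")
  out <- numeric(k)
  if (all_networks) out[] <- x
  else out[1L] <- x
  out
}

network_labels <- function(k_networks, k_artifacts) {
  lab <- rep("background", k_networks)
  lab[1L] <- "hub"
  if (k_networks > 1L) lab[k_networks] <- "sensory"
  c(lab, rep("artifact", k_artifacts))
}

#' Ellipsoidal analysis mask
#'
#' @param grid_dims integer vector of 3 voxel extents.
#' @return object of class `brain_mask`: logical 3D array plus the ordered
#'   index of in-mask voxels.
#' @export
ellipsoid_mask <- function(grid_dims) {
  d <- as.integer(grid_dims)
  ctr <- (d + 1) / 2
  semi <- d / 2 - 0.5
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  inside <- ((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
    ((g$z - ctr[3]) / semi[3])^2 <= 1
  arr <- array(inside, dim = d)
  as_brain_mask(arr)
}

#' Construct a mask object from a logical 3D array
#' @param arr logical (or 0/1) 3D array.
#' @return `brain_mask` object.
#' @export
as_brain_mask <- function(arr) {
  arr <- array(as.logical(arr), dim = dim(arr))
  if (length(dim(arr)) != 3L)
    stop_hubcent("mask must be 3-D", class = "hubcent_mask_error")
  idx <- which(arr)
  if (length(idx) < 2L)
    stop_hubcent("mask must contain >= 2 voxels", class = "hubcent_mask_error")
  structure(list(array = arr, idx = idx, dims = dim(arr)),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %s grid, %d in-mask voxels\n",
              paste(x$dims, collapse = "x"), length(x$idx)))
  invisible(x)
}

#' Generate planted network spatial maps
#'
#' Places `k` Gaussian blobs at mutually distant centres inside the mask and
#' returns unit-peak smooth nonnegative maps. Pairwise spatial correlations
#' stay below 0.5 by enforcing a minimum centre distance relative to the blob
#' width.
#'
#' @param grid_dims integer vector of 3 voxel extents.
#' @param k number of maps.
#' @param seed RNG seed; the result is deterministic given the seed.
#' @param sigma blob standard deviation in voxels.
#' @param mask optional `brain_mask`; defaults to [ellipsoid_mask()].
#' @return object of class `network_atlas`: 4-D array of maps
#'   (x, y, z, component), labels, centres, and the mask.
#' @export
generate_network_maps <- function(grid_dims, k, seed = 1L, sigma = 1.8,
                                  mask = NULL) {
  mask <- mask %||% ellipsoid_mask(grid_dims)
  d <- as.integer(grid_dims)
  # two Gaussian blobs at distance d have spatial correlation ~exp(-d^2/4s^2);
  # 3.2 sigma keeps pairwise map correlations well below the 0.5 bound
  min_dist <- 3.2 * sigma
  coords <- which(mask$array, arr.ind = TRUE)
  # keep centres away from the mask boundary so blobs are not truncated
  interior <- coords
  for (ax in 1:3) {
    interior <- interior[interior[, ax] > 2 & interior[, ax] < d[ax] - 1, ,
                         drop = FALSE]
  }
  if (nrow(interior) < k)
    stop_hubcent("grid %s too small for %d network centres",
                 paste(d, collapse = "x"), k, class = "hubcent_sizing_error")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # greedy farthest-point placement; retry from fresh random starts if a
  # start position leaves too little room for the remaining centres
  centers <- NULL
  for (attempt in seq_len(20L)) {
    cand <- matrix(NA_real_, k, 3)
    cand[1, ] <- interior[sample.int(nrow(interior), 1L), ]
    ok <- TRUE
    if (k > 1L) {
      dmin <- sqrt(rowSums(sweep(interior, 2, cand[1, ])^2))
      for (i in 2:k) {
        j <- which.max(dmin)
        if (dmin[j] < min_dist) { ok <- FALSE; break }
        cand[i, ] <- interior[j, ]
        dmin <- pmin(dmin, sqrt(rowSums(sweep(interior, 2, cand[i, ])^2)))
      }
    }
    if (ok) { centers <- cand; break }
  }
  if (is.null(centers))
    stop_hubcent("cannot place %d centres at spacing %.1f in grid %s",
                 k, min_dist, paste(d, collapse = "x"),
                 class = "hubcent_sizing_error")
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  maps <- array(0, dim = c(d, k))
  for (i in seq_len(k)) {
    r2 <- (g$x - centers[i, 1])^2 + (g$y - centers[i, 2])^2 +
      (g$z - centers[i, 3])^2
    m <- exp(-r2 / (2 * sigma^2))
    m[!mask$array] <- 0
    m <- m / max(m)
    if (sum(m >= 0.5) < 8L)
      stop_hubcent("network %d has < 8 supra-half-maximum voxels", i,
                   class = "hubcent_sizing_error")
    maps[, , , i] <- m
  }
  structure(list(maps = maps, centers = centers, sigma = sigma,
                 labels = rep("network", k), mask = mask),
            class = "network_atlas")
}

# save/restore .Random.seed so seeded helpers do not disturb the caller's RNG
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

atlas_matrix <- function(atlas) {
  # k x V matrix of maps restricted to the mask
  k <- dim(atlas$maps)[4]
  t(sapply(seq_len(k), function(i) atlas$maps[, , , i][atlas$mask$idx]))
}

#' n-back block design
#'
#' Three blocks per load level (0-, 1-, 2-back), each preceded by an
#' instruction period; each block holds 20 trials of which 5 are targets.
#' Blocks alternate 0/1/2-back. Response events are placed at target trials.
#'
#' @param blocks_per_condition blocks per load level.
#' @param trials_per_block trials per block.
#' @param targets_per_block target trials per block.
#' @param block_seconds block duration (s).
#' @param instruction_seconds instruction period before each block (s).
#' @return object of class `task_design` with onset/duration lists (seconds).
#' @export
make_task_design <- function(blocks_per_condition = 3L,
                             trials_per_block = 20L,
                             targets_per_block = 5L,
                             block_seconds = 30,
                             instruction_seconds = 10) {
  n_blocks <- 3L * blocks_per_condition
  cycle <- instruction_seconds + block_seconds
  cond_order <- rep(0:2, blocks_per_condition)
  trial_sec <- block_seconds / trials_per_block
  # deterministic target positions, spread through the block
  target_trials <- round(seq(3, trials_per_block - 1,
                             length.out = targets_per_block))
  onsets <- list(`0back` = numeric(0), `1back` = numeric(0),
                 `2back` = numeric(0))
  instr_onsets <- numeric(0); resp_onsets <- numeric(0)
  for (b in seq_len(n_blocks)) {
    t0 <- (b - 1) * cycle
    instr_onsets <- c(instr_onsets, t0)
    bl0 <- t0 + instruction_seconds
    key <- sprintf("%dback", cond_order[b])
    onsets[[key]] <- c(onsets[[key]], bl0)
    resp_onsets <- c(resp_onsets, bl0 + (target_trials - 1) * trial_sec + 0.5)
  }
  structure(list(onsets = onsets,
                 block_seconds = block_seconds,
                 instruction_onsets = instr_onsets,
                 instruction_seconds = instruction_seconds,
                 response_onsets = resp_onsets,
                 response_seconds = 0.5,
                 blocks_per_condition = as.integer(blocks_per_condition),
                 trials_per_block = as.integer(trials_per_block),
                 targets_per_block = as.integer(targets_per_block),
                 total_seconds = n_blocks * cycle),
            class = "task_design")
}

# hub-centred star covariance: partner network k's unit-variance process
# couples to the (unit-variance) hub process with correlation a_k, so
# corr(s_1, s_k) = a_k and corr(s_j, s_k) = a_j a_k — always PSD. Each
# network's time course is then scaled by an amplitude multiplier: the hub's
# amplitude carries the task, age, and subject-trait engagement effects (it
# drives both within-network coherence relative to voxel noise and the
# voxel-level cross-network correlations), and the task-negative sensory
# network's amplitude drops under task by the same planted delta.
network_couplings <- function(subject, condition, config) {
  k <- config$k_networks
  delta <- expand_network_param(config$task_coupling_delta, k)
  aslope <- expand_network_param(config$age_slope, k, all_networks = TRUE)
  mid <- mean(config$age_range_years)
  a <- rep(config$rho_base, k)
  a[-1] <- a[-1] + aslope[-1] * (subject$age_years - mid)
  if (condition == "task" && k > 1L) a[-1] <- a[-1] + delta[-1]
  a <- clamp(a, 0.01, 0.85)
  a[1] <- 1
  amp <- rep(1, k)
  amp[1] <- config$hub_amp_base + delta[1] * (condition == "task") +
    aslope[1] * (subject$age_years - mid) +
    subject$hub_coupling * (condition == "task")
  if (k > 1L && condition == "task") amp[k] <- amp[k] - delta[1]
  amp <- pmax(amp, 0.2)
  list(coupling = a, amplitude = amp)
}

#' Simulate one 4-D BOLD run
#'
#' Voxel series are a mixture of planted network time courses through the
#' atlas maps plus i.i.d. Gaussian noise. Partner network time courses couple
#' directly to the hub time course (star covariance), with couplings set by
#' condition, age, and the subject's engagement trait. Task runs add HRF-convolved block
#' regressors with positive amplitude on the hub and negative amplitude on
#' the sensory network, weighted by memory load.
#'
#' @param subject one-row data.frame (or list) with `id`, `age_years`, `sex`,
#'   `hub_coupling`.
#' @param condition `"rest"` or `"task"`.
#' @param atlas `network_atlas` whose 4th dimension is
#'   `k_networks + k_artifacts` (artifact maps last).
#' @param design `task_design`; required iff `condition == "task"`.
#' @param config `cohort_config`.
#' @param seed RNG seed for this run; defaults to a deterministic function of
#'   the config seed, subject id and condition.
#' @return object of class `bold_run` (4-D data array, TR, metadata).
#' @export
simulate_run <- function(subject, condition = c("rest", "task"), atlas,
                         design = NULL, config, seed = NULL) {
  condition <- match.arg(condition)
  if ((condition == "task") != !is.null(design))
    stop_hubcent("design must be supplied iff condition is 'task'",
                 class = "hubcent_config_error")
  sid <- as.character(subject$id %||% subject$subject_id)
  if (is.null(seed))
    seed <- run_seed(config$seed, sid, condition)
  Tn <- if (condition == "task") config$n_timepoints_task else
    config$n_timepoints_rest
  k_sig <- config$k_networks
  k_tot <- dim(atlas$maps)[4]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cpl <- network_couplings(subject, condition, config)
  a <- cpl$coupling; amp <- cpl$amplitude
  S <- matrix(0, Tn, k_tot)
  hub_process <- rnorm(Tn)                 # unit-variance hub process
  S[, 1] <- amp[1] * hub_process           # amplitude-modulated hub
  if (k_sig > 1L) for (j in 2:k_sig)
    S[, j] <- amp[j] * (sqrt(1 - a[j]^2) * rnorm(Tn) + a[j] * hub_process)
  if (k_tot > k_sig) {
    for (j in (k_sig + 1):k_tot)
      S[, j] <- exp(rnorm(1, 0, 0.4)) * rnorm(Tn)
  }
  if (condition == "task") {
    act <- task_activation_profile(design, Tn, config$tr_seconds)
    act_amp <- numeric(k_tot)
    act_amp[1] <- config$task_amplitude
    if (k_sig > 1L) act_amp[k_sig] <- -config$task_amplitude
    S <- S + outer(act, act_amp)
  }
  d <- config$grid_dims
  M <- atlas_matrix(atlas)                       # k_tot x V(mask)
  Y <- array(rnorm(prod(d) * Tn, sd = config$noise_sd), dim = c(d, Tn))
  sig <- S %*% M                                  # Tn x V
  vox <- atlas$mask$idx
  nvox <- prod(d)
  for (t in seq_len(Tn)) Y[vox + (t - 1) * nvox] <- Y[vox + (t - 1) * nvox] + sig[t, ]
  structure(list(data = Y, tr_seconds = config$tr_seconds,
                 subject_id = sid, condition = condition, seed = seed,
                 couplings = a, amplitudes = amp, timecourses = S),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> subject %s, %s, %sx%sx%s grid, %d volumes, TR %.1fs\n",
              x$subject_id, x$condition, d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}

# deterministic small-integer seed per run
run_seed <- function(base_seed, subject_id, condition) {
  sid <- sum(utf8ToInt(as.character(subject_id)) *
               seq_along(utf8ToInt(as.character(subject_id))))
  (base_seed * 2654435 + sid * 97 + (condition == "task") * 31 + 7) %% 2147483647L
}

# load-weighted activation time course: heavier memory load, stronger response
task_activation_profile <- function(design, Tn, tr) {
  w <- c(`0back` = 0.5, `1back` = 1.0, `2back` = 1.5)
  prof <- numeric(Tn)
  for (key in names(w)) {
    ons <- design$onsets[[key]]
    prof <- prof + w[[key]] *
      hrf_regressor(ons, rep(design$block_seconds, length(ons)), Tn, tr)
  }
  prof
}

#' Simulate in-scanner n-back behaviour
#'
#' Hit and false-alarm counts are binomial over the run's 45 targets and 135
#' non-targets (3 load levels x 3 blocks x 5 / 15 trials). The hit-rate logit
#' rises with age and with the subject's hub-coupling trait; the false-alarm
#' logit falls with both.
#'
#' @param subject one-row data.frame or list with `age_years`, `hub_coupling`.
#' @param config `cohort_config`.
#' @param seed optional RNG seed.
#' @return list with `hits`, `false_alarms`, `n_targets`, `n_nontargets`,
#'   `p_hit`, `p_fa`.
#' @export
simulate_behavior <- function(subject, config, seed = NULL) {
  des <- make_task_design()
  n_targets <- 3L * des$blocks_per_condition * des$targets_per_block
  n_nontargets <- 3L * des$blocks_per_condition *
    (des$trials_per_block - des$targets_per_block)
  mid <- mean(config$age_range_years)
  lh <- config$behavior_intercept +
    config$behavior_age_slope * (subject$age_years - mid) +
    config$behavior_link * subject$hub_coupling
  lf <- config$fa_intercept -
    0.5 * config$behavior_age_slope * (subject$age_years - mid) -
    0.5 * config$behavior_link * subject$hub_coupling
  p_hit <- stats::plogis(lh); p_fa <- stats::plogis(lf)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  if (!is.null(seed)) set.seed(seed)
  list(hits = rbinom(1L, n_targets, p_hit),
       false_alarms = rbinom(1L, n_nontargets, p_fa),
       n_targets = n_targets, n_nontargets = n_nontargets,
       p_hit = p_hit, p_fa = p_fa)
}

#' Generate a full synthetic cohort
#'
#' Draws subjects (age uniform over the configured range, sex Bernoulli(0.5),
#' hub-coupling trait Gaussian), plants the network atlas, simulates a rest
#' and a task run per subject plus behaviour, and returns everything with the
#' ground truth needed for recovery tests. Regeneration under the same config
#' is bit-identical.
#'
#' @param config `cohort_config`.
#' @param dir optional output directory; when given, runs and mask are written
#'   as NIfTI-1, the subject table as TSV, and the design as JSON.
#' @return list with `runs` (list of `bold_run`, rest then task per subject),
#'   `subjects` (data.frame `subject_id age sex hits false_alarms`), `mask`,
#'   `design`, `atlas`, and `ground_truth`.
#' @export
generate_cohort <- function(config, dir = NULL) {
  validate_cohort_config(config)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n <- config$n_subjects
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age_years = runif(n, config$age_range_years[1], config$age_range_years[2]),
    sex = rbinom(n, 1L, 0.5),
    hub_coupling = rnorm(n, 0, config$hub_coupling_sd),
    stringsAsFactors = FALSE)
  k_tot <- config$k_networks + config$k_artifacts
  atlas <- generate_network_maps(config$grid_dims, k_tot,
                                 seed = config$seed + 101L)
  atlas$labels <- network_labels(config$k_networks, config$k_artifacts)
  design <- make_task_design()
  if (design$total_seconds > config$n_timepoints_task * config$tr_seconds)
    stop_hubcent("task design (%.0fs) exceeds run duration (%.0fs)",
                 design$total_seconds,
                 config$n_timepoints_task * config$tr_seconds,
                 class = "hubcent_config_error")
  runs <- vector("list", 2L * n)
  dn <- list(subjects$subject_id, NULL, c("rest", "task"))
  couplings <- array(NA_real_, c(n, config$k_networks, 2), dimnames = dn)
  amplitudes <- array(NA_real_, c(n, config$k_networks, 2), dimnames = dn)
  for (i in seq_len(n)) {
    subj <- subjects[i, ]
    rest <- simulate_run(subj, "rest", atlas, NULL, config)
    task <- simulate_run(subj, "task", atlas, design, config)
    couplings[i, , 1] <- rest$couplings
    couplings[i, , 2] <- task$couplings
    amplitudes[i, , 1] <- rest$amplitudes
    amplitudes[i, , 2] <- task$amplitudes
    runs[[2 * i - 1]] <- rest
    runs[[2 * i]] <- task
    beh <- simulate_behavior(subj, config,
                             seed = run_seed(config$seed, subj$subject_id, "beh"))
    subjects$hits[i] <- beh$hits
    subjects$false_alarms[i] <- beh$false_alarms
    subjects$n_targets[i] <- beh$n_targets
    subjects$n_nontargets[i] <- beh$n_nontargets
  }
  k <- config$k_networks
  task_signs <- integer(k); task_signs[1] <- 1L
  if (k > 1L) task_signs[k] <- -1L
  ground_truth <- list(
    atlas = atlas,
    couplings = couplings,
    amplitudes = amplitudes,
    task_effect_signs = task_signs,
    age_slopes = expand_network_param(config$age_slope, k, TRUE),
    behavior = list(link = config$behavior_link,
                    intercept = config$behavior_intercept,
                    age_slope = config$behavior_age_slope),
    config = config)
  out <- list(runs = runs, subjects = subjects, mask = atlas$mask,
              design = design, atlas = atlas, ground_truth = ground_truth)
  if (!is.null(dir)) write_cohort(out, dir)
  out
}
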