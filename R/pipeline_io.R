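#' Pipeline configuration
#'
#' One document configuring the full analysis. Exactly one of `synthetic`
#' (a [cohort_config()]) or `paths` (existing files) must be supplied.
#'
#' @param synthetic `cohort_config` for synthetic-cohort generation.
#' @param paths list with `runs` (directory or vector of NIfTI files named
#'   `sub-<id>_<condition>.nii[.gz]`), `mask` (NIfTI), `subjects` (TSV),
#'   `design` (JSON).
#' @param ecm `ecm_config`.
#' @param ica_k components for the spatial ICA; default 40 (the conventional
#'   fixed model order), or planted networks + artifacts for synthetic runs.
#' @param ica_seed seed for the ICA rotation.
#' @param tfce `tfce_params`.
#' @param n_perm voxel-wise permutations.
#' @param fdr_q,fdr_scope FDR level and family scope (see
#'   [component_statistics()]).
#' @param cluster_cut flat clusters for the component dendrogram.
#' @param voxelwise_tests subset of `c("task_diff", "age_diff", "age_rest",
#'   "age_task")`.
#' @param out_dir output directory (`NULL` = keep everything in memory).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, paths = NULL,
                            ecm = ecm_config(), ica_k = NULL, ica_seed = 1L,
                            tfce = tfce_params(), n_perm = 500L,
                            fdr_q = 0.05, fdr_scope = "per_family",
                            cluster_cut = 2L,
                            voxelwise_tests = c("task_diff", "age_diff"),
                            out_dir = NULL) {
  if (is.null(synthetic) == is.null(paths))
    stop_hubcent("exactly one of synthetic/paths must be supplied",
                 class = "hubcent_config_error")
  if (!is.null(synthetic)) validate_cohort_config(synthetic)
  if (!is.null(paths)) {
    need <- c("runs", "mask", "subjects", "design")
    if (!all(need %in% names(paths)))
      stop_hubcent("paths must name %s", paste(need, collapse = ", "),
                   class = "hubcent_config_error")
    for (p in unlist(paths[c("mask", "subjects", "design")]))
      if (!file.exists(p))
        stop_hubcent("input path does not exist: %s", p,
                     class = "hubcent_config_error")
  }
  bad <- setdiff(voxelwise_tests,
                 c("task_diff", "age_diff", "age_rest", "age_task"))
  if (length(bad) > 0L)
    stop_hubcent("unknown voxelwise test(s): %s", paste(bad, collapse = ", "),
                 class = "hubcent_config_error")
  structure(list(synthetic = synthetic, paths = paths, ecm = ecm,
                 ica_k = ica_k, ica_seed = as.integer(ica_seed),
                 tfce = tfce, n_perm = as.integer(n_perm),
                 fdr_q = fdr_q, fdr_scope = fdr_scope,
                 cluster_cut = as.integer(cluster_cut),
                 voxelwise_tests = voxelwise_tests,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Write a synthetic cohort to disk
#'
#' Runs as 4-D NIfTI-1 (`runs/sub-<id>_<condition>.nii.gz`), mask as 3-D
#' NIfTI-1, the subject table as TSV with header
#' `subject_id age sex hits false_alarms`, and the task design as JSON.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "runs"), recursive = TRUE, showWarnings = FALSE)
  for (run in cohort$runs) {
    f <- file.path(dir, "runs",
                   sprintf("sub-%s_%s.nii.gz", run$subject_id, run$condition))
    img <- RNifti::asNifti(run$data)
    RNifti::pixdim(img) <- c(1, 1, 1, run$tr_seconds)
    RNifti::writeNifti(img, f)
  }
  RNifti::writeNifti(RNifti::asNifti(cohort$mask$array * 1L),
                     file.path(dir, "mask.nii.gz"))
  tab <- cohort$subjects[, c("subject_id", "age_years", "sex", "hits",
                             "false_alarms")]
  names(tab)[2] <- "age"
  write.table(tab, file.path(dir, "subjects.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  des <- cohort$design
  jsonlite::write_json(
    list(onsets = des$onsets,
         block_seconds = des$block_seconds,
         instruction_onsets = des$instruction_onsets,
         instruction_seconds = des$instruction_seconds,
         response_onsets = des$response_onsets,
         response_seconds = des$response_seconds,
         blocks_per_condition = des$blocks_per_condition,
         trials_per_block = des$trials_per_block,
         targets_per_block = des$targets_per_block,
         total_seconds = des$total_seconds),
    file.path(dir, "design.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read pipeline inputs from disk
#'
#' Enforces grid consistency across runs and mask and validates the subject
#' table schema; each failure mode is reported with the offending file or
#' column.
#'
#' @param paths list with `runs`, `mask`, `subjects`, `design` (see
#'   [pipeline_config()]).
#' @return list with `runs` (list of `bold_run`), `mask`, `subjects`,
#'   `design`.
#' @export
read_inputs <- function(paths) {
  mask_img <- RNifti::readNifti(paths$mask)
  mask <- as_brain_mask(array(as.numeric(mask_img) > 0, dim = dim(mask_img)))
  run_files <- paths$runs
  if (length(run_files) == 1L && dir.exists(run_files))
    run_files <- list.files(run_files, pattern = "\\.nii(\\.gz)?$",
                            full.names = TRUE)
  if (length(run_files) == 0L)
    stop_hubcent("no run images found", class = "hubcent_io_error")
  runs <- lapply(sort(run_files), function(f) {
    m <- regmatches(basename(f),
                    regexec("^sub-(.+)_(rest|task)\\.nii(\\.gz)?$",
                            basename(f)))[[1]]
    if (length(m) == 0L)
      stop_hubcent("run filename %s does not follow sub-<id>_<condition>.nii",
                   basename(f), class = "hubcent_io_error")
    img <- RNifti::readNifti(f)
    d <- dim(img)
    if (length(d) != 4L || !identical(as.integer(d[1:3]),
                                      as.integer(mask$dims)))
      stop_hubcent("grid mismatch between %s and mask", basename(f),
                   class = "hubcent_grid_error")
    tr <- RNifti::pixdim(img)[4]
    structure(list(data = array(as.numeric(img), dim = d),
                   tr_seconds = if (is.finite(tr) && tr > 0) tr else 3.0,
                   subject_id = m[2], condition = m[3]),
              class = "bold_run")
  })
  subjects <- read.delim(paths$subjects, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "hits", "false_alarms")
  missing_cols <- setdiff(need, names(subjects))
  if (length(missing_cols) > 0L)
    stop_hubcent("subject table missing column(s): %s",
                 paste(missing_cols, collapse = ", "),
                 class = "hubcent_schema_error")
  if (anyDuplicated(subjects$subject_id))
    stop_hubcent("duplicate subject ids in subject table",
                 class = "hubcent_schema_error")
  names(subjects)[names(subjects) == "age"] <- "age_years"
  dj <- jsonlite::read_json(paths$design, simplifyVector = TRUE)
  design <- structure(list(
    onsets = lapply(dj$onsets, as.numeric),
    block_seconds = dj$block_seconds,
    instruction_onsets = as.numeric(dj$instruction_onsets),
    instruction_seconds = dj$instruction_seconds,
    response_onsets = as.numeric(dj$response_onsets),
    response_seconds = dj$response_seconds,
    blocks_per_condition = dj$blocks_per_condition,
    trials_per_block = dj$trials_per_block,
    targets_per_block = dj$targets_per_block,
    total_seconds = dj$total_seconds), class = "task_design")
  list(runs = runs, mask = mask, subjects = subjects, design = design)
}

#' Run the full analysis pipeline
#'
#' Synthetic generation (or input reading), per-run eigenvector centrality,
#' spatial ICA with canonicalization and artifact exclusion, dual-regression
#' task GLMs, component statistics with FDR, component clustering, and
#' voxel-wise permutation inference — all driven by one config. Deterministic
#' stages reproduce byte-identically under the same config; with an
#' `out_dir`, completed stages are resumed from disk on rerun when the config
#' hash matches.
#'
#' @param config `pipeline_config`.
#' @param verbose print per-stage progress.
#' @return object of class `results_bundle`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  t_start <- Sys.time()
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  cache_dir <- NULL
  if (!is.null(config$out_dir)) {
    cache_dir <- file.path(config$out_dir, "stages")
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  }
  stage <- function(name, compute) {
    if (!is.null(cache_dir)) {
      f <- file.path(cache_dir, paste0(name, "_", hash, ".rds"))
      if (file.exists(f)) {
        if (verbose) message(sprintf("[%s] resumed from %s", name, f))
        return(readRDS(f))
      }
    }
    t0 <- Sys.time()
    out <- tryCatch(compute(), error = function(e) {
      stop_hubcent("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e), class = "hubcent_stage_error")
    })
    if (verbose)
      message(sprintf("[%s] %.1fs", name,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    if (!is.null(cache_dir))
      saveRDS(out, file.path(cache_dir, paste0(name, "_", hash, ".rds")))
    out
  }

  inputs <- stage("inputs", function() {
    if (!is.null(config$synthetic)) generate_cohort(config$synthetic)
    else read_inputs(config$paths)
  })
  mask <- inputs$mask
  ec_maps <- stage("ecm", function() {
    lapply(inputs$runs, compute_ec_map, mask = mask, config = config$ecm)
  })
  dec <- stage("decomposition", function() {
    K <- config$ica_k %||% if (!is.null(config$synthetic))
      config$synthetic$k_networks + config$synthetic$k_artifacts else 40L
    ecmat <- stack_ec_maps(ec_maps, mask)
    d <- canonicalize_components(
      fit_spatial_ica(ecmat, K, seed = config$ica_seed))
    if (!is.null(inputs$ground_truth)) {
      M <- atlas_matrix(inputs$atlas)
      sig <- inputs$atlas$labels != "artifact"
      d <- classify_artifact_components(d, M[sig, , drop = FALSE],
                                        M[!sig, , drop = FALSE])
    } else {
      d <- classify_artifact_components(d)
    }
    d
  })
  activation <- stage("task_glm", function() {
    keep <- which(dec$retained)
    task_runs <- inputs$runs[vapply(inputs$runs,
                                    function(r) r$condition == "task",
                                    logical(1))]
    ids <- vapply(task_runs, function(r) r$subject_id, character(1))
    contrasts <- t(vapply(task_runs, function(r) {
      dm <- build_design_matrix(inputs$design, dim(r$data)[4], r$tr_seconds)
      ts <- dual_regression_timeseries(r, dec$spatial_maps[keep, , drop = FALSE],
                                       mask)
      vapply(seq_along(keep), function(k)
        activation_contrast(fit_component_glm(ts[, k], dm)), numeric(1))
    }, numeric(length(keep))))
    rownames(contrasts) <- ids
    contrasts
  })
  stat_table <- stage("component_stats", function() {
    diff_ids <- compute_difference_scores(dec)$subject_id
    component_statistics(dec, inputs$subjects,
                         activation = activation[diff_ids, , drop = FALSE],
                         fdr_q = config$fdr_q, fdr_scope = config$fdr_scope)
  })
  clustering <- stage("clustering", function() {
    if (sum(dec$retained) >= 2L)
      component_weight_clustering(dec, config$cluster_cut)
    else NULL
  })
  voxel <- stage("voxelwise", function() {
    diffs <- voxelwise_difference(
      Filter(function(m) m$condition == "task", ec_maps),
      Filter(function(m) m$condition == "rest", ec_maps))
    sub <- inputs$subjects[match(rownames(diffs),
                                 inputs$subjects$subject_id), ]
    cov <- data.frame(age = sub$age_years, sex = sub$sex)
    out <- list()
    if ("task_diff" %in% config$voxelwise_tests)
      out$task_diff <- permutation_fwe(diffs, mask, test = "one_sample",
                                       n_perm = config$n_perm,
                                       seed = config$ica_seed,
                                       params = config$tfce)
    if ("age_diff" %in% config$voxelwise_tests)
      out$age_diff <- permutation_fwe(diffs, mask, covariates = cov,
                                      test = "regression",
                                      n_perm = config$n_perm,
                                      seed = config$ica_seed,
                                      params = config$tfce)
    for (cond in c("rest", "task")) {
      key <- paste0("age_", cond)
      if (key %in% config$voxelwise_tests) {
        M <- t(vapply(Filter(function(m) m$condition == cond, ec_maps),
                      function(m) m$values, numeric(length(mask$idx))))
        out[[key]] <- permutation_fwe(M, mask, covariates = cov,
                                      test = "regression",
                                      n_perm = config$n_perm,
                                      seed = config$ica_seed,
                                      params = config$tfce)
      }
    }
    out
  })
  manifest <- list(config_hash = hash,
                   n_runs = length(inputs$runs),
                   n_subjects = nrow(inputs$subjects),
                   ica_k = dec$K, retained = which(dec$retained),
                   n_perm = config$n_perm,
                   package_version = as.character(utils::packageVersion("hubcent")),
                   elapsed_seconds = as.numeric(difftime(Sys.time(), t_start,
                                                         units = "secs")))
  bundle <- structure(list(ec_maps = ec_maps, decomposition = dec,
                           activation = activation, stat_table = stat_table,
                           clustering = clustering, voxelwise = voxel,
                           subjects = inputs$subjects, mask = mask,
                           ground_truth = inputs$ground_truth,
                           manifest = manifest),
                      class = "results_bundle")
  if (!is.null(config$out_dir)) write_results(bundle, config$out_dir)
  bundle
}

#' @export
print.results_bundle <- function(x, ...) {
  cat(sprintf("<results_bundle> %d EC maps, %d/%d components retained, %d stat rows, voxelwise tests: %s\n",
              length(x$ec_maps), sum(x$decomposition$retained),
              x$decomposition$K, nrow(x$stat_table),
              paste(names(x$voxelwise), collapse = ", ")))
  invisible(x)
}

#' Write a results bundle to disk
#'
#' EC maps and voxel-wise statistic maps as NIfTI-1 with JSON sidecars,
#' component maps as 4-D NIfTI, weights and the statistics table as TSV,
#' the dendrogram as JSON, and a provenance manifest.
#'
#' @param bundle `results_bundle`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(bundle, dir) {
  dir.create(file.path(dir, "ecm"), recursive = TRUE, showWarnings = FALSE)
  mask <- bundle$mask
  embed <- function(v) {
    full <- array(0, dim = mask$dims); full[mask$idx] <- v; full
  }
  for (m in bundle$ec_maps) {
    base <- file.path(dir, "ecm", sprintf("ec_sub-%s_%s", m$subject_id,
                                          m$condition))
    RNifti::writeNifti(RNifti::asNifti(embed(m$values)),
                       paste0(base, ".nii.gz"))
    jsonlite::write_json(list(lambda = m$lambda, n_iter = m$n_iter,
                              flagged = m$flagged),
                         paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  }
  dec <- bundle$decomposition
  comp4d <- array(0, dim = c(mask$dims, dec$K))
  for (k in seq_len(dec$K)) comp4d[, , , k] <- embed(dec$spatial_maps[k, ])
  RNifti::writeNifti(RNifti::asNifti(comp4d),
                     file.path(dir, "components.nii.gz"))
  wt <- data.frame(run_id = seq_len(nrow(dec$weights)),
                   subject_id = dec$meta$subject_id,
                   condition = dec$meta$condition)
  W <- dec$weights
  colnames(W) <- sprintf("comp_%02d", seq_len(dec$K))
  write.table(cbind(wt, W), file.path(dir, "weights.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$stat_table, file.path(dir, "stat_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$clustering)) {
    h <- bundle$clustering$hclust
    jsonlite::write_json(list(merge = h$merge, height = h$height,
                              order = h$order,
                              labels = names(bundle$clustering$labels),
                              cluster = unname(bundle$clustering$labels)),
                         file.path(dir, "dendrogram.json"), digits = NA)
  }
  for (nm in names(bundle$voxelwise)) {
    vs <- bundle$voxelwise[[nm]]
    RNifti::writeNifti(RNifti::asNifti(embed(vs$t)),
                       file.path(dir, sprintf("voxel_%s_t.nii.gz", nm)))
    RNifti::writeNifti(RNifti::asNifti(embed(vs$tfce_obs)),
                       file.path(dir, sprintf("voxel_%s_tfce.nii.gz", nm)))
    RNifti::writeNifti(RNifti::asNifti(embed(1 - vs$p_fwe)),
                       file.path(dir, sprintf("voxel_%s_1mp.nii.gz", nm)))
    jsonlite::write_json(list(seed = vs$seed, n_perm = vs$n_perm,
                              E = vs$params$E, H = vs$params$H,
                              n_steps = vs$params$n_steps,
                              connectivity = vs$params$connectivity),
                         file.path(dir, sprintf("voxel_%s.json", nm)),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
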