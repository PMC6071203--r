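#' Task-minus-rest difference scores of subject weights
#'
#' For every retained component, the subject's task-run weight minus the
#' rest-run weight. Subjects missing either run are listed and dropped with a
#' warning.
#'
#' @param dec `ec_decomposition` whose `meta` carries `subject_id` and
#'   `condition` per run (row).
#' @return object of class `difference_scores`: `scores` (subjects x retained
#'   components, columns named `comp_<k>`), `subject_id`.
#' @export
compute_difference_scores <- function(dec) {
  meta <- dec$meta
  if (is.null(meta))
    stop_hubcent("decomposition carries no run metadata",
                 class = "hubcent_data_error")
  keep <- which(dec$retained)
  subjects <- unique(meta$subject_id)
  has_both <- vapply(subjects, function(s) {
    all(c("rest", "task") %in% meta$condition[meta$subject_id == s])
  }, logical(1))
  if (any(!has_both)) {
    warn_hubcent("unpaired subject(s) dropped from difference scores: %s",
                 paste(subjects[!has_both], collapse = ", "))
    subjects <- subjects[has_both]
  }
  W <- dec$weights[, keep, drop = FALSE]
  scores <- t(vapply(subjects, function(s) {
    it <- which(meta$subject_id == s & meta$condition == "task")[1]
    ir <- which(meta$subject_id == s & meta$condition == "rest")[1]
    W[it, ] - W[ir, ]
  }, numeric(length(keep))))
  colnames(scores) <- sprintf("comp_%d", keep)
  structure(list(scores = scores, subject_id = subjects,
                 components = keep),
            class = "difference_scores")
}

# weights for one condition, subjects x retained components, aligned to ids
condition_weights <- function(dec, condition, subject_id) {
  keep <- which(dec$retained)
  idx <- vapply(subject_id, function(s) {
    which(dec$meta$subject_id == s & dec$meta$condition == condition)[1]
  }, integer(1))
  W <- dec$weights[idx, keep, drop = FALSE]
  colnames(W) <- sprintf("comp_%d", keep)
  W
}

#' One-sample t tests on difference scores
#'
#' Per component: mean difference, `t = mean / (sd / sqrt(n))`, two-tailed p
#' with n - 1 degrees of freedom.
#'
#' @param diff `difference_scores` (or a plain subjects x components matrix).
#' @return data.frame with `component`, `family`, `estimate`, `t`, `p`, `n`.
#' @export
task_effect_test <- function(diff) {
  D <- if (inherits(diff, "difference_scores")) diff$scores else as.matrix(diff)
  n <- nrow(D)
  if (n < 3L) stop_hubcent("need >= 3 paired subjects", class = "hubcent_data_error")
  sds <- apply(D, 2, sd)
  if (any(sds == 0))
    stop_hubcent("zero-variance difference scores in component(s) %s",
                 paste(colnames(D)[sds == 0], collapse = ", "),
                 class = "hubcent_data_error")
  m <- colMeans(D)
  tv <- m / (sds / sqrt(n))
  data.frame(component = colnames(D) %||% sprintf("comp_%d", seq_along(m)),
             family = "task_effect", estimate = m, t = tv,
             p = 2 * pt(-abs(tv), n - 1), n = n, row.names = NULL)
}

#' OLS association between a per-subject response and a predictor
#'
#' Fits `response ~ intercept + covariates` and reports the coefficient,
#' t statistic and two-tailed p of the predictor of interest. Used for the
#' age, interaction, and performance families with the appropriate response
#' (task weights, rest weights, or difference scores).
#'
#' @param response numeric vector of per-subject values.
#' @param covariates data.frame of predictors (no missing values).
#' @param predictor_of_interest name of the covariate to report.
#' @return one-row data.frame with `estimate`, `t`, `p`, `n`.
#' @export
weight_regression <- function(response, covariates, predictor_of_interest) {
  covariates <- as.data.frame(covariates)
  if (!predictor_of_interest %in% names(covariates))
    stop_hubcent("predictor '%s' not among covariates", predictor_of_interest,
                 class = "hubcent_data_error")
  if (anyNA(response) || anyNA(covariates))
    stop_hubcent("missing values in response or covariates",
                 class = "hubcent_data_error")
  n <- length(response)
  if (n <= ncol(covariates) + 1L)
    stop_hubcent("n = %d too small for %d predictors", n, ncol(covariates),
                 class = "hubcent_data_error")
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  if (qr(X)$rank < ncol(X))
    stop_hubcent("collinear covariates", class = "hubcent_data_error")
  fit <- stats::lm.fit(X, response)
  df <- n - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(sigma2 * diag(XtXinv))
  j <- match(predictor_of_interest, colnames(X))
  tv <- fit$coefficients[j] / se[j]
  data.frame(estimate = fit$coefficients[j], t = tv,
             p = 2 * pt(-abs(tv), df), n = n, row.names = NULL)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted q-values with monotonicity enforced, and significance
#' flags at level `q`.
#'
#' @param pvals vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return list with `qvals` and logical `significant`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0L)
    stop_hubcent("empty p-value vector", class = "hubcent_data_error")
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop_hubcent("p-values must be finite in [0, 1]",
                 class = "hubcent_data_error")
  qv <- stats::p.adjust(pvals, method = "BH")
  list(qvals = qv, significant = qv <= q)
}

#' Full component-wise statistics table
#'
#' Runs every analysis family of the component-level inference: the
#' one-sample task-effect test on EC difference scores; age regressions on
#' task and rest weights (sex-adjusted); the task-by-age interaction
#' (difference score on age); performance associations (difference score on
#' hit rate, false-alarm rate, d-prime, each adjusting for age and sex); and,
#' when activation contrasts are supplied, the activation one-sample test and
#' its age regression. BH-FDR is applied per family (default) or globally.
#'
#' @param dec `ec_decomposition` (canonicalized, artifact-flagged).
#' @param subjects data.frame with `subject_id`, `age_years`, `sex`, and
#'   behaviour counts `hits`, `false_alarms`, `n_targets`, `n_nontargets`.
#' @param activation optional subjects x retained-components matrix of
#'   activation contrasts (rows aligned to `subjects`).
#' @param fdr_q FDR level.
#' @param fdr_scope `"per_family"` (default, one BH family per analysis) or
#'   `"global"` (one family across all tests and components).
#' @return data.frame of class `stat_table`:
#'   `component family estimate t p q significant n`.
#' @export
component_statistics <- function(dec, subjects, activation = NULL,
                                 fdr_q = 0.05,
                                 fdr_scope = c("per_family", "global")) {
  fdr_scope <- match.arg(fdr_scope)
  diff <- compute_difference_scores(dec)
  ids <- diff$subject_id
  sub <- subjects[match(ids, subjects$subject_id), , drop = FALSE]
  covar_base <- data.frame(age = sub$age_years, sex = sub$sex)
  rows <- list(task_effect_test(diff))
  Wt <- condition_weights(dec, "task", ids)
  Wr <- condition_weights(dec, "rest", ids)
  reg_family <- function(Y, family, covars, pred) {
    do.call(rbind, lapply(colnames(Y), function(cn) {
      r <- weight_regression(Y[, cn], covars, pred)
      cbind(component = cn, family = family, r)
    }))
  }
  rows$age_task <- reg_family(Wt, "age_task", covar_base, "age")
  rows$age_rest <- reg_family(Wr, "age_rest", covar_base, "age")
  rows$interaction <- reg_family(diff$scores, "interaction", covar_base, "age")
  if (all(c("hits", "false_alarms") %in% names(sub))) {
    beh <- behavior_scores(sub$hits, sub$false_alarms,
                           sub$n_targets %||% 45L, sub$n_nontargets %||% 135L)
    for (pf in c("hit_rate", "fp_rate", "dprime")) {
      fam <- c(hit_rate = "perf_hit", fp_rate = "perf_fp",
               dprime = "perf_dprime")[[pf]]
      cov <- cbind(covar_base, perf = beh[[pf]])
      rows[[fam]] <- reg_family(diff$scores, fam, cov, "perf")
    }
  }
  if (!is.null(activation)) {
    A <- as.matrix(activation)
    colnames(A) <- colnames(diff$scores)
    act <- task_effect_test(A)
    act$family <- "activation_task"
    rows$activation_task <- act
    rows$activation_age <- reg_family(A, "activation_age", covar_base, "age")
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (fdr_scope == "global") {
    f <- bh_fdr(tab$p, fdr_q)
    tab$q <- f$qvals; tab$significant <- f$significant
  } else {
    tab$q <- NA_real_; tab$significant <- NA
    for (fam in unique(tab$family)) {
      i <- tab$family == fam
      f <- bh_fdr(tab$p[i], fdr_q)
      tab$q[i] <- f$qvals; tab$significant[i] <- f$significant
    }
  }
  class(tab) <- c("stat_table", "data.frame")
  tab
}

#' @export
print.stat_table <- function(x, ...) {
  cat(sprintf("<stat_table> %d tests across %d components, %d families; %d significant (FDR)\n",
              nrow(x), length(unique(x$component)),
              length(unique(x$family)), sum(x$significant, na.rm = TRUE)))
  NextMethod()
}

#' Correlation between task effects on centrality and on activation
#'
#' Pearson correlation, across retained components, of the group-level task
#' statistic on EC difference scores with the group-level activation
#' statistic; by default the scale-invariant t values of the two families are
#' correlated (the per-component means are selectable).
#'
#' @param stat_table `stat_table` containing the `task_effect` and
#'   `activation_task` families.
#' @param use `"t"` (default) or `"estimate"`.
#' @return list with `r`, `p` (two-tailed, t-transform with n - 2 d.o.f.),
#'   `n_components`.
#' @export
ec_activation_correlation <- function(stat_table, use = c("t", "estimate")) {
  use <- match.arg(use)
  a <- stat_table[stat_table$family == "task_effect", ]
  b <- stat_table[stat_table$family == "activation_task", ]
  b <- b[match(a$component, b$component), ]
  if (nrow(a) < 3L || anyNA(b$component))
    stop_hubcent("need both families on >= 3 shared components",
                 class = "hubcent_data_error")
  x <- a[[use]]; y <- b[[use]]
  r <- cor(x, y)
  n <- nrow(a)
  tv <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tv), n - 2), n_components = n)
}
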