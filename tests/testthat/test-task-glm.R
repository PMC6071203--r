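test_that("the HRF peaks a few seconds after stimulus onset", {
  t <- seq(0, 32, by = 0.1)
  h <- hrf_double_gamma(t)
  expect_equal(max(h), 1, tolerance = 1e-2)
  expect_gt(t[which.max(h)], 4)
  expect_lt(t[which.max(h)], 7)
  expect_lt(min(h), 0)          # undershoot
})

test_that("block regressors match a direct fine-grid convolution oracle", {
  Tn <- 60; tr <- 3; dt <- 0.1
  col <- hrf_regressor(0, 30, Tn, tr, dt = dt)
  # oracle: discrete convolution of boxcar and HRF taps on the fine grid
  tg <- seq(0, Tn * tr + 32, by = dt)
  box <- as.numeric(tg >= 0 & tg < 30)
  h <- hrf_double_gamma(seq(0, 32, by = dt)) * dt
  h <- h / sum(h)
  full <- stats::convolve(box, rev(h), type = "open")[seq_along(tg)]
  oracle <- full[round((seq_len(Tn) - 1) * tr / dt) + 1]
  expect_equal(col, oracle, tolerance = 1e-8)
  # response rises to its maximum within the block, after the initial ramp
  tmax <- (which.max(col) - 1) * tr
  expect_gte(tmax, 6)
  expect_lte(tmax, 33)
})

test_that("design matrices carry the expected columns and fail loudly", {
  des <- make_task_design()
  dm <- build_design_matrix(des, 124, 3)
  expect_setequal(colnames(dm), c("0back", "1back", "2back", "instructions",
                                  "responses", "intercept"))
  cc <- cor(dm[, c("0back", "1back", "2back")])
  expect_true(all(cc[upper.tri(cc)] < 1))

  des2 <- des
  des2$response_onsets <- numeric(0)
  expect_warning(dm2 <- build_design_matrix(des2, 124, 3), "empty regressor")
  expect_false("responses" %in% colnames(dm2))

  des3 <- des
  des3$onsets$`2back` <- c(des3$onsets$`2back`, 1000)
  expect_error(build_design_matrix(des3, 124, 3),
               class = "hubcent_design_error")
})

test_that("dual regression recovers planted component time courses", {
  mask <- flat_mask(80)
  set.seed(1)
  m1 <- c(abs(rnorm(40, 2)), rep(0, 40))
  m2 <- c(rep(0, 40), abs(rnorm(40, 2)))   # orthogonal supports
  s1 <- rnorm(50); s2 <- rnorm(50)
  Y <- outer(s1, m1) + outer(s2, m2)
  run <- run_from_matrix(Y)
  ts <- dual_regression_timeseries(run, rbind(m1, m2), mask)
  expect_gt(cor(ts[, 1], s1), 0.99)
  expect_gt(cor(ts[, 2], s2), 0.99)
  expect_lt(abs(cor(ts[, 1], s2)), 0.1)

  # rank-one case
  ts1 <- dual_regression_timeseries(run_from_matrix(outer(s1, m1)), rbind(m1),
                                    mask)
  expect_gt(cor(ts1[, 1], s1), 0.999)

  # spatial demeaning: adding a constant offset per volume changes nothing
  run_off <- run_from_matrix(Y + 7)
  ts_off <- dual_regression_timeseries(run_off, rbind(m1, m2), mask)
  expect_equal(ts, ts_off, tolerance = 1e-9)

  expect_error(dual_regression_timeseries(run, rbind(m1, m1), mask),
               class = "hubcent_dim_error")
})

test_that("component GLMs are exact on noiseless input and unbiased on noise", {
  des <- make_task_design()
  dm <- build_design_matrix(des, 124, 3)
  fit <- fit_component_glm(dm[, "2back"], dm)
  expect_equal(unname(fit$betas["2back"]), 1, tolerance = 1e-9)
  expect_equal(unname(fit$betas["0back"]), 0, tolerance = 1e-9)
  expect_equal(unname(fit$betas["1back"]), 0, tolerance = 1e-9)
  expect_equal(fit$df, 124 - ncol(dm))

  set.seed(2)
  b1 <- vapply(1:200, function(i)
    fit_component_glm(rnorm(124), dm)$betas[["1back"]], numeric(1))
  se <- sd(b1) / sqrt(200)
  expect_lt(abs(mean(b1)), 2 * se + 1e-8)

  expect_error(fit_component_glm(rnorm(10), dm), class = "hubcent_dim_error")
})

test_that("planted condition betas are recovered to within 0.05", {
  des <- make_task_design()
  dm <- build_design_matrix(des, 124, 3)
  X <- unclass(dm)
  truth <- c(`0back` = 0.2, `1back` = 0.5, `2back` = 0.9)
  set.seed(3)
  est <- t(vapply(1:50, function(i) {
    y <- X[, "0back"] * 0.2 + X[, "1back"] * 0.5 + X[, "2back"] * 0.9 +
      rnorm(124, sd = 0.1)
    fit_component_glm(y, dm)$betas[names(truth)]
  }, numeric(3)))
  expect_true(all(abs(colMeans(est) - truth) < 0.05))
})

test_that("the activation contrast is (b1 + b2)/2 - b0", {
  mk <- function(b0, b1, b2)
    list(betas = c(`0back` = b0, `1back` = b1, `2back` = b2, intercept = 1))
  expect_equal(activation_contrast(mk(0, 0, 0)), 0)
  expect_equal(activation_contrast(mk(0, 0, 1)), 0.5)
  expect_equal(activation_contrast(mk(0.2, 0.5, 0.9)), 0.5)
  # shifting all three condition betas by a constant changes nothing
  expect_equal(activation_contrast(mk(0.2 + 3, 0.5 + 3, 0.9 + 3)),
               activation_contrast(mk(0.2, 0.5, 0.9)))
  expect_error(activation_contrast(list(betas = c(`0back` = 1))),
               class = "hubcent_data_error")
})

test_that("d-prime follows the z-difference definition with clamped rates", {
  b <- behavior_scores(hits = 22.5, false_alarms = 67.5, 45, 135)
  expect_equal(b$dprime, 0)
  b2 <- behavior_scores(36, 27, 45, 135)      # rates 0.8 and 0.2
  expect_equal(b2$dprime, qnorm(0.8) - qnorm(0.2))
  # perfect scores are clamped, not infinite
  b3 <- behavior_scores(45, 0, 45, 135)
  expect_true(is.finite(b3$dprime))
  expect_equal(b3$hit_rate, 1 - 1 / 90)
  expect_equal(b3$fp_rate, 1 / 270)
  # antisymmetry under swapping hit and false-alarm rates
  ba <- behavior_scores(40, 30, 45, 45)
  bb <- behavior_scores(30, 40, 45, 45)
  expect_equal(ba$dprime, -bb$dprime)
  expect_error(behavior_scores(50, 0, 45, 135), class = "hubcent_data_error")
})

test_that("stage-1 + stage-2 composition recovers planted contrast signs", {
  mask <- flat_mask(60)
  des <- make_task_design()
  dm <- build_design_matrix(des, 124, 3)
  X <- unclass(dm)
  m1 <- c(abs(rnorm(30, 2)), rep(0, 30))
  m2 <- c(rep(0, 30), abs(rnorm(30, 2)))
  # planted series: contrast +0.5 on component 1, -0.5 on component 2
  base1 <- X[, "1back"] * 0.5 + X[, "2back"] * 0.5 + X[, "0back"] * 0
  base2 <- -base1
  hits <- 0
  for (s in 1:40) {
    set.seed(s)
    y1 <- base1 + rnorm(124); y2 <- base2 + rnorm(124)
    Y <- outer(y1, m1) + outer(y2, m2) + matrix(rnorm(124 * 60), 124)
    run <- run_from_matrix(Y, condition = "task")
    ts <- dual_regression_timeseries(run, rbind(m1, m2), mask)
    c1 <- activation_contrast(fit_component_glm(ts[, 1], dm))
    c2 <- activation_contrast(fit_component_glm(ts[, 2], dm))
    if (c1 > 0 && c2 < 0) hits <- hits + 1
  }
  expect_gte(hits, 38)   # >= 95% of 40 replicates
})
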