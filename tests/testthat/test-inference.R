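test_that("profiled-REML solver agrees with lme4 across ICC regimes", {
  for (icc in c(0, 0.05, 0.3)) {
    d <- toy_frame(n = 246, k = 11, cluster_sd = sqrt(icc / max(1 - icc, 1e-9)),
                   seed = round(100 * icc) + 1)
    X <- model.matrix(~ arm + cost_baseline + staffing_ratio, data = d)
    fast <- lmm_ri(d$cost_total, X, d$cluster_id)
    mm <- suppressWarnings(suppressMessages(lme4::lmer(
      cost_total ~ arm + cost_baseline + staffing_ratio + (1 | cluster_id),
      data = d, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore"))))
    expect_equal(unname(fast$beta), unname(lme4::fixef(mm)), tolerance = 1e-5)
    expect_equal(unname(fast$se),
                 unname(sqrt(diag(as.matrix(vcov(mm))))), tolerance = 1e-4)
  }
})

test_that("with zero cluster variance the mixed model collapses to OLS", {
  d <- toy_frame(n = 200, k = 10, cluster_sd = 0, seed = 4)
  fit <- fit_adjusted_model(d, "cost_total", "cost_baseline",
                            engine = "profile")
  ols <- lm(cost_total ~ arm + cost_baseline + staffing_ratio, data = d)
  expect_lt(abs(fit$estimate - coef(ols)[["armintervention"]]), 1e-6)
})

test_that("identical outcomes in both arms give a null treatment effect", {
  set.seed(5)
  half <- tibble::tibble(
    cluster_id = rep(1:10, each = 10),
    staffing_ratio = runif(10)[rep(1:10, each = 10)],
    cost_baseline = rnorm(100, 2000, 400),
    cost_total = rgamma(100, 2, scale = 2000)
  )
  mirrored <- half; mirrored$cluster_id <- half$cluster_id + 10
  d <- rbind(cbind(half, arm = "intervention"),
             cbind(mirrored, arm = "control"))
  fit <- fit_adjusted_model(d, "cost_total", "cost_baseline",
                            engine = "profile")
  expect_lt(abs(fit$estimate), 1e-8)
  expect_error(
    fit_adjusted_model(d[d$cluster_id %in% c(1, 11), ], "cost_total",
                       "cost_baseline"),
    "2 clusters")
})

test_that("adjusted regression recovers a known treatment effect", {
  est <- vapply(1:40, function(s) {
    d <- toy_frame(n = 246, k = 11, delta_qaly = 0.175, cluster_sd = 0.2,
                   seed = s)
    fit_adjusted_model(d, "qaly", "util_baseline", engine = "profile")$estimate
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.175), 2 * sd(est) / sqrt(40))
})

test_that("bootstrap draw clouds have m x reps paired draws, reproducibly", {
  prepared <- lapply(1:3, function(i) toy_frame(n = 120, k = 6, seed = i))
  dr <- bootstrap_increments(prepared, reps = 40, seed = 2)
  expect_equal(nrow(dr), 3 * 40)
  expect_equal(attr(dr, "n_imputations"), 3)
  expect_equal(attr(dr, "reps_per_imputation"), 40)
  expect_identical(
    as.data.frame(bootstrap_increments(prepared, reps = 40, seed = 2)),
    as.data.frame(dr))
  # identity resample returns the point-estimate pair
  one <- bootstrap_increments(prepared[1], reps = 1, resample = "none",
                              seed = 1)
  fc <- fit_adjusted_model(prepared[[1]], "cost_total", "cost_baseline",
                           engine = "profile")
  fq <- fit_adjusted_model(prepared[[1]], "qaly", "util_baseline",
                           engine = "profile")
  expect_equal(one$delta_cost, fc$estimate)
  expect_equal(one$delta_qaly, fq$estimate)
})

test_that("paired draws carry the generating cost-QALY correlation", {
  d <- toy_frame(n = 2000, k = 20, rho = 0.5, seed = 9)
  # oracle: residual correlation of the generated participant-level data
  rc <- cor(resid(lm(cost_total ~ arm, d)), resid(lm(qaly ~ arm, d)))
  expect_gt(rc, 0.3)
  dr <- bootstrap_increments(list(d), reps = 200, seed = 3)
  expect_gt(cor(dr$delta_cost, dr$delta_qaly), 0)
  # breaking the pairing changes the acceptability curve
  shuffled <- dr
  shuffled$delta_cost <- sample(shuffled$delta_cost)
  grid <- seq(0, 50000, 500)
  expect_false(isTRUE(all.equal(ceac(dr, grid)$probability,
                                ceac(shuffled, grid)$probability)))
})

test_that("bias-corrected intervals match percentile arithmetic", {
  draws <- as.numeric(1:1000)
  ci <- bc_interval(draws, point = 500.5, level = 0.95)
  # z0 = 0, so this is the plain percentile interval
  expect_lt(abs(ci["lower"] - 25.5), 1.5)
  expect_lt(abs(ci["upper"] - 975.5), 1.5)
  set.seed(11)
  skew <- exp(rnorm(5000))
  bc <- bc_interval(skew, point = mean(skew))
  pct <- unname(quantile(skew, c(0.025, 0.975)))
  # mean > median, so z0 > 0 shifts both ends toward the long right tail
  expect_gt(bc["upper"], pct[2])
  expect_gte(bc["lower"], pct[1])
  expect_warning(out <- bc_interval(rep(1, 200), 1), "degenerate")
  expect_equal(unname(out), c(1, 1))
  expect_error(bc_interval(1:50, 25), "100 draws")
})

test_that("responsiveness model detects (only) real utility-behaviour links", {
  tr <- generate_trial(trial_design(8, 8, mean_cluster_size = 25, seed = 3),
                       generative_params(death_hazard = 0), seed = 3)
  panel <- merge(
    build_trajectories(tr$health_states, default_tariff, "proxy_carer"),
    tr$health_states[tr$health_states$respondent == "proxy_carer",
                     c("participant_id", "timepoint", "abc_score")])
  panel <- merge(panel, tr$participants[, c("participant_id", "cluster_id",
                                            "disability_level",
                                            "accommodation",
                                            "living_situation")])
  fit <- responsiveness_model(panel)
  expect_lt(fit$slope, 0)
  # translation invariance of the slope
  panel2 <- panel; panel2$abc_score <- panel2$abc_score + 100
  expect_equal(responsiveness_model(panel2)$slope, fit$slope,
               tolerance = 1e-6)
  # utilities unrelated to the behaviour score: CI straddles 0
  set.seed(1)
  panel3 <- panel; panel3$utility <- rnorm(nrow(panel3), 0.7, 0.15)
  fit3 <- responsiveness_model(panel3)
  expect_true(fit3$ci[1] < 0 && fit3$ci[2] > 0)
  panel4 <- panel; panel4$abc_score <- 10
  expect_error(responsiveness_model(panel4), "within-participant")
})
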