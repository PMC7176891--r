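test_that("identical seeds reproduce the trial byte-for-byte", {
  a <- quick_trial(seed = 5)
  b <- quick_trial(seed = 5)
  expect_identical(a$participants, b$participants)
  expect_identical(a$resource_use, b$resource_use)
  expect_identical(a$health_states, b$health_states)
  expect_identical(a$therapist_activity, b$therapist_activity)
  am <- apply_missingness(a, seed = 9)
  bm <- apply_missingness(b, seed = 9)
  expect_identical(am$missing_index, bm$missing_index)
})

test_that("default design yields about 246 participants over 23 clusters", {
  totals <- vapply(1:10, function(s) nrow(quick_trial(seed = s)$participants),
                   numeric(1))
  expect_true(abs(mean(totals) - 246) < 25)
  tr <- quick_trial(seed = 1)
  expect_equal(length(unique(tr$participants$cluster_id)), 23)
  # arm constant within cluster (cluster randomisation)
  expect_true(all(tapply(tr$participants$arm, tr$participants$cluster_id,
                         function(a) length(unique(a))) == 1))
  dm <- tr$participants$death_month
  expect_true(all(is.na(dm) | (dm > 0 & dm <= 36)))
})

test_that("invalid designs and parameters are rejected", {
  expect_error(trial_design(n_clusters_intervention = 0), "at least one")
  expect_error(trial_design(mean_cluster_size = 0), "positive")
  expect_error(trial_design(timepoints = c(6, 12)), "start at 0")
  expect_error(trial_design(timepoints = c(0, 12, 12)), "increasing")
  expect_error(generative_params(missing_fraction = 0.95), "0.9")
  expect_error(generative_params(utility_decrement_per_abc_point = 0.01),
               "<= 0")
  expect_error(generative_params(cost_icc = 1), "\\[0, 1\\)")
})

test_that("null configuration produces null arm contrasts", {
  p0 <- generative_params(true_delta_cost = 0, true_delta_qaly = 0,
                          cost_icc = 0, utility_icc = 0, death_hazard = 0,
                          missing_fraction = 0,
                          informal_care_hours = c(baseline = 25,
                                                  intervention = 25,
                                                  control = 25, sd = 20))
  pvals <- vapply(1:50, function(s) {
    tr <- generate_trial(trial_design(seed = s), p0, seed = s)
    pr <- prepare_analysis(assemble_analysis(tr), discount = FALSE)
    stats::t.test(qaly ~ arm, data = pr)$p.value
  }, numeric(1))
  expect_gte(sum(pvals > 0.05), 45)
})

test_that("latent utility slope on the behaviour score is the generating slope", {
  tr <- generate_trial(trial_design(20, 20, mean_cluster_size = 125, seed = 2),
                       generative_params(death_hazard = 0), seed = 2)
  hs <- tr$health_states[tr$health_states$respondent == "proxy_carer", ]
  ctl <- hs$participant_id %in%
    tr$participants$participant_id[tr$participants$arm == "control"]
  slope <- coef(lm(latent_utility ~ abc_score, hs[ctl, ]))[["abc_score"]]
  expect_lt(abs(slope - (-0.002)), 0.0005)
})

test_that("arm-level increments match the generating values at large n", {
  d <- trial_design(40, 40, mean_cluster_size = 50, seed = 11)
  p <- generative_params(death_hazard = 0, missing_fraction = 0)
  tr <- generate_trial(d, p, seed = 11)
  pr <- prepare_analysis(assemble_analysis(tr), discount = FALSE)
  # Monte-Carlo SE from cluster-level means (respects the cluster design)
  cl_means <- function(v) tapply(v, pr$cluster_id, mean)
  arm_of <- tapply(as.character(pr$arm), pr$cluster_id, `[`, 1)
  for (spec in list(list(v = pr$qaly, truth = p$true_delta_qaly),
                    list(v = pr$cost_total, truth = p$true_delta_cost))) {
    mm <- cl_means(spec$v)
    dd <- mean(mm[arm_of == "intervention"]) - mean(mm[arm_of == "control"])
    se <- sqrt(var(mm[arm_of == "intervention"]) / sum(arm_of == "intervention") +
                 var(mm[arm_of == "control"]) / sum(arm_of == "control"))
    expect_lt(abs(dd - spec$truth), 3 * se)
  }
})

test_that("masking hits the target fraction, spares baseline, and is MAR", {
  tr <- quick_trial(seed = 21)
  trm <- apply_missingness(tr, seed = 22)
  occ <- unique(tr$health_states[tr$health_states$timepoint > 0,
                                 c("participant_id", "timepoint")])
  frac <- nrow(trm$missing_index) / nrow(occ)
  expect_gte(frac, 0.30); expect_lte(frac, 0.40)
  expect_true(all(trm$missing_index$timepoint > 0))
  # baseline rows untouched
  expect_identical(
    trm$health_states[trm$health_states$timepoint == 0, ],
    tr$health_states[tr$health_states$timepoint == 0, ])
  # zero missingness is the identity
  p0 <- generative_params(missing_fraction = 0)
  tr0 <- generate_trial(trial_design(seed = 3), p0, seed = 3)
  expect_identical(apply_missingness(tr0, seed = 4), tr0)
})

test_that("severe disability doubles the masking odds when so configured", {
  lo <- c(disability_moderate = 0, disability_severe = log(2),
          accommodation_residential = 0, accommodation_supported_living = 0,
          living_with_others = 0)
  p <- generative_params(missingness_log_or = lo, death_hazard = 0)
  tr <- generate_trial(trial_design(20, 20, mean_cluster_size = 50, seed = 31),
                       p, seed = 31)
  trm <- apply_missingness(tr, seed = 32)
  occ <- unique(tr$health_states[tr$health_states$timepoint > 0,
                                 c("participant_id", "timepoint")])
  occ$severe <- tr$participants$disability_level[
    match(occ$participant_id, tr$participants$participant_id)] == "severe"
  occ$masked <- paste(occ$participant_id, occ$timepoint) %in%
    paste(trm$missing_index$participant_id, trm$missing_index$timepoint)
  tab <- table(occ$severe, occ$masked)
  or <- (tab["TRUE", "TRUE"] / tab["TRUE", "FALSE"]) /
    (tab["FALSE", "TRUE"] / tab["FALSE", "FALSE"])
  expect_gte(or, 1.5); expect_lte(or, 2.7)
})

test_that("trials round-trip through CSV + manifest", {
  tr <- apply_missingness(quick_trial(seed = 41), seed = 42)
  dir <- withr::local_tempdir()
  write_trial(tr, dir)
  back <- read_trial(dir)
  expect_equal(as.data.frame(back$participants),
               as.data.frame(tr$participants))
  expect_equal(as.data.frame(back$resource_use),
               as.data.frame(tr$resource_use))
  expect_equal(nrow(back$missing_index), nrow(tr$missing_index))
  expect_equal(back$design$timepoints, tr$design$timepoints)
  expect_equal(back$params$true_delta_qaly, tr$params$true_delta_qaly)
})
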