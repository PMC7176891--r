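test_that("a complete dataset yields m identical copies", {
  w <- toy_wide(50)
  imps <- mice_impute(w, m = 4, seed = 1)
  expect_length(imps, 4)
  for (i in 1:4) expect_identical(imps[[i]], w)
  expect_equal(missing_fraction(w), 0)
})

test_that("m = 'auto' equals the percentage of incomplete participants", {
  w <- toy_wide(100, miss_participants = 35)
  expect_equal(missing_fraction(w), 0.35)
  imps <- mice_impute(w, m = "auto", seed = 1)
  expect_equal(attr(imps, "m"), 35L)
  # minimum of 5 imputations
  w2 <- toy_wide(100, miss_participants = 1)
  expect_equal(attr(mice_impute(w2, m = "auto", seed = 1), "m"), 5L)
  # everyone missing the 36-month utility
  w3 <- toy_wide(20); w3$util_36 <- NA
  expect_equal(missing_fraction(w3), 1)
  expect_error(missing_fraction(toy_wide(0)), "empty")
})

test_that("observed cells are never altered and imputation is deterministic", {
  w <- toy_wide(100, miss_participants = 30, seed = 2)
  imps <- mice_impute(w, m = 5, seed = 7)
  obs <- !is.na(w$util_36)
  for (i in 1:5) {
    expect_identical(imps[[i]]$util_36[obs], w$util_36[obs])
    expect_identical(imps[[i]]$cost_12, w$cost_12)
    expect_false(anyNA(imps[[i]]$util_36))
  }
  # PMM keeps imputed values on the observed support
  pmm <- mice_impute(w, m = 2, method = "pmm", seed = 7)
  expect_true(all(pmm[[1]]$util_36 %in% w$util_36[obs]))
  expect_identical(pmm[[1]]$util_36[obs], w$util_36[obs])
  expect_identical(mice_impute(w, m = 5, seed = 7), imps)
  expect_false(identical(mice_impute(w, m = 5, seed = 8)[[1]]$util_36,
                         imps[[1]]$util_36))
})

test_that("an entirely missing predictor is rejected", {
  w <- toy_wide(50, miss_participants = 10)
  w$staffing_ratio <- NA_real_
  expect_error(mice_impute(w, m = 5, seed = 1), "staffing_ratio")
})

test_that("post-death utility cells carry the death value, not imputations", {
  w <- toy_wide(50, seed = 3)
  w$death_month[1] <- 20
  w$util_36[1] <- NA   # structural: participant died before 36 months
  w$util_36[2] <- NA   # genuinely missing
  expect_equal(missing_fraction(w), 1 / 50)
  imps <- mice_impute(w, m = 5, seed = 1)
  expect_equal(imps[[1]]$util_36[1], 0)
})

test_that("pooled MAR estimates recover the complete-data truth", {
  # oracle: the complete-data (pre-masking) estimate; pooled post-imputation
  # estimates across replications should centre on the generating value
  p <- generative_params(true_delta_qaly = 0.1, true_delta_cost = 0,
                         death_hazard = 0)
  reps <- 30
  est <- matrix(NA_real_, reps, 2,
                dimnames = list(NULL, c("complete", "pooled")))
  for (r in seq_len(reps)) {
    d <- trial_design(12, 12, mean_cluster_size = 84, seed = 500 + r)
    tr <- generate_trial(d, p, seed = 500 + r)
    wide_full <- assemble_analysis(tr)
    fitq <- function(w) {
      fit_adjusted_model(prepare_analysis(w, discount = FALSE), "qaly",
                         "util_baseline", engine = "profile")$estimate
    }
    est[r, "complete"] <- fitq(wide_full)
    trm <- apply_missingness(tr, seed = 900 + r)
    imps <- mice_impute(assemble_analysis(trm), m = 5, seed = 900 + r)
    est[r, "pooled"] <- mean(vapply(imps, fitq, numeric(1)))
  }
  mc_se <- sd(est[, "pooled"]) / sqrt(reps)
  expect_lt(abs(mean(est[, "pooled"]) - 0.1), 2 * mc_se + 1e-12)
  # and the imputed estimates track the complete-data oracle
  expect_gt(cor(est[, "complete"], est[, "pooled"]), 0.5)
})

test_that("under 10% MCAR pooled estimates sit close to complete-case", {
  p <- generative_params(missing_fraction = 0.1, death_hazard = 0,
                         missingness_log_or = c(
                           disability_moderate = 0, disability_severe = 0,
                           accommodation_residential = 0,
                           accommodation_supported_living = 0,
                           living_with_others = 0))
  d <- trial_design(16, 16, mean_cluster_size = 63, seed = 77)
  trm <- apply_missingness(generate_trial(d, p, seed = 77), seed = 78)
  wide <- assemble_analysis(trm)
  cc <- wide[complete.cases(wide[grep("^(cost|util)_", names(wide))]), ]
  fit_cc <- fit_adjusted_model(prepare_analysis(cc, discount = FALSE),
                               "qaly", "util_baseline", engine = "profile")
  imps <- mice_impute(wide, m = 10, seed = 79)
  pooled <- mean(vapply(imps, function(w) {
    fit_adjusted_model(prepare_analysis(w, discount = FALSE), "qaly",
                       "util_baseline", engine = "profile")$estimate
  }, numeric(1)))
  expect_lt(abs(pooled - fit_cc$estimate), 0.5 * fit_cc$se)
})

test_that("Rubin pooling keeps the variance decomposition coherent", {
  set.seed(1)
  est <- rnorm(10); v <- runif(10, 0.5, 1.5)
  pr <- pool_rubin(est, v)
  expect_gte(pr$between, 0)
  expect_gte(pr$total, pr$within)
  expect_equal(pr$estimate, mean(est))
  expect_equal(pr$total, pr$within + (1 + 1 / 10) * pr$between)
})
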