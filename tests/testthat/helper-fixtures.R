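# shared fixtures built in code; kept small so the default run stays fast

default_tariff <- read_tariff()
default_costs <- read_unit_costs()

# a trial at the default 23-cluster scale
quick_trial <- function(seed = 101, params = generative_params(), ...) {
  generate_trial(trial_design(seed = seed, ...), params, seed = seed)
}

# a minimal participant-level analysis frame with a known treatment effect
# and correlated cost/QALY residuals, for inference tests that should not
# depend on the full generator
toy_frame <- function(n = 200, k = 10, delta_cost = 500, delta_qaly = 0.1,
                      rho = 0, cluster_sd = 0, seed = 1) {
  set.seed(seed)
  cl <- rep(seq_len(2 * k), length.out = n)
  arm <- ifelse(cl <= k, "intervention", "control")
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  b <- rnorm(2 * k, 0, cluster_sd)
  tibble::tibble(
    participant_id = seq_len(n), cluster_id = cl,
    arm = factor(arm, levels = c("control", "intervention")),
    staffing_ratio = runif(2 * k)[cl],
    cost_baseline = rnorm(n, 2000, 400),
    util_baseline = rnorm(n, 0.7, 0.1),
    cost_total = 4000 + delta_cost * (arm == "intervention") +
      0.5 * rnorm(n, 2000, 400) + 800 * z1 + 400 * b[cl],
    qaly = 2 + delta_qaly * (arm == "intervention") + 0.3 * z2 +
      0.05 * b[cl]
  )
}

# wide analysis table built directly (no generator), for imputation tests
toy_wide <- function(n = 100, miss_participants = 0, seed = 1) {
  set.seed(seed)
  cl <- rep(1:10, length.out = n)
  w <- tibble::tibble(
    participant_id = seq_len(n), cluster_id = cl,
    arm = ifelse(cl <= 5, "intervention", "control"),
    disability_level = sample(c("mild", "moderate", "severe"), n, TRUE),
    accommodation = sample(c("residential", "supported_living",
                             "independent_floating"), n, TRUE),
    living_situation = sample(c("with_family", "alone", "with_others"), n, TRUE),
    staffing_ratio = runif(10)[cl], death_month = NA_real_,
    cost_0 = rgamma(n, 2, scale = 1000), util_0 = runif(n, 0.3, 0.9),
    cost_6 = rgamma(n, 2, scale = 1000), util_6 = runif(n, 0.3, 0.9),
    cost_12 = rgamma(n, 2, scale = 1000), util_12 = runif(n, 0.3, 0.9),
    cost_36 = rgamma(n, 2, scale = 1000), util_36 = runif(n, 0.3, 0.9)
  )
  if (miss_participants > 0) {
    w$util_36[seq_len(miss_participants)] <- NA
  }
  w
}
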