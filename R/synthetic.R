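#' Specify a cluster-trial design
#'
#' Defaults mirror a 23-service community intellectual-disability trial:
#' 11 clusters randomised to the intervention arm and 12 to treatment as
#' usual, about 246 participants in total, assessed at baseline, 6, 12
#' and 36 months.
#'
#' @param n_clusters_intervention,n_clusters_control Clusters per arm.
#' @param mean_cluster_size Mean participants per cluster (negative
#'   binomial across clusters, minimum 2).
#' @param size_dispersion Negative-binomial size parameter for cluster
#'   sizes (larger = less variable).
#' @param timepoints Assessment months, strictly increasing, starting 0.
#' @param seed Default seed carried with the design.
#' @return A `trial_design` list.
#' @export
trial_design <- function(n_clusters_intervention = 11,
                         n_clusters_control = 12,
                         mean_cluster_size = 246 / 23,
                         size_dispersion = 6,
                         timepoints = c(0, 6, 12, 36),
                         seed = 20140101) {
  if (n_clusters_intervention < 1 || n_clusters_control < 1) {
    stop("each arm needs at least one cluster")
  }
  if (mean_cluster_size <= 0) stop("cluster sizes must be positive")
  if (length(timepoints) < 2 || timepoints[1] != 0 ||
      any(diff(timepoints) <= 0)) {
    stop("timepoints must be strictly increasing and start at 0")
  }
  structure(list(
    n_clusters_intervention = n_clusters_intervention,
    n_clusters_control = n_clusters_control,
    mean_cluster_size = mean_cluster_size,
    size_dispersion = size_dispersion,
    timepoints = timepoints,
    seed = seed
  ), class = "trial_design")
}

#' Generative parameters for synthetic trial data
#'
#' The defaults define the study conditions the analysis pipeline is
#' exercised under: an incremental healthcare cost of GBP 399 and an
#' incremental 0.175 QALYs over 36 months (both on the undiscounted
#' generating scale), modest intraclass correlations, utilities linked to
#' an ABC-C-like challenging-behaviour score through a utility decrement
#' of 0.002 per point, 35% missing-at-random post-baseline records, 52%
#' of participants with an unpaid carer, and right-skewed costs
#' (gamma-mixed Poisson counts and gamma informal-care hours).
#'
#' @param true_delta_cost Generating incremental healthcare cost over
#'   follow-up, GBP per participant (intervention minus control,
#'   excluding the intervention cost itself).
#' @param true_delta_qaly Generating incremental QALYs over the horizon.
#' @param cost_icc,utility_icc Approximate share of cost / utility
#'   variance at cluster level, in `[0, 1)`.
#' @param abc_baseline Mean and sd of the baseline behaviour score.
#' @param utility_decrement_per_abc_point Latent utility slope per
#'   behaviour-score point; must be <= 0 (worse behaviour, lower
#'   utility).
#' @param missing_fraction Target fraction of post-baseline
#'   participant-timepoint records masked; must be below 0.9.
#' @param death_hazard Per-month death probability.
#' @param informal_care_hours Named vector: `baseline` mean (both arms),
#'   follow-up means by `intervention` / `control`, and `sd` (weekly
#'   hours, gamma distributed among participants with a carer).
#' @param carer_fraction Fraction of participants with an unpaid carer.
#' @param staffing_ratio_range Uniform range for the cluster staffing
#'   ratio covariate.
#' @param utility_intercept Latent utility at behaviour score 0; the
#'   default puts the population mean utility near 0.70.
#' @param utility_sd,participant_sd Occasion-level and participant-level
#'   latent utility standard deviations.
#' @param abc_within_sd,abc_drift_per_month Within-participant
#'   behaviour-score noise and common secular drift.
#' @param rate_dispersion Gamma shape of per-participant contact-rate
#'   multipliers (at most 2 keeps component costs right-skewed).
#' @param total_training_cost,n_staff_trained Staff-training cost model.
#' @param therapist_hourly_rate Band-6 equivalent delivery rate, GBP/h.
#' @param therapist_hours Mean and sd of logged delivery hours per
#'   participant.
#' @param activity_log_coverage Fraction of intervention participants
#'   with an activity log.
#' @param missingness_log_or Named log odds-ratios of masking for
#'   covariate levels (reference levels at 0); the intercept is
#'   calibrated so the realised masking fraction matches
#'   `missing_fraction`.
#' @return A `generative_params` list.
#' @export
generative_params <- function(true_delta_cost = 399,
                              true_delta_qaly = 0.175,
                              cost_icc = 0.05,
                              utility_icc = 0.05,
                              abc_baseline = c(mean = 64, sd = 28),
                              utility_decrement_per_abc_point = -0.002,
                              missing_fraction = 0.35,
                              death_hazard = 0.001,
                              informal_care_hours = c(baseline = 29,
                                                      intervention = 16,
                                                      control = 30, sd = 20),
                              carer_fraction = 0.52,
                              staffing_ratio_range = c(0.5, 1.5),
                              utility_intercept = 0.828,
                              utility_sd = 0.12,
                              participant_sd = 0.08,
                              abc_within_sd = 8,
                              abc_drift_per_month = -0.15,
                              rate_dispersion = 1.5,
                              total_training_cost = 42842,
                              n_staff_trained = 20,
                              therapist_hourly_rate = 44,
                              therapist_hours = c(mean = 27.3, sd = 15),
                              activity_log_coverage = 0.6,
                              missingness_log_or = c(
                                disability_moderate = 0.3,
                                disability_severe = 0.7,
                                accommodation_residential = 0.4,
                                accommodation_supported_living = 0.2,
                                living_with_others = 0.1)) {
  if (missing_fraction < 0 || missing_fraction >= 0.9) {
    stop("missing_fraction must be in [0, 0.9)")
  }
  if (utility_decrement_per_abc_point > 0) {
    stop("utility_decrement_per_abc_point must be <= 0")
  }
  if (cost_icc < 0 || cost_icc >= 1 || utility_icc < 0 || utility_icc >= 1) {
    stop("intraclass correlations must be in [0, 1)")
  }
  if (death_hazard < 0 || death_hazard >= 1) stop("death_hazard must be in [0, 1)")
  structure(as.list(environment()), class = "generative_params")
}

# trapezoidal AUC weight (in years) attached to each assessment timepoint
qaly_weights <- function(timepoints) {
  k <- length(timepoints)
  w <- numeric(k)
  w[1] <- (timepoints[2] - timepoints[1]) / 2
  if (k > 2) {
    w[2:(k - 1)] <- (timepoints[3:k] - timepoints[1:(k - 2)]) / 2
  }
  w[k] <- (timepoints[k] - timepoints[k - 1]) / 2
  w / 12
}

# default per-window contact/count rates by resource category
default_contact_rates <- function() {
  c(gp = 2, practice_nurse = 1, community_nurse = 3, psychiatrist = 1.5,
    psychologist = 1, outpatient = 0.8, a_and_e = 0.4, social_worker = 1.5,
    day_service = 10, medication = 6, police_contact = 0.3,
    court_appearance = 0.05, private_therapy = 0.2)
}

#' Generate a complete synthetic cluster-trial dataset
#'
#' Produces the four participant-level tables the analysis pipeline
#' consumes, before any missingness: participants (covariates, cluster,
#' arm, death), resource use (counts per category per 6-month recall
#' window, including explicit zero rows), health states (EQ-5D-3L
#' responses by proxy carers and by participants themselves, with the
#' behaviour score and the generating latent utility retained for
#' validation), and therapist activity logs. Health states are obtained
#' by mapping a latent utility -- linear in the behaviour score, plus
#' cluster, participant and occasion noise and the arm effect -- to the
#' nearest tariff-valued state. The arm effect on latent utility is
#' `true_delta_qaly` divided by the total post-baseline AUC weight, so
#' the expected incremental QALY equals `true_delta_qaly`; the expected
#' incremental healthcare cost is calibrated to `true_delta_cost` through
#' the psychiatric contact rate.
#'
#' @param design A [trial_design()].
#' @param params A [generative_params()].
#' @param seed Integer seed (defaults to the design's seed).
#' @param unit_costs Unit-cost table used to calibrate the cost contrast.
#' @param tariff Tariff used for nearest-state mapping.
#' @return A `cea_trial` list of tables plus the design/params/seed.
#' @export
generate_trial <- function(design, params = generative_params(),
                           seed = design$seed,
                           unit_costs = read_unit_costs(),
                           tariff = read_tariff()) {
  stopifnot(inherits(design, "trial_design"),
            inherits(params, "generative_params"))
  set.seed(seed)
  tps <- design$timepoints
  k_int <- design$n_clusters_intervention
  k_ctl <- design$n_clusters_control
  k <- k_int + k_ctl
  clusters <- tibble::tibble(
    cluster_id = seq_len(k),
    arm = rep(c("intervention", "control"), c(k_int, k_ctl)),
    staffing_ratio = runif(k, params$staffing_ratio_range[1],
                           params$staffing_ratio_range[2]),
    size = pmax(2, stats::rnbinom(k, mu = design$mean_cluster_size,
                                  size = design$size_dispersion))
  )
  n <- sum(clusters$size)
  cl_of <- rep(clusters$cluster_id, clusters$size)

  abc0 <- rnorm(n, params$abc_baseline["mean"], params$abc_baseline["sd"])
  while (any(abc0 < 15)) { # inclusion criterion: score of 15 or higher
    abc0[abc0 < 15] <- rnorm(sum(abc0 < 15), params$abc_baseline["mean"],
                             params$abc_baseline["sd"])
  }
  death_month <- rep(NA_real_, n)
  if (params$death_hazard > 0) {
    t_death <- rexp(n, rate = -log(1 - params$death_hazard))
    death_month[t_death <= max(tps)] <- t_death[t_death <= max(tps)]
  }
  participants <- tibble::tibble(
    participant_id = seq_len(n),
    cluster_id = cl_of,
    arm = clusters$arm[cl_of],
    disability_level = sample(c("mild", "moderate", "severe"), n, TRUE,
                              prob = c(0.17, 0.43, 0.40)),
    accommodation = sample(c("residential", "supported_living",
                             "independent_floating"), n, TRUE,
                           prob = c(0.43, 0.37, 0.20)),
    living_situation = sample(c("with_family", "alone", "with_others"), n,
                              TRUE, prob = c(0.30, 0.15, 0.55)),
    staffing_ratio = clusters$staffing_ratio[cl_of],
    abc_baseline = abc0,
    has_carer = runif(n) < params$carer_fraction,
    death_month = death_month
  )

  # long grid of alive participant-timepoints
  grid <- tidyr::expand_grid(participant_id = participants$participant_id,
                             timepoint = tps)
  dm <- participants$death_month[grid$participant_id]
  grid <- grid[is.na(dm) | grid$timepoint < dm, ]

  # --- health states -------------------------------------------------
  w_post <- sum(qaly_weights(tps)[-1])
  delta_u <- params$true_delta_qaly / w_post
  v_ind <- params$participant_sd^2 + params$utility_sd^2
  sd_cl_u <- sqrt(params$utility_icc / (1 - params$utility_icc) * v_ind)
  u_cl <- rnorm(k, 0, sd_cl_u)
  u_i <- rnorm(n, 0, params$participant_sd)

  pid <- grid$participant_id
  tp <- grid$timepoint
  abc <- pmax(0, participants$abc_baseline[pid] +
                params$abc_drift_per_month * tp +
                rnorm(nrow(grid), 0, params$abc_within_sd))
  latent <- params$utility_intercept +
    params$utility_decrement_per_abc_point * abc +
    u_cl[participants$cluster_id[pid]] + u_i[pid] +
    rnorm(nrow(grid), 0, params$utility_sd)
  # The nearest-state mapping is a step function with a plateau below
  # full health, which attenuates a latent shift. To make the expected
  # post-mapping utility contrast equal delta_u exactly (the generator's
  # contract), solve for the latent shift whose mapped mean difference
  # hits delta_u on the intervention-arm post-baseline occasions.
  sel <- participants$arm[pid] == "intervention" & tp > 0
  if (delta_u != 0 && any(sel)) {
    gv <- tariff_value_fun(tariff)
    base_mean <- mean(gv(latent[sel]))
    shift <- uniroot(function(dd) mean(gv(latent[sel] + dd)) - base_mean - delta_u,
                     interval = sort(c(0, 3 * delta_u + sign(delta_u) * 0.2)),
                     extendInt = if (delta_u > 0) "upX" else "downX",
                     tol = 1e-6)$root
    latent[sel] <- latent[sel] + shift
  }
  latent_self <- latent + rnorm(nrow(grid), 0, 0.05)
  code_proxy <- nearest_state(latent, tariff)
  code_self <- nearest_state(latent_self, tariff)
  hs_one <- function(code, who, lat) {
    m <- as_state_matrix(code)
    tibble::tibble(
      participant_id = pid, timepoint = tp, respondent = who,
      mobility = m[, 1], self_care = m[, 2], usual_activities = m[, 3],
      pain_discomfort = m[, 4], anxiety_depression = m[, 5],
      abc_score = abc, latent_utility = lat
    )
  }
  health_states <- dplyr::bind_rows(
    hs_one(code_proxy, "proxy_carer", latent),
    hs_one(code_self, "self", latent_self)
  )

  # --- resource use --------------------------------------------------
  rates <- default_contact_rates()
  psych_price <- with(
    unit_costs[unit_costs$category == "psychiatrist", ],
    rate * duration_hours
  )
  n_post <- length(tps) - 1
  delta_rate <- params$true_delta_cost / (n_post * psych_price)
  s_cl <- sqrt(params$cost_icc)
  m_cl <- exp(rnorm(k, 0, s_cl) - s_cl^2 / 2)
  g_i <- rgamma(n, shape = params$rate_dispersion,
                scale = 1 / params$rate_dispersion)
  mult <- m_cl[participants$cluster_id[pid]] * g_i[pid]

  ru_list <- lapply(names(rates), function(cat) {
    lam <- rates[[cat]] * mult
    if (cat == "psychiatrist") {
      bump <- delta_rate * (participants$arm[pid] == "intervention" & tp > 0)
      lam <- pmax(lam + bump, 0.01)
    }
    tibble::tibble(participant_id = pid, timepoint = tp, category = cat,
                   quantity = rpois(length(lam), lam))
  })
  # accommodation: fixed class per participant, 26 weeks per window
  acc_class <- ifelse(
    participants$accommodation == "residential",
    sample(c("residential_1_3bed", "residential_4plusbed"), n, TRUE),
    ifelse(participants$accommodation == "supported_living",
           sample(c("supported_living_24h", "supported_living_lt24h"), n, TRUE),
           "floating_support"))
  ru_acc <- tibble::tibble(participant_id = pid, timepoint = tp,
                           category = acc_class[pid], quantity = 26)
  # informal care: weekly hours, gamma, only for participants with a carer
  ich <- params$informal_care_hours
  mu_ic <- ifelse(tp == 0, ich["baseline"],
                  ifelse(participants$arm[pid] == "intervention",
                         ich["intervention"], ich["control"]))
  shape_ic <- (mu_ic / ich["sd"])^2
  hrs <- rgamma(length(mu_ic), shape = shape_ic, scale = mu_ic / shape_ic)
  hrs[!participants$has_carer[pid]] <- 0
  ru_ic <- tibble::tibble(participant_id = pid, timepoint = tp,
                          category = "informal_care", quantity = hrs)
  resource_use <- dplyr::bind_rows(c(ru_list, list(ru_acc, ru_ic)))

  # --- therapist activity logs --------------------------------------
  int_ids <- participants$participant_id[participants$arm == "intervention"]
  logged <- int_ids[runif(length(int_ids)) < params$activity_log_coverage]
  th <- params$therapist_hours
  shape_h <- (th["mean"] / th["sd"])^2
  therapist_activity <- tibble::tibble(
    participant_id = logged,
    hours = rgamma(length(logged), shape = shape_h,
                   scale = th["mean"] / shape_h)
  )

  structure(list(
    participants = participants,
    resource_use = resource_use,
    health_states = health_states,
    therapist_activity = therapist_activity,
    design = design, params = params, seed = seed
  ), class = "cea_trial")
}

#' Mask records missing-at-random
#'
#' Masks post-baseline participant-timepoint records (both the resource
#' use and the health states of that occasion) with probability given by
#' a logistic model in disability level, accommodation and living
#' situation -- the covariates predictive of missingness -- whose
#' intercept is calibrated by root-finding so the expected masked
#' fraction equals `params$missing_fraction` on this dataset's covariate
#' distribution. Baseline records are never masked, so the mechanism is
#' missing at random given fully observed covariates. With
#' `missing_fraction = 0` the trial is returned unchanged.
#'
#' @param trial A `cea_trial`.
#' @param params Generative parameters (defaults to those in the trial).
#' @param seed Integer seed.
#' @return The trial with masked rows removed and a `missing_index`
#'   table of the masked (participant, timepoint) pairs.
#' @export
apply_missingness <- function(trial, params = trial$params,
                              seed = trial$seed + 1) {
  stopifnot(inherits(trial, "cea_trial"))
  if (params$missing_fraction == 0) return(trial)
  set.seed(seed)
  p <- trial$participants
  occ <- unique(trial$health_states[
    trial$health_states$timepoint > 0, c("participant_id", "timepoint")])
  pi <- match(occ$participant_id, p$participant_id)
  lo <- params$missingness_log_or
  lp <- unname(
    lo["disability_moderate"] * (p$disability_level[pi] == "moderate") +
    lo["disability_severe"] * (p$disability_level[pi] == "severe") +
    lo["accommodation_residential"] * (p$accommodation[pi] == "residential") +
    lo["accommodation_supported_living"] * (p$accommodation[pi] == "supported_living") +
    lo["living_with_others"] * (p$living_situation[pi] == "with_others"))
  alpha <- uniroot(function(a) mean(stats::plogis(a + lp)) -
                     params$missing_fraction, c(-25, 25))$root
  mask <- runif(nrow(occ)) < stats::plogis(alpha + lp)
  idx <- occ[mask, ]
  key <- function(df) paste(df$participant_id, df$timepoint)
  bad <- key(idx)
  trial$resource_use <- trial$resource_use[!(key(trial$resource_use) %in% bad), ]
  trial$health_states <- trial$health_states[!(key(trial$health_states) %in% bad), ]
  trial$missing_index <- tibble::as_tibble(idx)
  trial
}

#' Write / read a synthetic trial as delimited tables
#'
#' Writes the four data tables (plus the masked-record index when
#' present) as CSV files with a JSON manifest recording the design,
#' generative parameters and seed.
#'
#' @param trial A `cea_trial`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("participants", "resource_use", "health_states",
            "therapist_activity")
  if (!is.null(trial$missing_index)) tabs <- c(tabs, "missing_index")
  for (tb in tabs) {
    write.csv(trial[[tb]], file.path(dir, paste0(tb, ".csv")),
              row.names = FALSE)
  }
  manifest <- list(design = unclass(trial$design),
                   params = unclass(trial$params), seed = trial$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_trial
#' @export
read_trial <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  de <- manifest$design
  design <- trial_design(de$n_clusters_intervention, de$n_clusters_control,
                         de$mean_cluster_size, de$size_dispersion,
                         unlist(de$timepoints), de$seed)
  pa <- manifest$params
  params <- do.call(generative_params, lapply(
    pa[names(pa) %in% names(formals(generative_params))],
    function(x) if (is.list(x)) unlist(x) else x))
  rd <- function(f) {
    path <- file.path(dir, paste0(f, ".csv"))
    if (file.exists(path)) tibble::as_tibble(read.csv(path)) else NULL
  }
  out <- list(participants = rd("participants"),
              resource_use = rd("resource_use"),
              health_states = rd("health_states"),
              therapist_activity = rd("therapist_activity"),
              design = design, params = params, seed = manifest$seed)
  mi <- rd("missing_index")
  if (!is.null(mi)) out$missing_index <- mi
  structure(out, class = "cea_trial")
}
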