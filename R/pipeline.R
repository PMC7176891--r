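#' Assemble the wide analysis table from trial tables
#'
#' Costs each participant-timepoint from the resource-use table
#' (excluding the intervention cost, which is added at analysis time),
#' values the requested respondent's health states with the tariff, and
#' reshapes to one row per participant with `cost_<m>` / `util_<m>`
#' columns per assessment month. Occasions with no records are `NA`
#' (missing); occasions at or after a participant's death have cost 0
#' and utility left to the death rule.
#'
#' @param trial A `cea_trial`.
#' @param perspective `"healthcare"` or `"societal"`.
#' @param respondent `"proxy_carer"` (base case) or `"self"`.
#' @param unit_costs,tariff Configuration tables.
#' @return Wide tibble with participant covariates and per-timepoint
#'   cost/utility columns.
#' @export
assemble_analysis <- function(trial,
                              perspective = c("healthcare", "societal"),
                              respondent = c("proxy_carer", "self"),
                              unit_costs = read_unit_costs(),
                              tariff = read_tariff()) {
  perspective <- match.arg(perspective)
  respondent <- match.arg(respondent)
  tps <- trial$design$timepoints
  comp <- cost_resource_use(trial$resource_use, unit_costs)
  tot <- aggregate_perspective(comp, perspective)
  traj <- build_trajectories(trial$health_states, tariff, respondent)
  wide <- trial$participants[, c("participant_id", "cluster_id", "arm",
                                 "disability_level", "accommodation",
                                 "living_situation", "staffing_ratio",
                                 "death_month")]
  for (t in tps) {
    ct <- tot$total[match(paste(wide$participant_id, t),
                          paste(tot$participant_id, tot$timepoint))]
    ut <- traj$utility[match(paste(wide$participant_id, t),
                             paste(traj$participant_id, traj$timepoint))]
    dead <- !is.na(wide$death_month) & t >= wide$death_month
    ct[dead] <- 0
    wide[[paste0("cost_", t)]] <- ct
    wide[[paste0("util_", t)]] <- ut
  }
  attr(wide, "perspective") <- perspective
  attr(wide, "respondent") <- respondent
  wide
}

#' Intervention (training plus delivery) cost per participant
#'
#' Training: total training cost divided by the number of
#' intervention-arm participants (a conservative allocation). Delivery:
#' mean logged therapist hours times the Band-6 hourly rate, with
#' unlogged participants assigned the arm mean.
#'
#' @param trial A `cea_trial`.
#' @param total_training_cost,hourly_rate Override the trial's
#'   generative parameters (useful for real data).
#' @param use_individual_hours Cost logged participants at their own
#'   hours.
#' @return List: `training_per_participant`, `delivery_mean`,
#'   `mean_per_participant`, and `per_participant` tibble
#'   (`participant_id`, `cost`) over the intervention arm.
#' @export
intervention_cost <- function(trial,
                              total_training_cost = trial$params$total_training_cost,
                              hourly_rate = trial$params$therapist_hourly_rate,
                              use_individual_hours = FALSE) {
  int_ids <- trial$participants$participant_id[
    trial$participants$arm == "intervention"]
  training_pp <- cost_training(total_training_cost, length(int_ids))
  deliv <- cost_delivery(trial$therapist_activity, int_ids, hourly_rate,
                         use_individual_hours)
  per <- tibble::tibble(participant_id = deliv$participant_id,
                        cost = training_pp + deliv$delivery_cost)
  list(training_per_participant = training_pp,
       delivery_mean = attr(deliv, "mean_cost"),
       mean_per_participant = training_pp + attr(deliv, "mean_cost"),
       per_participant = per)
}

#' Per-participant QALYs and follow-up costs from a completed dataset
#'
#' Computes, for one (imputed) wide table, each participant's QALYs
#' (trapezoidal AUC with the death rule, discounted after 12 months when
#' requested) and total follow-up cost (timepoint costs after baseline,
#' the 36-month window discounted, plus the intervention cost for
#' intervention-arm participants when supplied -- attached within the
#' first year, so undiscounted).
#'
#' @param wide A completed wide analysis table.
#' @param discount Apply 3.5% annual discounting after 12 months?
#' @param discount_rate,discount_start Discounting specification.
#' @param intervention_costs `NULL`, or the `per_participant` table from
#'   [intervention_cost()].
#' @param horizon Analysis horizon, months (default: last timepoint).
#' @return Analysis frame: `participant_id`, `cluster_id`, `arm`,
#'   `staffing_ratio`, `cost_baseline`, `util_baseline`, `cost_total`,
#'   `qaly`.
#' @export
prepare_analysis <- function(wide, discount = TRUE, discount_rate = 0.035,
                             discount_start = 12,
                             intervention_costs = NULL, horizon = NULL) {
  cols <- analysis_cols(wide)
  tps <- sort(unique(tp_from_cols(cols)))
  horizon <- horizon %||% max(tps)
  rate <- if (discount) discount_rate else 0
  ucols <- tp_cols("util", tps)
  ccols <- tp_cols("cost", tps)
  # discounted AUC is linear in node utilities: weights from unit vectors
  w <- vapply(seq_along(tps), function(k) {
    qaly_auc(tps, as.numeric(seq_along(tps) == k), horizon = horizon,
             discount_rate = rate, discount_start = discount_start)
  }, numeric(1))
  U <- as.matrix(wide[ucols])
  dm <- wide$death_month %||% rep(NA_real_, nrow(wide))
  qaly <- drop(U %*% w)
  for (i in which(!is.na(dm))) {
    keep <- tps < dm[i]
    qaly[i] <- qaly_auc(tps[keep], U[i, keep], death_month = dm[i],
                        horizon = horizon, discount_rate = rate,
                        discount_start = discount_start)
  }
  fu <- tps[tps > 0]
  fac <- discount_factor(fu, rate = rate, start = discount_start)
  cost_total <- drop(as.matrix(wide[tp_cols("cost", fu)]) %*% fac)
  if (!is.null(intervention_costs)) {
    extra <- intervention_costs$cost[
      match(wide$participant_id, intervention_costs$participant_id)]
    extra[is.na(extra)] <- 0
    cost_total <- cost_total + extra
  }
  tibble::tibble(
    participant_id = wide$participant_id,
    cluster_id = wide$cluster_id,
    arm = factor(wide$arm, levels = c("control", "intervention")),
    staffing_ratio = wide$staffing_ratio,
    cost_baseline = wide[[paste0("cost_", tps[1])]],
    util_baseline = wide[[paste0("util_", tps[1])]],
    cost_total = cost_total,
    qaly = qaly
  )
}

#' Full within-trial cost-utility analysis
#'
#' Runs the whole pipeline on a trial: assemble the analysis table,
#' multiply impute missing cost/utility cells, compute per-imputation
#' QALYs and follow-up costs (discounted after 12 months by default),
#' estimate adjusted incremental cost and QALYs by random-intercept
#' regression (pooling point estimates across imputations), draw the
#' paired cluster bootstrap cloud, and derive the decision outputs:
#' bias-corrected intervals, ICER, cost-effectiveness plane and
#' acceptability curve, and the probability cost-effective at the
#' willingness-to-pay threshold.
#'
#' @param trial A `cea_trial` (complete or with missingness applied).
#' @param perspective,respondent Analysis perspective and EQ-5D
#'   respondent role.
#' @param discount Discount costs and QALYs after 12 months at 3.5%?
#' @param m Imputations (`"auto"` = percentage of incomplete
#'   participants).
#' @param impute_method Posterior-draw method for [mice_impute()].
#' @param reps Bootstrap replications per imputation.
#' @param include_intervention Add training + delivery cost to
#'   intervention-arm participants.
#' @param wtp_grid,threshold CEAC grid and decision threshold.
#' @param seed Integer seed governing imputation and bootstrap.
#' @param engine Regression engine for the bootstrap refits.
#' @param unit_costs,tariff Configuration tables.
#' @return A `cea_result`: `summary` (one-row decision record), `ceac`,
#'   `plane`, `draws`, pooled estimates and run metadata.
#' @export
cea_analyse <- function(trial,
                        perspective = c("healthcare", "societal"),
                        respondent = c("proxy_carer", "self"),
                        discount = TRUE, m = "auto",
                        impute_method = c("norm", "pmm"), reps = 200,
                        include_intervention = TRUE,
                        wtp_grid = seq(0, 50000, by = 500),
                        threshold = 30000, seed = 1,
                        engine = c("profile", "lme4"),
                        unit_costs = read_unit_costs(),
                        tariff = read_tariff()) {
  perspective <- match.arg(perspective)
  respondent <- match.arg(respondent)
  engine <- match.arg(engine)
  impute_method <- match.arg(impute_method)
  wide <- assemble_analysis(trial, perspective, respondent, unit_costs, tariff)
  frac <- missing_fraction(wide)
  imps <- mice_impute(wide, m = m, method = impute_method, seed = seed)
  icost <- if (include_intervention) intervention_cost(trial) else NULL
  prepared <- lapply(imps, prepare_analysis, discount = discount,
                     intervention_costs = icost$per_participant)
  fits_c <- lapply(prepared, fit_adjusted_model, outcome = "cost_total",
                   baseline = "cost_baseline", engine = engine)
  fits_q <- lapply(prepared, fit_adjusted_model, outcome = "qaly",
                   baseline = "util_baseline", engine = engine)
  pool_c <- pool_rubin(vapply(fits_c, `[[`, 0, "estimate"),
                       vapply(fits_c, `[[`, 0, "se")^2)
  pool_q <- pool_rubin(vapply(fits_q, `[[`, 0, "estimate"),
                       vapply(fits_q, `[[`, 0, "se")^2)
  draws <- bootstrap_increments(prepared, reps = reps, seed = seed + 1,
                                engine = engine)
  summary_row <- decision_summary(draws, pool_c$estimate, pool_q$estimate,
                                  threshold = threshold, wtp_grid = wtp_grid)
  out <- list(
    summary = summary_row,
    ceac = ceac(draws, wtp_grid),
    plane = ce_plane(draws),
    draws = draws,
    pooled = list(cost = pool_c, qaly = pool_q),
    intervention_cost = icost,
    missing_fraction = frac,
    m = attr(imps, "m"), reps = reps,
    perspective = perspective, respondent = respondent,
    discounted = discount, seed = seed
  )
  class(out) <- "cea_result"
  out
}

#' @export
print.cea_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Within-trial cost-utility analysis (%s perspective%s)\n",
              x$perspective, if (x$discounted) ", discounted" else ""))
  cat(sprintf("  imputations x bootstrap reps: %d x %d = %d draws\n",
              x$m, x$reps, nrow(x$draws)))
  cat(sprintf("  incremental cost:  %0.0f GBP (95%% CI %0.0f to %0.0f)\n",
              s$delta_cost, s$delta_cost_lower, s$delta_cost_upper))
  cat(sprintf("  incremental QALYs: %0.3f (95%% CI %0.3f to %0.3f)\n",
              s$delta_qaly, s$delta_qaly_lower, s$delta_qaly_upper))
  if (s$icer_label == "icer") {
    cat(sprintf("  ICER: %0.0f GBP per QALY\n", s$icer))
  } else {
    cat(sprintf("  ICER: %s\n", s$icer_label))
  }
  cat(sprintf("  P(cost-effective at %0.0f GBP/QALY): %0.2f\n",
              s$wtp_threshold, s$p_cost_effective))
  invisible(x)
}

#' Export decision outputs as CSV files
#'
#' Writes `ceac.csv` (willingness to pay, probability), `plane.csv` (the
#' draw cloud), `draws.csv` (with imputation and replication ids) and
#' `summary.csv` (the one-row decision record) so plots are fully
#' reproducible from text artifacts.
#'
#' @param result A `cea_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cea_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$ceac, file.path(dir, "ceac.csv"), row.names = FALSE)
  write.csv(result$plane$cloud, file.path(dir, "plane.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(result$draws), file.path(dir, "draws.csv"),
            row.names = FALSE)
  write.csv(result$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  invisible(dir)
}
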