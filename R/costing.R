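#' Read a unit-cost configuration table
#'
#' Unit costs are supplied as a delimited table with one row per resource
#' category: `category`, `basis` (how the quantity is priced), `rate`
#' (GBP), `duration_hours` (for hourly-priced contacts), `component` (the
#' cost component the category belongs to) and `price_year`. The packaged
#' default uses 2014/2015 GBP with placeholder rates of realistic
#' magnitude; users substitute their own national unit-cost schedule.
#' Private care categories are priced at the same rate as their public
#' equivalents.
#'
#' Pricing bases: `per_contact_hourly` (quantity x hourly rate x
#' appointment duration), `per_unit` / `per_item` (quantity x rate),
#' `per_week` (weeks of occupancy x weekly rate) and `per_hour_weekly`
#' (hours per week x weeks in the recall window x hourly rate; used for
#' informal care at GBP 24/h).
#'
#' @param path CSV path; defaults to the packaged table.
#' @return Tibble of unit costs.
#' @export
read_unit_costs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "unit_costs.csv", package = "ceaclust")
  }
  uc <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(c("category", "basis", "rate", "duration_hours", "component")
                %in% names(uc)))
  if (any(uc$rate < 0)) stop("unit costs must be non-negative")
  hourly <- uc$basis == "per_contact_hourly"
  if (any(hourly & (is.na(uc$duration_hours) | uc$duration_hours <= 0))) {
    stop("hourly-priced categories need a positive appointment duration")
  }
  uc
}

healthcare_components <- function() {
  c("primary_care", "secondary_care", "social_care", "medication")
}

societal_extra_components <- function() {
  c("accommodation", "informal_care", "criminal_justice", "out_of_pocket")
}

#' Training cost per participant (or per staff member)
#'
#' Total cost of training therapists divided by the number of people it
#' is allocated over: dividing by the intervention-arm participants gives
#' the conservative per-participant training cost; dividing by the number
#' of staff trained gives the cost per therapist.
#'
#' @param total_training_cost Total cost of training, GBP.
#' @param n Number of participants (or staff) to allocate over.
#' @return GBP per head.
#' @export
#' @examples
#' cost_training(42842, 108) # ~397 per participant
#' cost_training(42842, 20)  # ~2142 per staff member trained
cost_training <- function(total_training_cost, n) {
  if (length(n) != 1 || is.na(n) || n < 1) {
    stop("n must be a count of at least 1")
  }
  if (total_training_cost < 0) stop("training cost must be non-negative")
  total_training_cost / n
}

#' Intervention delivery cost per participant from therapist activity logs
#'
#' Mean logged therapist hours are multiplied by the hourly rate of an
#' NHS Agenda for Change Band 6 equivalent. Activity logs typically cover
#' only part of the intervention arm; participants without a log entry
#' are assigned the arm-mean delivery cost (the default, mirroring the
#' use of a single arm mean), or logged participants can keep their
#' individual hours via `use_individual_hours`.
#'
#' @param activity Data frame with `participant_id` and `hours` (total
#'   therapist hours delivering the intervention to that participant).
#' @param participant_ids All intervention-arm participant ids (logged or
#'   not). Defaults to the logged ids only.
#' @param hourly_rate Band-6 equivalent cost per hour, GBP.
#' @param use_individual_hours If `TRUE`, logged participants are costed
#'   at their own hours; unlogged participants still get the arm mean.
#' @return Tibble (`participant_id`, `delivery_cost`), with the arm-mean
#'   cost in attribute `"mean_cost"`.
#' @export
cost_delivery <- function(activity, participant_ids = NULL, hourly_rate,
                          use_individual_hours = FALSE) {
  if (nrow(activity) > 0 && any(activity$hours < 0)) {
    stop("therapist hours must be non-negative")
  }
  if (hourly_rate < 0) stop("hourly rate must be non-negative")
  participant_ids <- participant_ids %||% activity$participant_id
  mean_cost <- if (nrow(activity) == 0) 0 else mean(activity$hours) * hourly_rate
  out <- tibble::tibble(participant_id = participant_ids,
                        delivery_cost = mean_cost)
  if (use_individual_hours && nrow(activity) > 0) {
    idx <- match(out$participant_id, activity$participant_id)
    logged <- !is.na(idx)
    out$delivery_cost[logged] <- activity$hours[idx[logged]] * hourly_rate
  }
  attr(out, "mean_cost") <- mean_cost
  out
}

#' Cost resource-use records with a unit-cost table
#'
#' Multiplies each resource-use quantity by its unit cost according to
#' the category's pricing basis and aggregates to one row per
#' participant-timepoint with one column per cost component. Each
#' timepoint's recall window covers the preceding `weeks_per_window`
#' weeks (26 for the 6-month CSRI recall), which scales weekly-hours
#' quantities such as informal care.
#'
#' @param resource_use Data frame with `participant_id`, `timepoint`,
#'   `category`, `quantity`.
#' @param unit_costs Unit-cost table from [read_unit_costs()].
#' @param weeks_per_window Weeks covered by each recall window.
#' @return Tibble: `participant_id`, `timepoint`, one column per
#'   component (all components always present, 0 where unused).
#' @export
#' @examples
#' uc <- read_unit_costs()
#' ru <- data.frame(participant_id = 1, timepoint = 6,
#'                  category = "informal_care", quantity = 10)
#' cost_resource_use(ru, uc)$informal_care # 10 * 26 * 24 = 6240
cost_resource_use <- function(resource_use, unit_costs = read_unit_costs(),
                              weeks_per_window = 26) {
  components <- c(healthcare_components(), societal_extra_components())
  # only occasions actually present in the records: an absent
  # participant-timepoint is missing data, not zero use
  base <- dplyr::distinct(
    tibble::as_tibble(resource_use[, c("participant_id", "timepoint")]))
  if (nrow(resource_use) == 0) {
    out <- base
    for (cc in components) out[[cc]] <- numeric(nrow(out))
    return(out)
  }
  if (any(resource_use$quantity < 0)) stop("quantities must be non-negative")
  unknown <- setdiff(unique(resource_use$category), unit_costs$category)
  if (length(unknown) > 0) {
    stop("unknown resource categories: ", paste(unknown, collapse = ", "))
  }
  idx <- match(resource_use$category, unit_costs$category)
  basis <- unit_costs$basis[idx]
  rate <- unit_costs$rate[idx]
  dur <- unit_costs$duration_hours[idx]
  cost <- rep(NA_real_, nrow(resource_use))
  q <- resource_use$quantity
  cost[basis == "per_contact_hourly"] <-
    (q * rate * dur)[basis == "per_contact_hourly"]
  cost[basis %in% c("per_unit", "per_item")] <-
    (q * rate)[basis %in% c("per_unit", "per_item")]
  cost[basis == "per_week"] <- (q * rate)[basis == "per_week"]
  cost[basis == "per_hour_weekly"] <-
    (q * weeks_per_window * rate)[basis == "per_hour_weekly"]
  if (anyNA(cost)) stop("unknown pricing basis in unit-cost table")
  long <- tibble::tibble(
    participant_id = resource_use$participant_id,
    timepoint = resource_use$timepoint,
    component = unit_costs$component[idx],
    cost = cost
  )
  agg <- dplyr::summarise(
    dplyr::group_by(long, .data$participant_id, .data$timepoint,
                    .data$component),
    cost = sum(.data$cost), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(agg, names_from = "component",
                             values_from = "cost", values_fill = 0)
  for (cc in setdiff(components, names(wide))) wide[[cc]] <- 0
  out <- dplyr::left_join(base, wide, by = c("participant_id", "timepoint"))
  for (cc in components) out[[cc]][is.na(out[[cc]])] <- 0
  out[, c("participant_id", "timepoint", components)]
}

#' Aggregate component costs into a perspective total
#'
#' The healthcare perspective (NICE base case) sums NHS and personal
#' social services components: primary care, secondary care, social care
#' and medication. The societal perspective additionally includes
#' accommodation, informal (unpaid) care, criminal justice and private /
#' out-of-pocket costs. The intervention cost (staff training plus
#' delivery) is added to intervention-arm participants only, at the
#' timepoint given by `intervention_timepoint` (within the first year, so
#' it is never discounted), when `include_intervention = TRUE`.
#'
#' @param component_costs Output of [cost_resource_use()].
#' @param perspective `"healthcare"` or `"societal"`.
#' @param include_intervention Add the intervention cost?
#' @param arms Data frame (`participant_id`, `arm`) used to gate the
#'   intervention cost; required when `include_intervention = TRUE`.
#' @param intervention_cost_per_participant GBP added to each
#'   intervention-arm participant (training + delivery), or a data frame
#'   (`participant_id`, `cost`) for per-participant values.
#' @param intervention_timepoint Timepoint (months) the intervention cost
#'   is attached to.
#' @return `component_costs` with an `intervention` column and a `total`
#'   column equal to the exact sum of the perspective's components.
#' @export
aggregate_perspective <- function(component_costs,
                                  perspective = c("healthcare", "societal"),
                                  include_intervention = FALSE,
                                  arms = NULL,
                                  intervention_cost_per_participant = 0,
                                  intervention_timepoint = 12) {
  perspective <- match.arg(perspective)
  comps <- if (perspective == "healthcare") healthcare_components() else
    c(healthcare_components(), societal_extra_components())
  out <- component_costs
  out$intervention <- 0
  if (include_intervention) {
    if (is.null(arms)) stop("arms table required to allocate the intervention cost")
    arm <- arms$arm[match(out$participant_id, arms$participant_id)]
    at <- out$timepoint == intervention_timepoint &
      !is.na(arm) & arm == "intervention"
    if (is.data.frame(intervention_cost_per_participant)) {
      pc <- intervention_cost_per_participant
      cost_i <- pc$cost[match(out$participant_id, pc$participant_id)]
      cost_i[is.na(cost_i)] <- 0
      out$intervention[at] <- cost_i[at]
    } else {
      out$intervention[at] <- intervention_cost_per_participant
    }
  }
  out$total <- rowSums(out[, comps, drop = FALSE]) + out$intervention
  attr(out, "perspective") <- perspective
  out
}
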