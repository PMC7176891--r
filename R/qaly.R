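#' Annual discount factors for costs and outcomes
#'
#' NICE reference-case discounting: accruals in the first year (up to
#' `start` months) are undiscounted; an accrual in year \eqn{t \ge 2} is
#' weighted by \eqn{(1 + r)^{-(t - 1)}}. Years are 12-month blocks from
#' baseline, so a value recorded at 36 months falls in year 3 and is
#' weighted by \eqn{(1+r)^{-2}}.
#'
#' @param months Numeric vector of accrual times in months since baseline.
#' @param rate Annual discount rate (default 0.035).
#' @param start Months after which discounting applies (default 12).
#' @return Numeric vector of multiplicative discount factors.
#' @export
#' @examples
#' discount_factor(36) # 1.035^-2
discount_factor <- function(months, rate = 0.035, start = 12) {
  if (rate < 0) stop("discount rate must be non-negative")
  if (start < 0) stop("discount start must be non-negative")
  year <- ceiling(pmax(months, 1e-9) / 12)
  ifelse(months <= start, 1, (1 + rate)^-(year - 1))
}

#' Discount a stream of timepoint accruals
#'
#' @param values Amounts accruing at `months`.
#' @inheritParams discount_factor
#' @return `values` multiplied by the corresponding discount factors.
#' @export
discount_values <- function(values, months, rate = 0.035, start = 12) {
  values * discount_factor(months, rate = rate, start = start)
}

# piecewise-linear utility path including the death rule: utility runs
# linearly between observations, drops linearly from the last observation
# to 0 at death, and stays 0 until the horizon
utility_path <- function(times, utilities, death_month = NA, horizon = NULL) {
  ok <- !is.na(utilities)
  times <- times[ok]; utilities <- utilities[ok]
  o <- order(times)
  times <- times[o]; utilities <- utilities[o]
  if (anyDuplicated(times)) stop("duplicate timepoints in trajectory")
  if (length(times) < 2 && is.na(death_month)) {
    stop("cannot integrate a trajectory with fewer than 2 observed utilities")
  }
  if (length(times) < 1) stop("trajectory has no observed utilities")
  if (!is.na(death_month)) {
    if (death_month <= 0) stop("death_month must be positive")
    if (any(times >= death_month)) {
      stop("observed utilities at or after death_month")
    }
    times <- c(times, death_month)
    utilities <- c(utilities, 0)
  }
  horizon <- horizon %||% max(times)
  if (horizon < max(times)) stop("horizon before last observation")
  if (horizon > max(times)) {
    # after death utility is 0; otherwise the last value is carried forward
    times <- c(times, horizon)
    utilities <- c(utilities, if (is.na(death_month)) utilities[length(utilities)] else 0)
  }
  list(t = times, u = utilities)
}

# trapezoidal integral of a piecewise-linear path over [from, to], months
auc_piecewise <- function(t, u, from, to) {
  if (to <= from) return(0)
  uf <- stats::approx(t, u, xout = c(from, to), rule = 2)$y
  keep <- t > from & t < to
  tt <- c(from, t[keep], to)
  uu <- c(uf[1], u[keep], uf[2])
  sum(diff(tt) * (head(uu, -1) + uu[-1]) / 2)
}

#' QALYs as the area under the utility curve
#'
#' Computes per-participant quality-adjusted life-years by trapezoidal
#' integration of the utility trajectory over the trial horizon, with
#' utilities linearly interpolated between observations. If the
#' participant died, utility is taken as 0 at the date of death, the
#' curve runs as a straight line from the last available measurement to
#' that point, and contributes 0 thereafter. With a positive discount
#' rate the area is sliced into 12-month blocks and each block after the
#' first year is weighted by its annual discount factor.
#'
#' @param times Observation times in months since baseline.
#' @param utilities Utilities at `times` (NAs dropped).
#' @param death_month Month of death, or `NA` if the participant survived
#'   the horizon.
#' @param horizon Analysis horizon in months (default: last observation,
#'   or death).
#' @param discount_rate Annual rate; 0 (default) disables discounting.
#' @param discount_start Months after which discounting applies.
#' @return QALYs (years).
#' @export
#' @examples
#' qaly_auc(c(0, 6, 12, 36), c(0.8, 0.8, 0.8, 0.8)) # 2.4
#' qaly_auc(c(0, 6), c(0.6, 0.8), death_month = 12) # 0.55
qaly_auc <- function(times, utilities, death_month = NA, horizon = NULL,
                     discount_rate = 0, discount_start = 12) {
  if (discount_rate < 0) stop("discount rate must be non-negative")
  path <- utility_path(times, utilities, death_month, horizon)
  hz <- max(path$t)
  if (discount_rate == 0) {
    return(auc_piecewise(path$t, path$u, 0, hz) / 12)
  }
  bounds <- unique(c(seq(0, hz, by = 12), hz))
  total <- 0
  for (i in seq_len(length(bounds) - 1)) {
    lo <- bounds[i]; hi <- bounds[i + 1]
    w <- if (hi <= discount_start) 1 else
      (1 + discount_rate)^-(ceiling(hi / 12) - 1)
    total <- total + w * auc_piecewise(path$t, path$u, lo, hi)
  }
  total / 12
}
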