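#' Incremental cost-effectiveness ratio with dominance labelling
#'
#' Returns delta cost / delta QALY in GBP per QALY, or the decision
#' label for the degenerate quadrants: `"dominant"` when the
#' intervention saves money and gains QALYs (delta cost < 0, delta QALY
#' > 0), `"dominated"` when it costs more and loses QALYs, and
#' `"undefined (delta QALY = 0)"` when the QALY difference is exactly
#' zero. In the two remaining off-diagonal cases (same-sign differences)
#' the ratio itself is reported.
#'
#' @param delta_cost Incremental cost, GBP.
#' @param delta_qaly Incremental QALYs.
#' @return List with `value` (GBP/QALY, `NA` when labelled) and `label`.
#' @export
#' @examples
#' icer(2046, 0.175)   # ~11691 GBP per QALY
#' icer(-500, 0.1)     # dominant
icer <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0) {
    out <- list(value = NA_real_, label = "undefined (delta QALY = 0)")
  } else if (delta_cost < 0 && delta_qaly > 0) {
    out <- list(value = NA_real_, label = "dominant")
  } else if (delta_cost > 0 && delta_qaly < 0) {
    out <- list(value = NA_real_, label = "dominated")
  } else {
    out <- list(value = delta_cost / delta_qaly, label = "icer")
  }
  class(out) <- "icer_estimate"
  out
}

#' @export
print.icer_estimate <- function(x, ...) {
  if (x$label == "icer") {
    cat(sprintf("ICER: %.0f GBP per QALY gained\n", x$value))
  } else {
    cat("ICER:", x$label, "\n")
  }
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value lambda, the probability that the
#' intervention is cost-effective is the fraction of bootstrap draws
#' with positive net monetary benefit, lambda * delta QALY - delta cost
#' > 0 (strict inequality; ties count as not cost-effective). At lambda
#' = 0 this is the probability of cost saving; as lambda grows it tends
#' to the probability of a QALY gain.
#'
#' @param draws A `boot_draws` table (or any data frame with
#'   `delta_cost`, `delta_qaly`).
#' @param wtp_grid Strictly increasing willingness-to-pay grid,
#'   GBP/QALY. The default covers 0--50,000 in 500 steps, spanning the
#'   20,000--30,000 NICE decision band.
#' @return Tibble (`wtp`, `probability`).
#' @export
ceac <- function(draws, wtp_grid = seq(0, 50000, by = 500)) {
  if (nrow(draws) == 0) stop("no bootstrap draws")
  if (length(wtp_grid) == 0) stop("empty willingness-to-pay grid")
  if (any(diff(wtp_grid) <= 0)) stop("wtp grid must be strictly increasing")
  prob <- vapply(wtp_grid, function(l)
    mean(l * draws$delta_qaly - draws$delta_cost > 0), numeric(1))
  tibble::tibble(wtp = wtp_grid, probability = prob)
}

#' Cost-effectiveness plane quadrant summary
#'
#' Partitions the draw cloud into the four quadrants of the
#' cost-effectiveness plane (delta QALY on x, delta cost on y): NE (more
#' effective, more costly), SE (more effective, cost saving --
#' dominant), NW (less effective, more costly -- dominated), SW (less
#' effective, cost saving). Boundary draws are assigned to the
#' non-positive side.
#'
#' @param draws A `boot_draws` table.
#' @return List: `quadrants` tibble (fractions summing to 1) and the
#'   `cloud` itself for plotting / export.
#' @export
ce_plane <- function(draws) {
  if (nrow(draws) == 0) stop("no bootstrap draws")
  qpos <- draws$delta_qaly > 0
  cpos <- draws$delta_cost > 0
  quadrants <- tibble::tibble(
    quadrant = c("NE", "SE", "NW", "SW"),
    description = c("more QALYs, higher cost", "more QALYs, cost saving",
                    "fewer QALYs, higher cost", "fewer QALYs, cost saving"),
    fraction = c(mean(qpos & cpos), mean(qpos & !cpos),
                 mean(!qpos & cpos), mean(!qpos & !cpos))
  )
  list(quadrants = quadrants,
       cloud = tibble::tibble(delta_cost = draws$delta_cost,
                              delta_qaly = draws$delta_qaly))
}

#' One-row decision summary at a willingness-to-pay threshold
#'
#' Extracts the machine-readable record a reimbursement decision needs:
#' adjusted incremental cost and QALYs with bias-corrected bootstrap
#' intervals, the ICER (or dominance label), the probability
#' cost-effective at the stated threshold (which must lie on the CEAC
#' grid), and mean net monetary benefit at the threshold.
#'
#' @param draws A `boot_draws` table.
#' @param point_delta_cost,point_delta_qaly Pooled point estimates.
#' @param threshold Willingness to pay, GBP/QALY (default 30,000, the
#'   NICE upper decision threshold).
#' @param wtp_grid Grid used for the CEAC; must contain `threshold`.
#' @param level Confidence level for the intervals.
#' @return One-row tibble.
#' @export
decision_summary <- function(draws, point_delta_cost, point_delta_qaly,
                             threshold = 30000,
                             wtp_grid = seq(0, 50000, by = 500),
                             level = 0.95) {
  if (!threshold %in% wtp_grid) {
    stop("threshold must be a point on the willingness-to-pay grid")
  }
  curve <- ceac(draws, wtp_grid)
  ci_c <- bc_interval(draws$delta_cost, point_delta_cost, level)
  ci_q <- bc_interval(draws$delta_qaly, point_delta_qaly, level)
  ic <- icer(point_delta_cost, point_delta_qaly)
  nmb <- threshold * draws$delta_qaly - draws$delta_cost
  nmb_point <- threshold * point_delta_qaly - point_delta_cost
  ci_n <- bc_interval(nmb, nmb_point, level)
  tibble::tibble(
    delta_cost = point_delta_cost,
    delta_cost_lower = ci_c["lower"], delta_cost_upper = ci_c["upper"],
    delta_qaly = point_delta_qaly,
    delta_qaly_lower = ci_q["lower"], delta_qaly_upper = ci_q["upper"],
    icer = ic$value, icer_label = ic$label,
    wtp_threshold = threshold,
    p_cost_effective = curve$probability[curve$wtp == threshold],
    nmb = nmb_point, nmb_lower = ci_n["lower"], nmb_upper = ci_n["upper"]
  )
}
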