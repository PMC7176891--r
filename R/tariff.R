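#' EQ-5D-3L tariff coefficients
#'
#' Reads a value-set coefficient table that converts a five-digit,
#' three-level EQ-5D health state into a utility. The default packaged
#' value set is the UK time-trade-off (MVH) tariff: utility is 1 minus a
#' constant decrement (if any dimension is above level 1), minus per-
#' dimension decrements for levels 2 and 3, minus an "N3" decrement if any
#' dimension is at level 3. Other national value sets of the same additive
#' form can be supplied as a file with columns `term`, `level`,
#' `decrement`.
#'
#' @param path Path to a coefficient CSV. Defaults to the packaged UK TTO
#'   value set.
#' @return A `tariff` object (list with `constant`, `n3` and a 2x5 matrix
#'   of level-2/level-3 decrements, one column per dimension).
#' @export
#' @examples
#' tt <- read_tariff()
#' value_state(c(1, 1, 1, 1, 1), tt) # 1
read_tariff <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tariff_uk_tto.csv", package = "ceaclust")
  }
  tab <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("term", "level", "decrement") %in% names(tab)))
  if (any(tab$decrement < 0)) {
    stop("tariff decrements must be non-negative")
  }
  dims <- eq5d_dimensions()
  dec <- matrix(NA_real_, nrow = 2, ncol = 5,
                dimnames = list(c("2", "3"), dims))
  for (d in dims) {
    for (lv in c("2", "3")) {
      row <- tab$term == d & tab$level == lv
      if (sum(row) != 1) stop("tariff file must have one row per dimension-level")
      dec[lv, d] <- tab$decrement[row]
    }
  }
  out <- list(
    constant = tab$decrement[tab$term == "constant"][1],
    n3 = tab$decrement[tab$term == "n3"][1],
    decrements = dec
  )
  if (is.na(out$constant) || is.na(out$n3)) {
    stop("tariff file must contain 'constant' and 'n3' terms")
  }
  class(out) <- "tariff"
  out
}

eq5d_dimensions <- function() {
  c("mobility", "self_care", "usual_activities",
    "pain_discomfort", "anxiety_depression")
}

#' Value EQ-5D-3L health states
#'
#' Applies the additive tariff formula to one or more five-dimension,
#' three-level health states. Full health (11111) is valued at exactly 1;
#' the UK TTO worst state (33333) at -0.594.
#'
#' @param state Either a length-5 vector of levels (each in 1:3), a matrix
#'   with 5 columns, or a character vector of 5-digit codes like "21321".
#' @param tariff A `tariff` object from [read_tariff()].
#' @return Numeric vector of utilities.
#' @export
value_state <- function(state, tariff = read_tariff()) {
  m <- as_state_matrix(state)
  if (any(is.na(m)) || any(m < 1) || any(m > 3) || any(m != floor(m))) {
    stop("health-state levels must be integers in {1, 2, 3}")
  }
  l2 <- tariff$decrements["2", ]
  l3 <- tariff$decrements["3", ]
  any_above_1 <- rowSums(m > 1) > 0
  any_3 <- rowSums(m == 3) > 0
  dim_dec <- (m == 2) %*% l2 + (m == 3) %*% l3
  unname(drop(1 - tariff$constant * any_above_1 - dim_dec - tariff$n3 * any_3))
}

as_state_matrix <- function(state) {
  if (is.character(state)) {
    if (any(nchar(state) != 5)) stop("state codes must have 5 digits")
    m <- t(vapply(strsplit(state, ""),
                  function(x) as.numeric(x), numeric(5)))
  } else if (is.matrix(state) || is.data.frame(state)) {
    m <- as.matrix(state)
    if (ncol(m) != 5) stop("state matrix must have 5 columns")
  } else {
    if (length(state) != 5) stop("a single state must have 5 levels")
    m <- matrix(as.numeric(state), nrow = 1)
  }
  colnames(m) <- eq5d_dimensions()
  m
}

#' Enumerate all 243 EQ-5D-3L states with their tariff values
#'
#' @param tariff A `tariff` object.
#' @return Tibble with the five dimension levels, the 5-digit `code` and
#'   the tariff `value`, one row per state.
#' @export
all_states <- function(tariff = read_tariff()) {
  g <- expand.grid(
    mobility = 1:3, self_care = 1:3, usual_activities = 1:3,
    pain_discomfort = 1:3, anxiety_depression = 1:3
  )
  # lexicographic order of the 5-digit code
  g <- g[order(g$mobility, g$self_care, g$usual_activities,
               g$pain_discomfort, g$anxiety_depression), ]
  g$code <- paste0(g$mobility, g$self_care, g$usual_activities,
                   g$pain_discomfort, g$anxiety_depression)
  g$value <- value_state(g[, 1:5], tariff)
  tibble::as_tibble(g)
}

#' Map latent utilities to the nearest valid EQ-5D-3L state
#'
#' Used by the synthetic-data generator: a continuous latent utility is
#' converted to the 3-level state whose tariff value is closest; ties are
#' broken toward the lexicographically smaller 5-digit code, so the
#' mapping is deterministic.
#'
#' @param u Numeric vector of latent utilities (clamped to the tariff
#'   range).
#' @param tariff A `tariff` object.
#' @return Character vector of 5-digit state codes.
#' @export
nearest_state <- function(u, tariff = read_tariff()) {
  st <- all_states(tariff)
  # among equal-valued states keep the lexicographically smallest code
  st <- st[order(st$value, st$code), ]
  st <- st[!duplicated(st$value), ]
  vals <- st$value # ascending
  u <- pmin(pmax(u, min(vals)), max(vals))
  idx <- findInterval(u, vals, all.inside = TRUE)
  lo <- vals[idx]; hi <- vals[idx + 1]
  d_lo <- u - lo; d_hi <- hi - u
  # tie (equidistant): the lower-valued state is the lexicographically
  # larger code only by accident; resolve ties by comparing codes
  pick_hi <- d_hi < d_lo |
    (d_hi == d_lo & st$code[idx + 1] < st$code[idx])
  st$code[idx + as.integer(pick_hi)]
}

# fast latent-utility -> nearest tariff value lookup (value only, no code)
tariff_value_fun <- function(tariff) {
  vals <- sort(unique(all_states(tariff)$value))
  function(u) {
    u <- pmin(pmax(u, vals[1]), vals[length(vals)])
    idx <- findInterval(u, vals, all.inside = TRUE)
    lo <- vals[idx]; hi <- vals[idx + 1]
    ifelse(hi - u < u - lo, hi, lo)
  }
}

#' Assemble per-participant utility trajectories from health-state tables
#'
#' Filters a long health-state table to one respondent role (proxy carer
#' responses for the base-case analysis, self responses for sensitivity
#' analysis), values every state with the tariff, and returns one row per
#' participant-timepoint. Missing timepoints are simply absent; they are
#' handled by multiple imputation downstream, not here.
#'
#' @param health_states Data frame with columns `participant_id`,
#'   `timepoint`, `respondent` and the five dimension columns.
#' @param tariff A `tariff` object.
#' @param respondent Which respondent role to keep: `"proxy_carer"`
#'   (default, the base case) or `"self"`.
#' @return Tibble with `participant_id`, `timepoint`, `utility`.
#' @export
build_trajectories <- function(health_states, tariff = read_tariff(),
                               respondent = c("proxy_carer", "self")) {
  respondent <- match.arg(respondent)
  hs <- health_states[health_states$respondent == respondent, , drop = FALSE]
  if (nrow(hs) == 0) stop("no responses for respondent role '", respondent, "'")
  key <- paste(hs$participant_id, hs$timepoint, hs$respondent)
  if (anyDuplicated(key)) {
    stop("duplicate (participant, timepoint, respondent) rows in health-state table")
  }
  tibble::tibble(
    participant_id = hs$participant_id,
    timepoint = hs$timepoint,
    utility = value_state(hs[, eq5d_dimensions()], tariff)
  )
}
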