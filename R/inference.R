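#' Exact profiled-REML fit of a single-random-intercept linear model
#'
#' Fits \eqn{y = X\beta + b_{cluster} + e} with one random intercept per
#' cluster by profiling the REML criterion over the variance ratio
#' \eqn{\lambda = \tau^2/\sigma^2} (one-dimensional optimisation with
#' cluster-wise Woodbury identities, so each criterion evaluation is
#' O(n p)). The boundary \eqn{\lambda = 0} is ordinary least squares,
#' which is returned when the REML criterion prefers it -- the same
#' answer lme4 gives at a singular fit. Used as the fast engine for the
#' thousands of refits in the bootstrap; agrees with [lme4::lmer()] to
#' numerical precision.
#'
#' @param y Response vector.
#' @param X Design matrix (including intercept).
#' @param cluster Cluster identifiers.
#' @return List: `beta`, `se`, `sigma2`, `tau2`, `lambda`, `ols`
#'   (logical: boundary fit).
#' @export
lmm_ri <- function(y, X, cluster) {
  cl <- match(cluster, unique(cluster))
  n <- length(y); p <- ncol(X)
  nj <- tabulate(cl)
  Sx <- rowsum(X, cl); Sy <- drop(rowsum(y, cl))
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y * y)
  crit <- function(lambda) {
    cj <- lambda / (1 + lambda * nj)
    A <- XtX - crossprod(Sx * sqrt(cj))
    u <- Xty - crossprod(Sx, cj * Sy)
    R <- chol(A)
    beta <- backsolve(R, backsolve(R, u, transpose = TRUE))
    rss <- yty - sum(cj * Sy^2) - sum(u * beta)
    (n - p) * log(rss) + sum(log1p(lambda * nj)) + 2 * sum(log(diag(R)))
  }
  opt <- optimize(function(l) crit(exp(l)), c(-12, 8), tol = 1e-8)
  lam <- exp(opt$minimum)
  if (crit(1e-10) <= opt$objective) lam <- 0
  cj <- lam / (1 + lam * nj)
  A <- XtX - crossprod(Sx * sqrt(cj))
  u <- Xty - crossprod(Sx, cj * Sy)
  Ainv <- chol2inv(chol(A))
  beta <- drop(Ainv %*% u)
  rss <- yty - sum(cj * Sy^2) - sum(u * beta)
  sigma2 <- rss / (n - p)
  list(beta = setNames(beta, colnames(X)),
       se = setNames(sqrt(sigma2 * diag(Ainv)), colnames(X)),
       sigma2 = sigma2, tau2 = sigma2 * lam, lambda = lam, ols = lam == 0)
}

adjusted_formula <- function(outcome, baseline, covariates, treatment) {
  as.formula(paste(outcome, "~", paste(c(treatment, baseline, covariates),
                                       collapse = " + ")))
}

#' Adjusted incremental cost / QALY from a random-intercept regression
#'
#' Regresses the outcome (total follow-up cost or QALYs) on the
#' treatment indicator, adjusting for the baseline value of the outcome
#' (regression-to-the-mean control, always included) and cluster-level
#' covariates such as the staffing ratio, with a random intercept per
#' cluster. The treatment coefficient is the adjusted incremental value.
#' With `engine = "lme4"` a singular random-effect fit falls back to
#' fixed-effects OLS with a warning; `engine = "profile"` uses the exact
#' profiled-REML solver ([lmm_ri()]), which handles the boundary
#' natively.
#'
#' @param data Analysis frame from [prepare_analysis()] (or any frame
#'   with the named columns).
#' @param outcome,baseline Outcome and baseline-covariate column names.
#' @param covariates Additional covariate columns.
#' @param treatment Treatment column (factor, reference level first).
#' @param cluster Cluster id column.
#' @param engine `"lme4"` or `"profile"`.
#' @return `adjusted_fit` list: `estimate` (treatment beta), `se`,
#'   `engine`, `singular`, and the underlying `fit`.
#' @export
fit_adjusted_model <- function(data, outcome, baseline,
                               covariates = "staffing_ratio",
                               treatment = "arm", cluster = "cluster_id",
                               engine = c("lme4", "profile")) {
  engine <- match.arg(engine)
  if (!is.factor(data[[treatment]])) {
    data[[treatment]] <- factor(data[[treatment]],
                                levels = c("control", "intervention"))
  }
  if (length(unique(data[[cluster]][data[[treatment]] == levels(data[[treatment]])[1]])) < 2 ||
      length(unique(data[[cluster]][data[[treatment]] == levels(data[[treatment]])[2]])) < 2) {
    stop("need at least 2 clusters per arm")
  }
  ff <- adjusted_formula(outcome, baseline, covariates, treatment)
  beta_name <- paste0(treatment, levels(data[[treatment]])[2])
  if (engine == "profile") {
    X <- model.matrix(ff[-2], data = data)
    fit <- lmm_ri(data[[outcome]], X, data[[cluster]])
    out <- list(estimate = unname(fit$beta[beta_name]),
                se = unname(fit$se[beta_name]),
                engine = "profile", singular = fit$ols, fit = fit)
  } else {
    mf <- as.formula(paste(deparse(ff), "+ (1 |", cluster, ")"))
    fit <- suppressMessages(lme4::lmer(
      mf, data = data, REML = TRUE,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore")))
    singular <- lme4::isSingular(fit)
    if (singular) {
      warning("singular random-effect fit; falling back to fixed-effects OLS")
      fit <- lm(ff, data = data)
      out <- list(estimate = unname(coef(fit)[beta_name]),
                  se = unname(sqrt(diag(vcov(fit)))[beta_name]),
                  engine = "lme4/ols-fallback", singular = TRUE, fit = fit)
    } else {
      out <- list(estimate = unname(lme4::fixef(fit)[beta_name]),
                  se = unname(sqrt(diag(as.matrix(vcov(fit))))[beta_name]),
                  engine = "lme4", singular = FALSE, fit = fit)
    }
  }
  class(out) <- "adjusted_fit"
  out
}

#' @export
print.adjusted_fit <- function(x, ...) {
  cat(sprintf("adjusted treatment effect: %.4f (se %.4f, engine %s%s)\n",
              x$estimate, x$se, x$engine,
              if (x$singular) ", singular/OLS" else ""))
  invisible(x)
}

#' Paired bootstrap draws of incremental cost and QALYs across imputations
#'
#' For each imputed dataset, whole clusters are resampled with
#' replacement within arm (respecting the cluster-randomised design;
#' resampled copies are relabelled as distinct pseudo-clusters) and the
#' adjusted cost and QALY regressions are refitted on the *same*
#' resample, so each draw is a (delta cost, delta QALY) pair carrying
#' the cost-QALY correlation. Draws are pooled across imputations into a
#' single cloud of `length(prepared) * reps` pairs: 35 imputations at
#' 200 replications each give 7000 draws. Participant-level resampling
#' and the identity resample (`"none"`, giving the point-estimate pair)
#' are available for comparison.
#'
#' @param prepared A list of analysis frames (one per imputation) from
#'   [prepare_analysis()], or a single frame.
#' @param reps Bootstrap replications per imputation.
#' @param seed Integer seed.
#' @param resample `"cluster"` (default), `"participant"` or `"none"`.
#' @param engine `"profile"` (fast exact REML) or `"lme4"`.
#' @param covariates Cluster-level covariates for both regressions.
#' @param variance_correction With few clusters the nonparametric
#'   bootstrap understates sampling variance: resampling G clusters with
#'   replacement gives a bootstrap variance of the arm mean that is
#'   (G-1)/G of the true one. When `TRUE` (default, cluster resampling
#'   only) each imputation's draw deviations around its point-estimate
#'   pair are rescaled by the corresponding factor, computed from the
#'   two arms' cluster counts.
#' @return `boot_draws` tibble (`imputation`, `rep`, `delta_cost`,
#'   `delta_qaly`) with draw-count metadata in attributes.
#' @export
bootstrap_increments <- function(prepared, reps = 200, seed = 1,
                                 resample = c("cluster", "participant", "none"),
                                 engine = c("profile", "lme4"),
                                 covariates = "staffing_ratio",
                                 variance_correction = TRUE) {
  resample <- match.arg(resample)
  engine <- match.arg(engine)
  if (is.data.frame(prepared)) prepared <- list(prepared)
  if (length(prepared) < 1) stop("need at least one imputed dataset")
  set.seed(seed)
  res <- vector("list", length(prepared))
  for (i in seq_along(prepared)) {
    d <- prepared[[i]]
    d$arm <- factor(d$arm, levels = c("control", "intervention"))
    Xc <- model.matrix(adjusted_formula("cost_total", "cost_baseline",
                                        covariates, "arm")[-2], data = d)
    Xq <- model.matrix(adjusted_formula("qaly", "util_baseline",
                                        covariates, "arm")[-2], data = d)
    yc <- d$cost_total; yq <- d$qaly
    cl <- d$cluster_id
    arm_of_cluster <- tapply(as.character(d$arm), cl, function(a) a[1])
    cl_ids <- names(arm_of_cluster)
    rows_of <- split(seq_len(nrow(d)), cl)
    int_cl <- cl_ids[arm_of_cluster == "intervention"]
    ctl_cl <- cl_ids[arm_of_cluster == "control"]
    dc <- dq <- numeric(reps)
    for (r in seq_len(reps)) {
      for (attempt in seq_len(100)) {
        if (resample == "cluster") {
          picked <- c(sample(int_cl, length(int_cl), replace = TRUE),
                      sample(ctl_cl, length(ctl_cl), replace = TRUE))
          idx <- unlist(rows_of[picked], use.names = FALSE)
          pseudo <- rep(seq_along(picked),
                        lengths(rows_of[picked]))
        } else if (resample == "participant") {
          idx <- unlist(lapply(split(seq_len(nrow(d)), d$arm), function(ii)
            sample(ii, length(ii), replace = TRUE)), use.names = FALSE)
          pseudo <- cl[idx]
        } else {
          idx <- seq_len(nrow(d)); pseudo <- cl
        }
        arm01 <- Xc[idx, "armintervention"]
        ok <- length(unique(pseudo[arm01 == 1])) >= 2 &&
          length(unique(pseudo[arm01 == 0])) >= 2
        if (ok) break
        if (attempt == 100) stop("resampling produced < 2 clusters in an arm 100 times")
      }
      if (engine == "profile") {
        fc <- lmm_ri(yc[idx], Xc[idx, , drop = FALSE], pseudo)
        fq <- lmm_ri(yq[idx], Xq[idx, , drop = FALSE], pseudo)
        dc[r] <- fc$beta["armintervention"]
        dq[r] <- fq$beta["armintervention"]
      } else {
        db <- d[idx, ]; db$.pseudo <- pseudo
        dc[r] <- fit_adjusted_model(db, "cost_total", "cost_baseline",
                                    covariates, cluster = ".pseudo",
                                    engine = "lme4")$estimate
        dq[r] <- fit_adjusted_model(db, "qaly", "util_baseline",
                                    covariates, cluster = ".pseudo",
                                    engine = "lme4")$estimate
      }
    }
    if (variance_correction && resample == "cluster") {
      g1 <- length(int_cl); g2 <- length(ctl_cl)
      infl <- sqrt(2 / ((g1 - 1) / g1 + (g2 - 1) / g2))
      fc0 <- lmm_ri(yc, Xc, cl)$beta["armintervention"]
      fq0 <- lmm_ri(yq, Xq, cl)$beta["armintervention"]
      dc <- fc0 + infl * (dc - fc0)
      dq <- fq0 + infl * (dq - fq0)
    }
    res[[i]] <- tibble::tibble(imputation = i, rep = seq_len(reps),
                               delta_cost = dc, delta_qaly = dq)
  }
  out <- dplyr::bind_rows(res)
  attr(out, "n_imputations") <- length(prepared)
  attr(out, "reps_per_imputation") <- reps
  attr(out, "method") <- "bias_corrected_percentile"
  attr(out, "seed") <- seed
  attr(out, "engine") <- engine
  class(out) <- c("boot_draws", class(out))
  out
}

#' Bias-corrected percentile bootstrap interval
#'
#' The bias-correction constant is \eqn{z_0 = \Phi^{-1}} of the fraction
#' of draws below the point estimate; the interval endpoints are the
#' draw quantiles at \eqn{\Phi(2 z_0 \pm z_{\alpha/2})}. With draws
#' symmetric about the point estimate this reduces to the plain
#' percentile interval.
#'
#' @param draws Numeric vector of bootstrap draws (at least 100).
#' @param point The point estimate the draws surround.
#' @param level Confidence level.
#' @return Named vector `c(lower, upper)`.
#' @export
bc_interval <- function(draws, point, level = 0.95) {
  b <- length(draws)
  if (b < 100) stop("need at least 100 draws for a bootstrap interval")
  if (length(unique(draws)) == 1) {
    warning("all bootstrap draws identical; degenerate interval")
    return(c(lower = draws[1], upper = draws[1]))
  }
  frac <- mean(draws < point)
  frac <- min(max(frac, 1 / (b + 1)), b / (b + 1))
  z0 <- qnorm(frac)
  zq <- qnorm(c((1 - level) / 2, 1 - (1 - level) / 2))
  probs <- pnorm(2 * z0 + zq)
  out <- unname(quantile(draws, probs))
  c(lower = out[1], upper = out[2])
}

#' Responsiveness of proxy-reported utility to the behaviour score
#'
#' Multilevel model of utility at each timepoint on the concurrent
#' behaviour (ABC-C-like) score, adjusting for disability level,
#' accommodation and living situation, with random intercepts for
#' service (cluster) and participant. The slope estimates the utility
#' change per behaviour-score point; a significantly negative slope
#' indicates the proxy-completed instrument responds to changes in
#' challenging behaviour.
#'
#' @param panel Long data frame with `utility`, `abc_score`, the
#'   covariates, `cluster_id` and `participant_id`.
#' @param covariates Adjustment covariates.
#' @param level Confidence level for the Wald interval.
#' @return List: `slope`, `se`, `ci` (length 2), `fit`.
#' @export
responsiveness_model <- function(panel,
                                 covariates = c("disability_level",
                                                "accommodation",
                                                "living_situation"),
                                 level = 0.95) {
  wv <- tapply(panel$abc_score, panel$participant_id, function(x)
    if (length(x) > 1) var(x) else 0)
  if (all(wv == 0, na.rm = TRUE)) {
    stop("no within-participant variation in the behaviour score")
  }
  covariates <- intersect(covariates, names(panel))
  ff <- as.formula(paste(
    "utility ~ abc_score",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else "",
    "+ (1 | cluster_id) + (1 | participant_id)"))
  fit <- suppressMessages(lme4::lmer(
    ff, data = panel, REML = TRUE,
    control = lme4::lmerControl(calc.derivs = FALSE,
                                check.conv.singular = "ignore")))
  est <- lme4::fixef(fit)["abc_score"]
  se <- sqrt(diag(as.matrix(vcov(fit))))["abc_score"]
  z <- qnorm(1 - (1 - level) / 2)
  list(slope = unname(est), se = unname(se),
       ci = unname(c(est - z * se, est + z * se)), fit = fit)
}
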