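#' Cox proportional-hazards fit for risk-weight seeding
#'
#' Fits the Cox partial likelihood (Breslow tie handling) of the risk-event
#' time on the supplied covariates and returns the coefficient table in the
#' shape the weight-seeding step consumes: log hazard, standard error,
#' hazard ratio with 95% CI, and z statistic per covariate. Constant
#' columns are dropped before fitting.
#'
#' @param time Positive follow-up / event times (days).
#' @param event Binary event indicator (1 = risk event, 0 = censored).
#' @param X Numeric covariate matrix or data.frame (one column per factor).
#' @param tol,max_iter Convergence controls passed to the partial-likelihood
#'   maximizer.
#' @return A \code{cox_model}: data.frame with rownames = covariates and
#'   columns \code{beta}, \code{se}, \code{hr}, \code{ci_low},
#'   \code{ci_high}, \code{z}; the fitted \code{survival::coxph} object is
#'   attached as attribute \code{"fit"}.
#' @export
fit_cox <- function(time, event, X, tol = 1e-9, max_iter = 50L) {
  X <- as.data.frame(X)
  if (length(time) != nrow(X) || length(event) != nrow(X))
    stop("ahprisk_cox_error: time, event and X must have matching lengths")
  if (any(time <= 0))
    stop("ahprisk_cox_error: all times must be positive")
  if (!all(event %in% c(0, 1)))
    stop("ahprisk_cox_error: event must be binary")
  keep <- vapply(X, function(col) stats::var(as.numeric(col)) > 0, logical(1))
  if (!any(keep))
    stop("ahprisk_cox_error: no non-constant covariates")
  X <- X[, keep, drop = FALSE]
  d <- X
  d$.time <- time
  d$.event <- event
  form <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(X)), collapse = " + ")))
  fit <- survival::coxph(
    form, data = d, ties = "breslow",
    control = survival::coxph.control(eps = tol, iter.max = max_iter))
  if (any(is.na(stats::coef(fit))))
    stop(sprintf(
      "ahprisk_cox_error: fit produced NA coefficients (last iterate: %s); check for separation or collinearity",
      paste(signif(stats::coef(fit), 4), collapse = ", ")))
  b <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  out <- data.frame(beta = b, se = se, hr = exp(b),
                    ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
                    z = b / se)
  attr(out, "fit") <- fit
  class(out) <- c("cox_model", "data.frame")
  out
}

#' @method print cox_model
#' @export
print.cox_model <- function(x, digits = 3, ...) {
  cat("Cox proportional-hazards coefficient table (Breslow ties)\n")
  print.data.frame(round(as.data.frame(x), digits))
  invisible(x)
}

#' Seed AHP element weights from Cox coefficients
#'
#' Converts fitted log-hazard coefficients into a leaf weight vector for
#' \code{\link{set_hierarchy_weights}}: the magnitude |beta| of each
#' requested factor, normalized to sum 1, so protective and harmful effects
#' contribute symmetrically to factor importance. Factors missing from the
#' model are an error; an all-zero coefficient set degrades to equal
#' weights with a warning.
#'
#' @param m A \code{cox_model}.
#' @param factors Character vector of leaf factor names; defaults to all
#'   fitted covariates.
#' @param significance_filter If \code{TRUE}, factors with |z| < 1.96 get
#'   zero seed weight before normalization (off by default).
#' @return Named weight vector summing to 1.
#' @export
cox_weight_seed <- function(m, factors = rownames(m),
                            significance_filter = FALSE) {
  missing <- setdiff(factors, rownames(m))
  if (length(missing))
    stop(sprintf("ahprisk_cox_error: no fitted coefficient for: %s",
                 paste(missing, collapse = ", ")))
  b <- abs(m[factors, "beta"])
  if (significance_filter) b[abs(m[factors, "z"]) < 1.96] <- 0
  if (all(b == 0)) {
    warning("all coefficients zero; falling back to equal weights")
    b <- rep(1, length(factors))
  }
  stats::setNames(b / sum(b), factors)
}

#' Age-period-cohort mixed model
#'
#' Fits the age-period-cohort decomposition of event rates on an
#' age-group x period grid: a Poisson model for cell event counts with
#' log person-year exposure offset, age and period as fixed effects under
#' sum-to-zero contrasts, and the cohort (period index minus age index) as
#' a random intercept. The random cohort axis breaks the exact linear
#' dependence age + cohort = period that makes the three effects otherwise
#' unidentifiable.
#'
#' @param cells \code{data.frame} with \code{age_group}, \code{period},
#'   \code{events}, \code{exposure} (and optionally \code{cohort}; derived
#'   if absent). See \code{\link{apc_grid}}.
#' @return An \code{apc_model}: list with \code{age_effects},
#'   \code{period_effects} (named, sum-to-zero), \code{cohort_effects}
#'   (conditional modes), \code{cohort_variance}, \code{intercept} and the
#'   underlying \code{lme4} fit.
#' @export
fit_apc <- function(cells) {
  need <- c("age_group", "period", "events", "exposure")
  if (!all(need %in% names(cells)))
    stop("ahprisk_apc_error: cells need age_group, period, events, exposure")
  if (length(unique(cells$period)) < 2L)
    stop("ahprisk_apc_error: degenerate grid; at least 2 periods required")
  if (length(unique(cells$age_group)) < 2L)
    stop("ahprisk_apc_error: degenerate grid; at least 2 age groups required")
  if (is.null(cells$cohort)) cells$cohort <- cells$period - cells$age_group
  cells$age_f <- factor(cells$age_group)
  cells$period_f <- factor(cells$period)
  cells$cohort_f <- factor(cells$cohort)
  fit <- lme4::glmer(
    events ~ age_f + period_f + (1 | cohort_f),
    data = cells, family = stats::poisson(),
    offset = log(cells$exposure),
    contrasts = list(age_f = stats::contr.sum, period_f = stats::contr.sum),
    control = lme4::glmerControl(check.conv.singular = "ignore"))
  fe <- lme4::fixef(fit)
  a_lev <- levels(cells$age_f)
  p_lev <- levels(cells$period_f)
  a_idx <- grep("^age_f", names(fe))
  p_idx <- grep("^period_f", names(fe))
  age_eff <- c(fe[a_idx], -sum(fe[a_idx]))
  names(age_eff) <- a_lev
  per_eff <- c(fe[p_idx], -sum(fe[p_idx]))
  names(per_eff) <- p_lev
  re <- lme4::ranef(fit)$cohort_f
  coh_eff <- stats::setNames(re[, 1], rownames(re))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    intercept = unname(fe[1]),
    age_effects = age_eff,
    period_effects = per_eff,
    cohort_effects = coh_eff,
    cohort_variance = vc$vcov[1],
    fit = fit), class = "apc_model")
}

#' @method print apc_model
#' @export
print.apc_model <- function(x, ...) {
  cat("Age-period-cohort mixed model (Poisson, log person-year offset)\n")
  cat(sprintf("  intercept (log rate): %.4f\n", x$intercept))
  cat(sprintf("  cohort variance:      %.5f\n", x$cohort_variance))
  cat("  period effects (sum-to-zero):\n")
  print(round(x$period_effects, 4))
  invisible(x)
}

#' Remove the fitted period effect from rates or scores
#'
#' Subtracts the fitted calendar-period effect on the linear-predictor
#' (log) scale, eliminating annual-policy shifts from event rates or risk
#' scores: \code{adjusted = x * exp(-period_effect[period])}. Values whose
#' period is outside the fitted range use effect 0. Within a period the
#' adjustment is a common positive factor, so orderings are preserved.
#'
#' @param x Positive rates or scores.
#' @param period Period labels aligned to \code{x}, matching the levels the
#'   model was fitted on.
#' @param apc An \code{apc_model}.
#' @return Adjusted values, same length as \code{x}.
#' @export
period_adjust <- function(x, period, apc) {
  stopifnot(inherits(apc, "apc_model"), length(x) == length(period))
  if (any(x < 0)) stop("ahprisk_apc_error: rates/scores must be nonnegative")
  eff <- apc$period_effects[as.character(period)]
  eff[is.na(eff)] <- 0
  unname(x * exp(-eff))
}
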