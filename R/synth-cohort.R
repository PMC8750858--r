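#' Default log-hazard coefficients of the synthetic generator
#'
#' Per-covariate log hazard ratios used as ground truth by
#' \code{\link{generate_cohort}}. The defaults are the Cox coefficient set
#' the pipeline is designed to recover: for example compliance 0.48,
#' female gender -0.37, diagnostic type 0.61. Covariates without a listed
#' coefficient carry zero effect.
#'
#' @return Named numeric vector of log hazard ratios.
#' @export
default_coefficients <- function() {
  c(adverse_reaction_times        =  0.01,
    drug_combination              =  0.16,
    age_rating                    =  0.09,
    diagnostic_type               =  0.61,
    course_duration               =  0.05,
    auxiliary_drug_combination    = -0.06,
    gender                        = -0.37,
    disability_rating             = -0.06,
    social_function               =  0.25,
    compliance                    =  0.48,
    targeted_poverty_alleviation  =  0.31,
    family_guardianship_subsidy   =  0.39)
}

#' Parameters of the synthetic follow-up cohort generator
#'
#' @param n Number of patient-course records.
#' @param coefficients Named log-hazard coefficients over covariates
#'   (default \code{\link{default_coefficients}}).
#' @param n_regions Number of regions.
#' @param region_effects Per-region log-hazard offsets (length
#'   \code{n_regions}); default spread over +/- 0.5.
#' @param female_frac Fraction of female patients.
#' @param age_range Age range in years (uniform).
#' @param period_range Calendar-year range of follow-up periods.
#' @param policy_year First year of the policy step effect.
#' @param policy_effect Log-hazard step from \code{policy_year} onward.
#' @param event_rate Target marginal event prevalence used to calibrate the
#'   exponential baseline hazard.
#' @param seed Integer RNG seed; the same seed reproduces the cohort exactly.
#' @return A \code{cohort_params} list.
#' @export
cohort_params <- function(n = 2000L,
                          coefficients = default_coefficients(),
                          n_regions = 5L,
                          region_effects = seq(-0.5, 0.5, length.out = n_regions),
                          female_frac = 0.45,
                          age_range = c(18, 80),
                          period_range = c(2010L, 2019L),
                          policy_year = 2015L,
                          policy_effect = 0.3,
                          event_rate = 0.15,
                          seed = 1L) {
  stopifnot(n >= 10L, n_regions >= 2L,
            length(region_effects) == n_regions,
            female_frac >= 0, female_frac <= 1,
            event_rate > 0, event_rate < 1)
  if (event_rate >= 0.999)
    stop("ahprisk_generator_error: impossible event-rate target")
  structure(list(
    n = as.integer(n), coefficients = coefficients, n_regions = n_regions,
    region_effects = region_effects, female_frac = female_frac,
    age_range = age_range, period_range = as.integer(period_range),
    policy_year = as.integer(policy_year), policy_effect = policy_effect,
    event_rate = event_rate, seed = as.integer(seed)),
    class = "cohort_params")
}

#' Generate a synthetic follow-up cohort
#'
#' Draws one row per patient-course with the covariate schema of the risk
#' hierarchy (demography, treatment and disease-course variables), then
#' event times from an exponential proportional-hazards model whose linear
#' predictor is the sum of coefficient-weighted covariates, a region offset
#' and the annual-policy step; records are administratively censored at the
#' end of their follow-up duration. The exponential baseline rate is
#' calibrated so the realized event prevalence matches the
#' \code{event_rate} target. Everything is driven by the single seed, so a
#' given parameter set is exactly reproducible.
#'
#' @param p A \code{\link{cohort_params}} object.
#' @return List with \code{data} (the cohort \code{data.frame}) and
#'   \code{truth} (the exact generator parameters, including the calibrated
#'   baseline hazard).
#' @export
generate_cohort <- function(p = cohort_params()) {
  stopifnot(inherits(p, "cohort_params"))
  set.seed(p$seed)
  n <- p$n
  age <- stats::runif(n, p$age_range[1], p$age_range[2])
  d <- data.frame(
    region = sample.int(p$n_regions, n, replace = TRUE),
    age = round(age, 1),
    age_rating = as.integer(cut(age, breaks = c(-Inf, 30, 42, 54, 66, Inf))),
    gender = stats::rbinom(n, 1L, p$female_frac),
    education = sample(0:4, n, replace = TRUE,
                       prob = c(0.15, 0.30, 0.30, 0.15, 0.10)),
    disability_rating = sample(0:3, n, replace = TRUE,
                               prob = c(0.40, 0.30, 0.20, 0.10)),
    social_function = sample(1:4, n, replace = TRUE,
                             prob = c(0.25, 0.35, 0.25, 0.15)),
    economic_status = sample(1:3, n, replace = TRUE,
                             prob = c(0.45, 0.40, 0.15)),
    compliance = stats::rbinom(n, 1L, 0.5),
    adverse_reaction_times = stats::rpois(n, 1.2),
    drug_combination = stats::rbinom(n, 1L, 0.4),
    auxiliary_drug_combination = stats::rbinom(n, 1L, 0.3),
    drug_combination_number = stats::rpois(n, 1.5),
    hospitalization_times = stats::rpois(n, 0.8),
    referral_times = stats::rpois(n, 0.5),
    suggest_referral = stats::rbinom(n, 1L, 0.2),
    diagnostic_type = stats::rbinom(n, 1L, 0.35),
    poverty = stats::rbinom(n, 1L, 0.25),
    targeted_poverty_alleviation = stats::rbinom(n, 1L, 0.15),
    family_guardianship_subsidy = stats::rbinom(n, 1L, 0.10),
    course_of_disease_rating = sample(1:4, n, replace = TRUE,
                                      prob = c(0.30, 0.35, 0.25, 0.10)),
    course_duration = round(stats::rnorm(n), 3),
    period_year = sample(seq(p$period_range[1], p$period_range[2]), n,
                         replace = TRUE),
    duration_days = pmin(3650L, pmax(30L, round(stats::rgamma(n, shape = 2,
                                                              scale = 500)))))

  beta <- p$coefficients
  unknown <- setdiff(names(beta), names(d))
  if (length(unknown))
    stop(sprintf("ahprisk_generator_error: coefficient(s) for unknown covariate(s): %s",
                 paste(unknown, collapse = ", ")))
  # center effect-carrying covariates so the coefficient scale does not
  # drift the marginal prevalence away from the calibrated target
  lp <- rep(0, n)
  for (v in names(beta))
    lp <- lp + beta[[v]] * (d[[v]] - mean(d[[v]]))
  lp <- lp + p$region_effects[d$region]
  lp <- lp + ifelse(d$period_year >= p$policy_year, p$policy_effect, 0)

  # calibrate the exponential baseline so mean P(T < duration) hits the target
  prev <- function(log_lam0)
    mean(1 - exp(-exp(log_lam0 + lp) * d$duration_days)) - p$event_rate
  log_lam0 <- stats::uniroot(prev, c(-20, 0), tol = 1e-10)$root
  lam <- exp(log_lam0 + lp)
  t_event <- stats::rexp(n, rate = lam)
  d$event <- as.integer(t_event < d$duration_days)
  d$event_time_days <- pmax(0.01, round(pmin(t_event, d$duration_days), 2))

  truth <- list(params = p, baseline_log_hazard = log_lam0,
                linear_predictor_sd = stats::sd(lp),
                realized_event_rate = mean(d$event))
  list(data = d, truth = truth)
}

#' Aggregate a cohort into an age-by-period event/exposure grid
#'
#' Builds the input of the age-period-cohort model: events and person-year
#' exposure per age-group x calendar-period cell, with the cohort index
#' defined by the identity cohort = period index - age index.
#'
#' @param data A cohort \code{data.frame} (needs \code{age},
#'   \code{period_year}, \code{event}, \code{duration_days}).
#' @param age_breaks Age-group cut points in years.
#' @return \code{data.frame} with \code{age_group}, \code{period},
#'   \code{cohort}, \code{events}, \code{exposure} (person-years) and
#'   \code{n}.
#' @export
apc_grid <- function(data, age_breaks = seq(15, 85, by = 10)) {
  stopifnot(all(c("age", "period_year", "event", "duration_days") %in% names(data)))
  ag <- as.integer(cut(data$age, breaks = age_breaks, include.lowest = TRUE))
  pe <- as.integer(factor(data$period_year))
  cells <- stats::aggregate(
    cbind(events = data$event,
          exposure = data$duration_days / 365.25,
          n = 1L) ~ age_group + period,
    data = data.frame(age_group = ag, period = pe),
    FUN = sum)
  cells$cohort <- cells$period - cells$age_group
  cells[order(cells$age_group, cells$period),
        c("age_group", "period", "cohort", "events", "exposure", "n")]
}
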