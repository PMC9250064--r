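#' Default age distribution for the synthetic population
#'
#' A discretized bell-shaped distribution over adult ages, loosely matching
#' the median ages (mid-30s to late 50s) reported for vaccinated EHR
#' populations.
#'
#' @param ages integer vector of attainable ages.
#' @param mean,sd location and spread of the (truncated, discretized) shape.
#' @return data.frame with columns `age` (integer) and `prob` (sums to 1).
#' @export
default_age_distribution <- function(ages = 18:85, mean = 50, sd = 18) {
  w <- dnorm(ages, mean, sd)
  data.frame(age = as.integer(ages), prob = w / sum(w))
}

#' Scenario configuration for the synthetic EHR generator
#'
#' Bundles every parameter of the generative model: demographics, the latent
#' health burden, encounter-conditional recording, health-selected
#' vaccination, and the vaccination-to-visit coupling probability `kappa`
#' (`visit_coupling_prob`) that drives day-0 anchoring effects.
#'
#' The model, per person i with latent burden h_i ~ Gamma(shape, scale) and
#' age a_i (in decades where it enters a linear predictor):
#' \itemize{
#'   \item chronic concept c present with probability
#'     `plogis(intercept_c + burden_loading_c * h_i + age_loading_c * a_i)`;
#'   \item visits: homogeneous Poisson process with per-day rate
#'     `base_visit_rate_per_day * exp(visit_rate_burden_coef * h_i +
#'     visit_rate_age_coef * a_i)`, dates deduplicated;
#'   \item at each visit, each present chronic concept is recorded with
#'     `record_prob_chronic`, each measurement concept with
#'     `record_prob_measurement`, each drug concept with `record_prob_drug`,
#'     and each acute concept occurs with `acute_event_prob_per_visit`;
#'   \item vaccination (first dose only) with probability
#'     `plogis(vaccination_logit_intercept + vaccination_burden_coef * h_i +
#'     vaccination_age_coef * a_i)`, date uniform over `vaccination_window`;
#'     with probability `visit_coupling_prob` the date is moved onto a visit
#'     (an existing visit in the window if any, else a visit is created on
#'     the drawn date); otherwise no visit is created on that date.
#' }
#'
#' @param n_persons number of simulated persons.
#' @param observation_start,observation_end observation period (Dates); must
#'   span at least 900 days.
#' @param age_distribution data.frame(age, prob).
#' @param sex_probability probability of sex `"F"`.
#' @param health_burden_shape,health_burden_scale Gamma parameters of the
#'   latent burden h.
#' @param n_chronic_concepts,n_acute_concepts,n_measurement_concepts,n_drug_concepts
#'   covariate-universe sizes per domain.
#' @param chronic_prevalence_intercepts,burden_loadings,age_loadings numeric
#'   vectors of length `n_chronic_concepts`.
#' @param base_visit_rate_per_day baseline visit rate lambda0 (per day).
#' @param visit_rate_burden_coef,visit_rate_age_coef visit-rate log-linear
#'   coefficients (age in decades).
#' @param record_prob_chronic,record_prob_measurement,record_prob_drug
#'   per-visit recording probabilities.
#' @param acute_event_prob_per_visit per-visit, per-concept probability of an
#'   acute event.
#' @param vaccination_logit_intercept,vaccination_burden_coef,vaccination_age_coef
#'   vaccination-propensity logit coefficients (age in decades).
#' @param visit_coupling_prob probability kappa that a vaccination is
#'   administered at a health care visit.
#' @param vaccination_window Date vector of length 2; every date in it must
#'   admit a 450-day lookback within the observation period.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output tables.
#' @return an object of class `scenario_config` (a validated list).
#' @seealso [make_scenario()] for the influenza-like / COVID-like / null
#'   presets, [generate_population()].
#' @export
scenario_config <- function(n_persons = 20000L,
                            observation_start = as.Date("2017-01-01"),
                            observation_end = observation_start + 1249L,
                            age_distribution = default_age_distribution(),
                            sex_probability = 0.6,
                            health_burden_shape = 2,
                            health_burden_scale = 1,
                            n_chronic_concepts = 40L,
                            n_acute_concepts = 20L,
                            n_measurement_concepts = 30L,
                            n_drug_concepts = 30L,
                            chronic_prevalence_intercepts =
                              seq(-4.5, -1.5, length.out = n_chronic_concepts),
                            burden_loadings =
                              seq(0.25, 0.55, length.out = n_chronic_concepts),
                            age_loadings = rep(0.15, n_chronic_concepts),
                            base_visit_rate_per_day = 0.003,
                            visit_rate_burden_coef = 0.35,
                            visit_rate_age_coef = 0.06,
                            record_prob_chronic = 0.25,
                            record_prob_measurement = 0.3,
                            record_prob_drug = 0.15,
                            acute_event_prob_per_visit = 0.02,
                            vaccination_logit_intercept = -0.85,
                            vaccination_burden_coef = 0,
                            vaccination_age_coef = 0.1,
                            visit_coupling_prob = 0.1,
                            vaccination_window =
                              c(observation_start + 930L, observation_start + 1100L),
                            seed = 1L) {
  config <- structure(
    list(
      n_persons = as.integer(n_persons),
      observation_start = as.Date(observation_start),
      observation_end = as.Date(observation_end),
      age_distribution = age_distribution,
      sex_probability = sex_probability,
      health_burden_shape = health_burden_shape,
      health_burden_scale = health_burden_scale,
      n_chronic_concepts = as.integer(n_chronic_concepts),
      n_acute_concepts = as.integer(n_acute_concepts),
      n_measurement_concepts = as.integer(n_measurement_concepts),
      n_drug_concepts = as.integer(n_drug_concepts),
      chronic_prevalence_intercepts = chronic_prevalence_intercepts,
      burden_loadings = burden_loadings,
      age_loadings = age_loadings,
      base_visit_rate_per_day = base_visit_rate_per_day,
      visit_rate_burden_coef = visit_rate_burden_coef,
      visit_rate_age_coef = visit_rate_age_coef,
      record_prob_chronic = record_prob_chronic,
      record_prob_measurement = record_prob_measurement,
      record_prob_drug = record_prob_drug,
      acute_event_prob_per_visit = acute_event_prob_per_visit,
      vaccination_logit_intercept = vaccination_logit_intercept,
      vaccination_burden_coef = vaccination_burden_coef,
      vaccination_age_coef = vaccination_age_coef,
      visit_coupling_prob = visit_coupling_prob,
      vaccination_window = as.Date(vaccination_window),
      seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
  validate_scenario(config)
  config
}

#' Validate a scenario configuration
#'
#' Checks probability ranges, rate positivity, per-concept vector lengths and
#' the lookback feasibility of the vaccination window (every vaccination date
#' must admit a 450-day lookback).
#'
#' @param config a `scenario_config`.
#' @return the config, invisibly, or an error.
#' @export
validate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  ck <- function(cond, msg) if (!cond) stop("invalid scenario_config: ", msg, call. = FALSE)
  ck(length(config$n_persons) == 1 && config$n_persons >= 1, "n_persons must be a positive integer")
  span <- as.integer(config$observation_end - config$observation_start) + 1L
  ck(span >= 900L, "observation period must span at least 900 days")
  ad <- config$age_distribution
  ck(is.data.frame(ad) && all(c("age", "prob") %in% names(ad)) &&
       all(ad$prob >= 0) && abs(sum(ad$prob) - 1) < 1e-8,
     "age_distribution must be a data.frame(age, prob) with prob summing to 1")
  probs <- c(config$sex_probability, config$record_prob_chronic,
             config$record_prob_measurement, config$record_prob_drug,
             config$acute_event_prob_per_visit, config$visit_coupling_prob)
  ck(all(probs >= 0 & probs <= 1), "all probabilities must lie in [0, 1]")
  ck(config$health_burden_shape > 0 && config$health_burden_scale > 0,
     "health burden Gamma parameters must be positive")
  ck(config$base_visit_rate_per_day > 0, "base_visit_rate_per_day must be positive")
  nc <- config$n_chronic_concepts
  ck(all(c(config$n_acute_concepts, config$n_measurement_concepts,
           config$n_drug_concepts, nc) >= 0), "concept counts must be nonnegative")
  ck(length(config$chronic_prevalence_intercepts) == nc &&
       length(config$burden_loadings) == nc &&
       length(config$age_loadings) == nc,
     "chronic concept coefficient vectors must have length n_chronic_concepts")
  vw <- config$vaccination_window
  ck(length(vw) == 2 && vw[1] <= vw[2], "vaccination_window must be an ordered Date pair")
  ck(vw[1] >= config$observation_start && vw[2] <= config$observation_end,
     "vaccination_window must lie within the observation period")
  ck(as.integer(vw[1] - config$observation_start) >= 450L,
     "observation window too short: vaccination dates must admit a 450-day lookback")
  invisible(config)
}

#' Expected background daily visit probability under a scenario
#'
#' The population-average probability that a person has at least one visit on
#' a given calendar day, `E[1 - exp(-lambda_i)]`, integrating the visit-rate
#' model over the latent burden (Gamma) and age distributions. Used to set
#' the null preset's visit-coupling probability and as the closed-form `q` in
#' same-day-visit calibration checks.
#'
#' @param config a `scenario_config`.
#' @return a probability.
#' @export
expected_daily_visit_prob <- function(config) {
  shape <- config$health_burden_shape
  scale <- config$health_burden_scale
  lam0 <- config$base_visit_rate_per_day
  b <- config$visit_rate_burden_coef
  a <- config$visit_rate_age_coef
  ad <- config$age_distribution
  q_age <- vapply(ad$age / 10, function(aged) {
    integrate(function(h) {
      (1 - exp(-lam0 * exp(b * h + a * aged))) * dgamma(h, shape, scale = scale)
    }, 0, Inf, rel.tol = 1e-9)$value
  }, numeric(1))
  sum(ad$prob * q_age)
}

#' Scenario presets: influenza-like, COVID-like, null
#'
#' Three parameterizations of the generator capturing the qualitatively
#' different vaccination regimes:
#' \describe{
#'   \item{`influenza_like`}{visit-coupled administration
#'     (`visit_coupling_prob = 0.558`) with positive health selection
#'     (sicker people more likely vaccinated): influenza vaccination is
#'     typically delivered during a health care visit to vulnerable
#'     populations.}
#'   \item{`covid_like`}{visit-decoupled administration
#'     (`visit_coupling_prob = 0.027`) with negative health selection
#'     (vaccinated population healthier on average than the EHR-captured
#'     population): mass COVID-19 vaccination at sites unconnected to care.}
#'   \item{`null`}{no health or age selection into vaccination and a
#'     coupling probability equal to the background daily visit probability
#'     (computed analytically via [expected_daily_visit_prob()]), so that
#'     anchoring differences reflect sampling error only.}
#' }
#'
#' @param preset one of `"influenza_like"`, `"covid_like"`, `"null"`.
#' @param ... overrides forwarded to [scenario_config()] (e.g. `n_persons`,
#'   `seed`); overrides take precedence over preset values.
#' @return a `scenario_config`.
#' @export
make_scenario <- function(preset = c("influenza_like", "covid_like", "null"), ...) {
  preset <- match.arg(preset)
  preset_args <- switch(preset,
    influenza_like = list(visit_coupling_prob = 0.558,
                          vaccination_burden_coef = 0.35,
                          vaccination_logit_intercept = -1.6),
    covid_like = list(visit_coupling_prob = 0.027,
                      vaccination_burden_coef = -0.35,
                      vaccination_logit_intercept = -0.25),
    null = list(visit_coupling_prob = NA_real_,  # filled analytically below
                vaccination_burden_coef = 0,
                vaccination_age_coef = 0,
                vaccination_logit_intercept = -0.85)
  )
  user <- list(...)
  args <- utils::modifyList(preset_args, user)
  if (preset == "null" && is.na(args$visit_coupling_prob)) {
    args$visit_coupling_prob <- 0  # placeholder to pass validation
    cfg <- do.call(scenario_config, args)
    cfg$visit_coupling_prob <- expected_daily_visit_prob(cfg)
    cfg <- validate_scenario(cfg)
    return(cfg)
  }
  do.call(scenario_config, args)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  persons: %d, seed: %d\n", x$n_persons, x$seed))
  cat(sprintf("  observation: %s .. %s (%d days)\n",
              format(x$observation_start), format(x$observation_end),
              as.integer(x$observation_end - x$observation_start) + 1L))
  cat(sprintf("  vaccination window: %s .. %s, coupling kappa = %.4g\n",
              format(x$vaccination_window[1]), format(x$vaccination_window[2]),
              x$visit_coupling_prob))
  cat(sprintf("  vaccination logit: %.3g + %.3g*burden + %.3g*age_decades\n",
              x$vaccination_logit_intercept, x$vaccination_burden_coef,
              x$vaccination_age_coef))
  cat(sprintf("  concepts: %d chronic / %d acute / %d measurement / %d drug\n",
              x$n_chronic_concepts, x$n_acute_concepts,
              x$n_measurement_concepts, x$n_drug_concepts))
  invisible(x)
}
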