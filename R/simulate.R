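#' Construct a population dataset from its component tables
#'
#' Low-level constructor used by [generate_population()] and by tests that
#' build tiny hand-written fixtures. Validates the recording invariants
#' (events only at visits; coupled vaccinations have a same-day visit; at
#' most one vaccination per person).
#'
#' @param persons data.frame(person_id, sex, age_at_start, latent_burden).
#' @param visits data.frame(person_id, visit_date).
#' @param events data.frame(person_id, event_date, concept_id, domain).
#' @param vaccinations data.frame(person_id, vaccination_date, coupled_flag).
#' @param observation_start,observation_end observation period (Dates).
#' @param config the generating `scenario_config`, or NULL for hand-built data.
#' @return an object of class `population_dataset`.
#' @export
population_dataset <- function(persons, visits, events, vaccinations,
                               observation_start, observation_end,
                               config = NULL) {
  pop <- structure(
    list(
      persons = as.data.table(persons),
      visits = as.data.table(visits),
      events = as.data.table(events),
      vaccinations = as.data.table(vaccinations),
      observation_start = as.Date(observation_start),
      observation_end = as.Date(observation_end),
      config = config
    ),
    class = "population_dataset"
  )
  validate_population(pop)
  pop
}

#' Validate a population dataset's recording invariants
#'
#' Asserts that (1) every clinical event falls on a visit date of the same
#' person (recording is encounter-driven), (2) every vaccination flagged as
#' visit-coupled has a same-person visit on the vaccination date, and (3)
#' each person has at most one vaccination row.
#'
#' @param pop a `population_dataset`.
#' @return the dataset, invisibly, or an error describing the violated
#'   invariant.
#' @export
validate_population <- function(pop) {
  stopifnot(inherits(pop, "population_dataset"))
  ck <- function(cond, msg) if (!cond) stop("invalid population_dataset: ", msg, call. = FALSE)
  ck(all(c("person_id", "sex", "age_at_start", "latent_burden") %in% names(pop$persons)),
     "persons table missing columns")
  ck(all(c("person_id", "visit_date") %in% names(pop$visits)), "visits table missing columns")
  ck(all(c("person_id", "event_date", "concept_id", "domain") %in% names(pop$events)),
     "events table missing columns")
  ck(all(c("person_id", "vaccination_date", "coupled_flag") %in% names(pop$vaccinations)),
     "vaccinations table missing columns")
  ck(all(pop$events$domain %in% c("condition", "procedure", "measurement", "drug")),
     "unknown event domain")
  if (nrow(pop$events)) {
    hit <- pop$visits[pop$events, on = c("person_id", visit_date = "event_date"),
                      nomatch = NA, which = TRUE]
    ck(!anyNA(hit), "events must coincide with a same-person visit date")
  }
  vc <- pop$vaccinations[coupled_flag == TRUE]
  if (nrow(vc)) {
    hit <- pop$visits[vc, on = c("person_id", visit_date = "vaccination_date"),
                      nomatch = NA, which = TRUE]
    ck(!anyNA(hit), "coupled vaccinations must have a same-day visit")
  }
  ck(!anyDuplicated(pop$vaccinations$person_id), "at most one vaccination per person")
  invisible(pop)
}

#' @export
print.population_dataset <- function(x, ...) {
  cat("<population_dataset>\n")
  cat(sprintf("  observation: %s .. %s\n",
              format(x$observation_start), format(x$observation_end)))
  cat(sprintf("  persons: %d, visits: %d, events: %d, vaccinated: %d (%.1f%%)\n",
              nrow(x$persons), nrow(x$visits), nrow(x$events),
              nrow(x$vaccinations),
              100 * nrow(x$vaccinations) / max(1L, nrow(x$persons))))
  invisible(x)
}

#' Generate a synthetic OMOP-lite population
#'
#' Simulates persons, encounter histories, encounter-conditional clinical
#' events and health-selected vaccinations under a [scenario_config()]. The
#' mechanism that matters for anchoring: covariates are only *recorded* when
#' a person visits, and vaccination is administered at a visit with
#' probability `visit_coupling_prob` (kappa). With kappa high
#' (influenza-like), day-0 of the vaccinated cohort is saturated with
#' encounter-generated records; with kappa near zero (COVID-like) it is not.
#'
#' Determinism: identical config (including `seed`) yields bit-identical
#' tables. Dates are simulated as integer day offsets from
#' `observation_start` and exported as calendar `Date`s.
#'
#' @param config a `scenario_config`.
#' @return a `population_dataset` with tables `persons`, `visits`, `events`,
#'   `vaccinations`.
#' @examples
#' pop <- generate_population(make_scenario("influenza_like", n_persons = 500))
#' pop
#' @export
generate_population <- function(config) {
  validate_scenario(config)
  obs0 <- config$observation_start
  W <- as.integer(config$observation_end - obs0) + 1L
  n <- config$n_persons

  withr::with_seed(config$seed, {
    sex <- ifelse(runif(n) < config$sex_probability, "F", "M")
    age <- sample(config$age_distribution$age, n, replace = TRUE,
                  prob = config$age_distribution$prob)
    h <- rgamma(n, config$health_burden_shape, scale = config$health_burden_scale)
    aged <- age / 10

    # person-level chronic concept presence
    nc <- config$n_chronic_concepts
    if (nc > 0) {
      lin <- matrix(config$chronic_prevalence_intercepts, n, nc, byrow = TRUE) +
        outer(h, config$burden_loadings) + outer(aged, config$age_loadings)
      present <- matrix(runif(n * nc), n, nc) < plogis(lin)
    } else {
      present <- matrix(FALSE, n, 0)
    }

    # visits: homogeneous Poisson per person, deduplicated to day resolution
    lam <- config$base_visit_rate_per_day *
      exp(config$visit_rate_burden_coef * h + config$visit_rate_age_coef * aged)
    nv <- rpois(n, lam * W)
    visits <- data.table(person_id = rep(seq_len(n), nv))
    visits[, day := as.integer(floor(runif(.N) * W))]
    visits <- unique(visits)

    # vaccination: health-selected assignment, uniform date, kappa-coupling
    pv <- plogis(config$vaccination_logit_intercept +
                   config$vaccination_burden_coef * h +
                   config$vaccination_age_coef * aged)
    vid <- which(runif(n) < pv)
    wlo <- as.integer(config$vaccination_window[1] - obs0)
    whi <- as.integer(config$vaccination_window[2] - obs0)
    vday <- wlo + as.integer(floor(runif(length(vid)) * (whi - wlo + 1L)))
    coupled <- runif(length(vid)) < config$visit_coupling_prob
    vacc <- data.table(person_id = vid, day = vday, coupled_flag = coupled)
    if (any(coupled)) {
      # coupled dose moves onto an existing in-window visit if the person has
      # one, else a visit is created on the drawn date
      cw <- visits[person_id %in% vid[coupled] & day >= wlo & day <= whi]
      if (nrow(cw)) {
        pick <- cw[, .(pday = day[sample.int(.N, 1L)]), keyby = person_id]
        vacc[pick, day := i.pday, on = "person_id"]
      } else {
        pick <- data.table(person_id = integer())
      }
      need <- vacc[coupled_flag == TRUE & !person_id %in% pick$person_id]
      if (nrow(need)) visits <- unique(rbind(visits, need[, .(person_id, day)]))
    }
    setkey(visits, person_id, day)

    # encounter-conditional event recording
    ev <- vector("list", 0L)
    add <- function(rows, days, cid, dom) {
      data.table(person_id = rows, day = days, concept_id = cid, domain = dom)
    }
    vp <- visits$person_id
    vd <- visits$day
    nvr <- nrow(visits)
    for (cc in seq_len(nc)) {
      elig <- which(present[vp, cc])
      keep <- elig[runif(length(elig)) < config$record_prob_chronic]
      if (length(keep))
        ev[[length(ev) + 1L]] <- add(vp[keep], vd[keep], 1000L + cc, "condition")
    }
    per_visit <- function(n_concepts, base_id, prob, dom) {
      for (cc in seq_len(n_concepts)) {
        keep <- which(runif(nvr) < prob)
        if (length(keep))
          ev[[length(ev) + 1L]] <<- add(vp[keep], vd[keep], base_id + cc, dom)
      }
    }
    per_visit(config$n_acute_concepts, 2000L, config$acute_event_prob_per_visit, "condition")
    per_visit(config$n_measurement_concepts, 3000L, config$record_prob_measurement, "measurement")
    per_visit(config$n_drug_concepts, 4000L, config$record_prob_drug, "drug")
    events <- if (length(ev)) rbindlist(ev) else
      data.table(person_id = integer(), day = integer(),
                 concept_id = integer(), domain = character())
    setkey(events, person_id, day, domain, concept_id)

    persons <- data.table(person_id = seq_len(n), sex = sex,
                          age_at_start = as.integer(age), latent_burden = h)
    setkey(vacc, person_id)

    population_dataset(
      persons = persons,
      visits = visits[, .(person_id, visit_date = obs0 + day)],
      events = events[, .(person_id, event_date = obs0 + day, concept_id, domain)],
      vaccinations = vacc[, .(person_id, vaccination_date = obs0 + day, coupled_flag)],
      observation_start = obs0,
      observation_end = config$observation_end,
      config = config
    )
  })
}
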