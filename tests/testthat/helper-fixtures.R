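# Hand-built fixtures, constructed in code at test time.
library(data.table)

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_obs0 <- as.Date("2017-01-01")
toy_day <- function(d) toy_obs0 + d

# Three persons, all indexed on day 960; every event sits on a visit.
# Visit days (offsets from index 960 in brackets):
#   p1: 930 (-30), 959 (-1), 960 (0)
#   p2: 780 (-180), 959 (-1)
#   p3: 510 (-450), 960 (0)
# Events:
#   p1: condition 1001 @960, measurement 3001 @930, drug 4001 @959 and @960
#   p2: condition 1001 @959, measurement 3001 @780
#   p3: measurement 3001 @510
make_toy_population <- function() {
  persons <- data.table(person_id = 1:3,
                        sex = c("F", "F", "M"),
                        age_at_start = c(62L, 63L, 45L),
                        latent_burden = c(2, 1.5, 1))
  visits <- data.table(
    person_id = c(1L, 1L, 1L, 2L, 2L, 3L, 3L),
    visit_date = toy_day(c(930, 959, 960, 780, 959, 510, 960)))
  events <- data.table(
    person_id  = c(1L, 1L, 1L, 1L, 2L, 2L, 3L),
    event_date = toy_day(c(960, 930, 959, 960, 959, 780, 510)),
    concept_id = c(1001L, 3001L, 4001L, 4001L, 1001L, 3001L, 3001L),
    domain = c("condition", "measurement", "drug", "drug",
               "condition", "measurement", "measurement"))
  vaccinations <- data.table(person_id = 1L,
                             vaccination_date = toy_day(960),
                             coupled_flag = TRUE)
  population_dataset(persons, visits, events, vaccinations,
                     toy_obs0, toy_obs0 + 1249L)
}

toy_cohort <- function(person_id, index_day, anchor_type = "vaccination") {
  data.table(person_id = as.integer(person_id),
             index_date = toy_day(index_day),
             anchor_type = anchor_type,
             match_group_id = as.integer(person_id))
}

# fast scenario for simulation-based unit tests: no clinical concepts unless
# asked, so only persons/visits/vaccinations are generated
fast_scenario <- function(..., n_chronic = 0L, n_acute = 0L, n_meas = 0L,
                          n_drug = 0L) {
  scenario_config(n_chronic_concepts = n_chronic, n_acute_concepts = n_acute,
                  n_measurement_concepts = n_meas, n_drug_concepts = n_drug,
                  ...)
}

# per-person daily visit probability implied by a config and a persons table
person_daily_visit_prob <- function(config, persons) {
  lam <- config$base_visit_rate_per_day *
    exp(config$visit_rate_burden_coef * persons$latent_burden +
          config$visit_rate_age_coef * persons$age_at_start / 10)
  1 - exp(-lam)
}
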