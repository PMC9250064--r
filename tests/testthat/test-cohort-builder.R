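# small population for matching tests: 3 vaccinated targets (day 960),
# 4 unvaccinated candidates; age bins of width 5 put candidates 4,5 in the
# same stratum as targets 1,2 (F|12), candidate 6 with target 3 (M|9), and
# candidate 7 (F|16) in an empty stratum
make_match_population <- function(visits = NULL) {
  persons <- data.table(
    person_id = 1:7,
    sex = c("F", "F", "M", "F", "F", "M", "F"),
    age_at_start = c(62L, 63L, 45L, 64L, 60L, 47L, 80L),
    latent_burden = rep(1, 7))
  if (is.null(visits)) {
    visits <- data.table(person_id = integer(), visit_date = as.Date(character()))
  }
  events <- data.table(person_id = integer(), event_date = as.Date(character()),
                       concept_id = integer(), domain = character())
  vaccinations <- data.table(person_id = 1:3, vaccination_date = toy_day(960),
                             coupled_flag = FALSE)
  population_dataset(persons, visits, events, vaccinations,
                     toy_obs0, toy_obs0 + 1249L)
}

test_that("vaccinated cohort applies the lookback rule with attrition accounting", {
  persons <- data.table(person_id = 1:5, sex = c("F", "M", "F", "M", "F"),
                        age_at_start = c(40L, 50L, 60L, 70L, 30L),
                        latent_burden = rep(1, 5))
  vacc <- data.table(person_id = c(1L, 2L, 3L),
                     vaccination_date = toy_day(c(500, 100, 960)),
                     coupled_flag = FALSE)
  pop <- population_dataset(
    persons,
    data.table(person_id = integer(), visit_date = as.Date(character())),
    data.table(person_id = integer(), event_date = as.Date(character()),
               concept_id = integer(), domain = character()),
    vacc, toy_obs0, toy_obs0 + 1249L)

  coh <- build_vaccinated_cohort(pop, match_spec(lookback_required_days = 450L))
  # person 1 (day 500) and person 3 (day 960) admit the lookback; person 2
  # (day 100) does not
  expect_setequal(coh$person_id, c(1L, 3L))
  expect_true(all(coh$anchor_type == "vaccination"))
  expect_identical(coh[person_id == 1L]$index_date, toy_day(500))
  att <- attrition(coh)
  expect_identical(att[stage == "excluded_lookback"]$n, 1L)
  expect_identical(att[stage == "vaccinated"]$n, 3L)
})

test_that("all-eligible toy dataset yields a cohort of all vaccinated", {
  pop <- make_match_population()
  coh <- build_vaccinated_cohort(pop, match_spec())
  expect_identical(nrow(coh), 3L)   # 3 of 5+ persons vaccinated, all eligible
  expect_identical(attrition(coh)[stage == "unmatched" | stage == "excluded_lookback"]$n, 0L)
})

test_that("empty vaccinated pool warns and returns an empty cohort", {
  pop <- make_match_population()
  pop$vaccinations <- pop$vaccinations[0]
  expect_warning(coh <- build_vaccinated_cohort(pop, match_spec()), "no vaccinated")
  expect_identical(nrow(coh), 0L)
})

test_that("arbitrary-date matching is exact on sex, age bin and calendar date", {
  pop <- make_match_population()
  targets <- build_vaccinated_cohort(pop, match_spec())
  comp <- match_arbitrary_date(targets, pop, match_spec(seed = 1))
  # every stratum has enough candidates: zero attrition, perfect 1:1
  expect_identical(nrow(comp), 3L)
  expect_identical(attrition(comp)[stage == "unmatched"]$n, 0L)
  expect_true(all(comp$anchor_type == "matched_date"))
  expect_true(all(comp$index_date == toy_day(960)))
  per <- pop$persons
  for (i in seq_len(nrow(comp))) {
    tgt <- per[person_id == comp$match_group_id[i]]
    cmp <- per[person_id == comp$person_id[i]]
    expect_identical(tgt$sex, cmp$sex)
    expect_identical(tgt$age_at_start %/% 5L, cmp$age_at_start %/% 5L)
  }
  # comparators are unvaccinated and never reused
  expect_false(any(comp$person_id %in% pop$vaccinations$person_id))
  expect_identical(anyDuplicated(comp$person_id), 0L)
})

test_that("a target with an empty stratum is left unmatched, not an error", {
  pop <- make_match_population()
  # make person 3 the only M target and remove the only M candidate (6)
  pop$persons <- pop$persons[person_id != 6L]
  targets <- build_vaccinated_cohort(pop, match_spec())
  comp <- match_arbitrary_date(targets, pop, match_spec(seed = 4))
  expect_false(3L %in% comp$match_group_id)
  expect_identical(attrition(comp)[stage == "unmatched"]$n, 1L)
  expect_identical(attrition(comp)[stage == "matched"]$n, 2L)
})

test_that("greedy matching equals a brute-force re-implementation across seeds", {
  pop <- make_match_population()
  targets <- build_vaccinated_cohort(pop, match_spec())
  per <- pop$persons
  for (s in 1:6) {
    comp <- match_arbitrary_date(targets, pop, match_spec(seed = s))
    # independent oracle: greedy in seed-shuffled target order, candidates in
    # ascending person_id order within exact (sex, age bin) strata
    cand <- per[!person_id %in% pop$vaccinations$person_id]
    key <- function(p) paste(per[person_id == p]$sex,
                             per[person_id == p]$age_at_start %/% 5L, sep = "|")
    pools <- split(cand$person_id, paste(cand$sex, cand$age_at_start %/% 5L, sep = "|"))
    used <- c()
    expected <- list()
    withr::with_seed(s, {
      ord <- sample.int(nrow(targets))
      for (i in ord) {
        pids <- pools[[key(targets$person_id[i])]]
        avail <- setdiff(pids, used)
        if (length(avail) < 1) next
        pick <- avail[sample.int(length(avail), 1L)]
        used <- c(used, pick)
        expected[[length(expected) + 1L]] <-
          data.table(person_id = pick, match_group_id = targets$person_id[i])
      }
    })
    expected <- rbindlist(expected)[order(match_group_id, person_id)]
    expect_identical(comp[, .(person_id, match_group_id)], expected,
                     label = sprintf("seed %d", s))
  }
})

test_that("visit-date matching requires a same-day visit unless a tolerance is set", {
  # candidate 4 (same stratum as targets 1-2) has a visit 3 days after the
  # index; candidate 5 has one on the index date; candidate 6 has none
  vis <- data.table(person_id = c(4L, 5L),
                    visit_date = toy_day(c(963, 960)))
  pop <- make_match_population(visits = vis)
  targets <- build_vaccinated_cohort(pop, match_spec())

  strict <- match_visit_date(targets, pop, match_spec(seed = 2))
  # only candidate 5 has a visit on day 960: one match, index on that date
  expect_identical(nrow(strict), 1L)
  expect_identical(strict$person_id, 5L)
  expect_identical(strict$index_date, toy_day(960))
  expect_identical(attrition(strict)[stage == "unmatched"]$n, 2L)

  tol <- match_visit_date(targets, pop, match_spec(seed = 2, visit_date_tolerance = 7L))
  # candidate 4 now eligible, anchored on its nearest visit (day 963)
  expect_identical(nrow(tol), 2L)
  expect_identical(tol[person_id == 4L]$index_date, toy_day(963))
  expect_true(all(tol$anchor_type == "matched_visit"))
})

test_that("matched cohorts mirror target sex and age-bin marginals without reuse", {
  pop <- generate_population(make_scenario("influenza_like", n_persons = 2500, seed = 14))
  spec <- match_spec(seed = 14)
  targets <- build_vaccinated_cohort(pop, spec)
  for (comp in list(match_arbitrary_date(targets, pop, spec),
                    match_visit_date(targets, pop, spec))) {
    expect_identical(anyDuplicated(comp$person_id), 0L)
    paired <- complete_pairs(targets, comp)
    demo <- function(coh) {
      d <- merge(coh, pop$persons, by = "person_id")[, .(sex, bin = age_at_start %/% 5L)]
      d[order(sex, bin), .N, by = .(sex, bin)]
    }
    expect_identical(demo(paired), demo(comp))
    # attrition accounting: targets_in = matched + unmatched
    att <- attrition(comp)
    expect_identical(att[stage == "targets_in"]$n,
                     att[stage == "matched"]$n + att[stage == "unmatched"]$n)
  }
})

test_that("self-controlled anchors stay in the pre-vaccination window", {
  pop <- generate_population(make_scenario("influenza_like", n_persons = 1200, seed = 6))
  targets <- build_vaccinated_cohort(pop, match_spec())
  for (mode in c("prior_date", "prior_visit")) {
    ctrl <- self_controlled_anchors(targets, pop, mode, seed = 6)
    expect_true(all(ctrl$anchor_type == mode))
    vd <- targets[match(ctrl$match_group_id, match_group_id)]$index_date
    off <- as.integer(ctrl$index_date - vd)
    expect_true(all(off >= -450L & off <= -180L))
    # controls admit their own lookback
    expect_true(all(as.integer(ctrl$index_date - pop$observation_start) >= 450L))
    att <- attrition(ctrl)
    expect_identical(att[stage == "targets_in"]$n,
                     att[stage == "anchored"]$n +
                       att[stage == "excluded_no_eligible_day"]$n)
  }
})

test_that("prior-visit anchoring excludes exactly the persons without an in-window visit", {
  vis <- data.table(person_id = c(1L, 1L, 2L),
                    visit_date = toy_day(c(700, 950, 100)))
  pop <- make_match_population(visits = vis)
  targets <- build_vaccinated_cohort(pop, match_spec())
  ctrl <- self_controlled_anchors(targets, pop, "prior_visit", seed = 3)
  # person 1: single eligible visit at day 700 (window [510, 780]) -> forced
  expect_identical(ctrl$person_id, 1L)
  expect_identical(ctrl$index_date, toy_day(700))
  # persons 2 (visit at day 100, outside) and 3 (no visits) are excluded
  expect_setequal(attr(ctrl, "dropped_person_ids"), c(2L, 3L))
  # complete-pair restriction drops them from the case side too
  cases <- complete_pairs(targets, ctrl)
  expect_identical(cases$person_id, 1L)
})

test_that("prior-date sampling matches a reference sampler", {
  pop <- make_match_population()
  targets <- build_vaccinated_cohort(pop, match_spec())
  for (s in c(1, 7, 19)) {
    ctrl <- self_controlled_anchors(targets, pop, "prior_date", seed = s)
    # reference: persons ascending, one uniform draw over the 271 candidate
    # days [510, 780] each (vaccination day 960, window [-450, -180],
    # lookback 450)
    expected <- withr::with_seed(s, {
      vapply(1:3, function(p) 510L + sample.int(271L, 1L) - 1L, integer(1))
    })
    expect_identical(as.integer(ctrl$index_date - toy_obs0), expected,
                     label = sprintf("seed %d", s))
  }
})

test_that("with replacement, a comparator may serve several targets", {
  pop <- make_match_population()
  # leave only candidate 4 in the F|12 stratum serving targets 1 and 2
  pop$persons <- pop$persons[person_id != 5L]
  targets <- build_vaccinated_cohort(pop, match_spec())
  no_rep <- match_arbitrary_date(targets, pop, match_spec(seed = 3))
  expect_identical(attrition(no_rep)[stage == "matched"]$n, 2L)
  with_rep <- match_arbitrary_date(targets, pop,
                                   match_spec(seed = 3, with_replacement = TRUE))
  expect_identical(attrition(with_rep)[stage == "matched"]$n, 3L)
  expect_identical(sum(with_rep$person_id == 4L), 2L)
})
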