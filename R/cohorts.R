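#' Matching specification for comparator anchoring
#'
#' Controls the exact greedy 1:`ratio` matching used to anchor unvaccinated
#' comparators: comparators are matched to vaccinated targets on sex, coarse
#' age bin and (by default) the exact calendar index date, in a seed-shuffled
#' target order, without replacement unless requested.
#'
#' @param age_bin_width width of the exact-matching age bins, in years.
#' @param require_same_sex match exactly on sex.
#' @param require_same_calendar_date if TRUE (default) the comparator's index
#'   date is the target's calendar index date (for visit anchoring, a visit
#'   on that date); if FALSE the comparator's index is drawn from its own
#'   history (an arbitrary eligible date, or an arbitrary eligible visit).
#' @param ratio comparators per target (all-or-nothing: a target with fewer
#'   than `ratio` available candidates is left unmatched).
#' @param with_replacement allow one comparator person to serve several
#'   targets.
#' @param lookback_required_days days of observation required before any
#'   index date.
#' @param visit_date_tolerance for visit anchoring only: accept a comparator
#'   visit within +/- this many days of the target's index date (the nearest
#'   such visit becomes the comparator's index date). 0 = strict same-day.
#' @param seed integer seed driving target shuffling and candidate sampling.
#' @return an object of class `match_spec`.
#' @export
match_spec <- function(age_bin_width = 5L, require_same_sex = TRUE,
                       require_same_calendar_date = TRUE, ratio = 1L,
                       with_replacement = FALSE,
                       lookback_required_days = 450L,
                       visit_date_tolerance = 0L, seed = 1L) {
  stopifnot(age_bin_width >= 1, ratio >= 1, lookback_required_days >= 0,
            visit_date_tolerance >= 0)
  structure(list(age_bin_width = as.integer(age_bin_width),
                 require_same_sex = isTRUE(require_same_sex),
                 require_same_calendar_date = isTRUE(require_same_calendar_date),
                 ratio = as.integer(ratio),
                 with_replacement = isTRUE(with_replacement),
                 lookback_required_days = as.integer(lookback_required_days),
                 visit_date_tolerance = as.integer(visit_date_tolerance),
                 seed = as.integer(seed)),
            class = "match_spec")
}

#' Attrition record of a cohort-building step
#'
#' Every cohort constructor attaches a small table accounting for persons
#' excluded by eligibility or matching failure (no silent drops).
#'
#' @param x a `CohortTable` returned by a cohort builder.
#' @return data.table(stage, n).
#' @export
attrition <- function(x) attr(x, "attrition")

new_cohort <- function(person_id, index_date, anchor_type, match_group_id,
                       attrition_tbl) {
  out <- data.table(person_id = as.integer(person_id),
                    index_date = as.Date(index_date, origin = "1970-01-01"),
                    anchor_type = anchor_type,
                    match_group_id = as.integer(match_group_id))
  setattr(out, "attrition", attrition_tbl)
  out[]
}

#' Build the vaccinated target cohort
#'
#' One row per vaccinated person whose vaccination date admits the required
#' lookback; the index date is the vaccination date. Persons excluded for
#' insufficient lookback are counted in the attrition record.
#'
#' @param data a `population_dataset`.
#' @param spec a [match_spec()] (only `lookback_required_days` is used here).
#' @return a CohortTable: data.table(person_id, index_date, anchor_type =
#'   "vaccination", match_group_id = person_id), with an [attrition()]
#'   attribute.
#' @export
build_vaccinated_cohort <- function(data, spec = match_spec()) {
  stopifnot(inherits(data, "population_dataset"), inherits(spec, "match_spec"))
  v <- data$vaccinations
  if (nrow(v) == 0L) {
    warning("no vaccinated persons in the dataset; returning empty cohort")
    att <- data.table(stage = c("vaccinated", "lookback_eligible", "excluded_lookback"),
                      n = c(0L, 0L, 0L))
    return(new_cohort(integer(), as.Date(character()), character(), integer(), att))
  }
  ok <- as.integer(v$vaccination_date - data$observation_start) >=
    spec$lookback_required_days &
    v$vaccination_date <= data$observation_end
  att <- data.table(stage = c("vaccinated", "lookback_eligible", "excluded_lookback"),
                    n = c(nrow(v), sum(ok), sum(!ok)))
  keep <- v[ok]
  new_cohort(keep$person_id, keep$vaccination_date,
             rep("vaccination", nrow(keep)), keep$person_id, att)
}

# shared greedy matcher. candidate_lookup(index_day) must return an integer
# vector of candidate person_ids for the current stratum/date; pick_index
# resolves the matched person's comparator index day.
.greedy_match <- function(targets, persons, data, spec, anchor_type,
                          visit_mode = FALSE) {
  obs0 <- data$observation_start
  last_day <- as.integer(data$observation_end - obs0)
  lb <- spec$lookback_required_days

  t_info <- merge(targets, persons[, .(person_id, sex, age_at_start)],
                  by = "person_id", sort = FALSE)
  t_info[, age_bin := age_at_start %/% spec$age_bin_width]
  t_info[, day := as.integer(index_date - obs0)]

  cand <- persons[!person_id %in% data$vaccinations$person_id]
  cand[, age_bin := age_at_start %/% spec$age_bin_width]
  strat_key <- function(sex, bin) {
    if (spec$require_same_sex) paste(sex, bin, sep = "|") else as.character(bin)
  }

  # candidate index: person ids per stratum; for visit anchoring also person
  # ids per stratum x visit day
  pool <- new.env(parent = emptyenv())
  if (!visit_mode) {
    ck <- strat_key(cand$sex, cand$age_bin)
    for (k in unique(ck)) assign(k, cand$person_id[ck == k], envir = pool)
  } else {
    cv <- merge(data$visits, cand[, .(person_id, sex, age_bin)], by = "person_id")
    cv[, day := as.integer(visit_date - obs0)]
    cv <- cv[day >= lb & day <= last_day]
    if (spec$require_same_calendar_date) {
      ckd <- paste(strat_key(cv$sex, cv$age_bin), cv$day, sep = "@")
      spl <- split(cv$person_id, ckd)
      for (k in names(spl)) assign(k, unique(spl[[k]]), envir = pool)
    } else {
      ck <- strat_key(cv$sex, cv$age_bin)
      spl <- split(cv$person_id, ck)
      for (k in names(spl)) assign(k, unique(spl[[k]]), envir = pool)
    }
    visits_by_person <- split(as.integer(cv$day), cv$person_id)
  }

  n_pid <- max(c(persons$person_id, 0L))
  used <- rep(FALSE, n_pid)
  nT <- nrow(t_info)
  res_person <- integer(0)
  res_day <- integer(0)
  res_group <- integer(0)
  n_matched <- 0L

  withr::with_seed(spec$seed, {
    ord <- sample.int(nT)
    for (i in ord) {
      d <- t_info$day[i]
      if (d - lb < 0L || d > last_day) next  # target index must admit lookback
      avail <- NULL
      if (!visit_mode) {
        k <- strat_key(t_info$sex[i], t_info$age_bin[i])
        pids <- if (exists(k, envir = pool, inherits = FALSE)) get(k, envir = pool) else integer(0)
        avail <- pids[!used[pids]]
      } else if (spec$require_same_calendar_date) {
        base <- strat_key(t_info$sex[i], t_info$age_bin[i])
        days <- (d - spec$visit_date_tolerance):(d + spec$visit_date_tolerance)
        days <- days[days >= lb & days <= last_day]
        pids <- unlist(lapply(days, function(dd) {
          k <- paste(base, dd, sep = "@")
          if (exists(k, envir = pool, inherits = FALSE)) get(k, envir = pool) else integer(0)
        }), use.names = FALSE)
        pids <- unique(pids)
        avail <- pids[!used[pids]]
      } else {
        k <- strat_key(t_info$sex[i], t_info$age_bin[i])
        pids <- if (exists(k, envir = pool, inherits = FALSE)) get(k, envir = pool) else integer(0)
        avail <- pids[!used[pids]]
      }
      if (length(avail) < spec$ratio) next
      pick <- avail[sample.int(length(avail), spec$ratio)]
      if (!spec$with_replacement) used[pick] <- TRUE
      if (!visit_mode) {
        idx_day <- if (spec$require_same_calendar_date) rep(d, spec$ratio) else
          lb + (sample.int(last_day - lb + 1L, spec$ratio, replace = TRUE) - 1L)
      } else if (spec$require_same_calendar_date) {
        # nearest eligible visit to the target index date; ties -> earlier
        idx_day <- vapply(pick, function(p) {
          vd <- visits_by_person[[as.character(p)]]
          vd <- vd[abs(vd - d) <= spec$visit_date_tolerance]
          vd[order(abs(vd - d), vd)][1L]
        }, integer(1))
      } else {
        idx_day <- vapply(pick, function(p) {
          vd <- visits_by_person[[as.character(p)]]
          vd[sample.int(length(vd), 1L)]
        }, integer(1))
      }
      res_person <- c(res_person, pick)
      res_day <- c(res_day, idx_day)
      res_group <- c(res_group, rep(t_info$match_group_id[i], spec$ratio))
      n_matched <- n_matched + 1L
    }
  })

  att <- data.table(stage = c("targets_in", "matched", "unmatched"),
                    n = c(nT, n_matched, nT - n_matched))
  out <- new_cohort(res_person, obs0 + res_day,
                    rep(anchor_type, length(res_person)), res_group, att)
  setorder(out, match_group_id, person_id)
  out
}

#' Match unvaccinated comparators on an arbitrary date
#'
#' For each vaccinated target, greedily samples an unvaccinated person of the
#' same sex and age bin, observed with full lookback on the target's index
#' calendar date; the comparator's index date is that calendar date (it need
#' not carry any medical event). Exhausted strata leave targets unmatched
#' (recorded in attrition), never raise.
#'
#' @param targets the vaccination-anchored CohortTable from
#'   [build_vaccinated_cohort()].
#' @param data the `population_dataset` the targets were built from.
#' @param spec a [match_spec()].
#' @return comparator CohortTable (anchor_type `"matched_date"`,
#'   match_group_id = matched target's person_id), with [attrition()].
#' @export
match_arbitrary_date <- function(targets, data, spec = match_spec()) {
  stopifnot(inherits(data, "population_dataset"), inherits(spec, "match_spec"))
  .greedy_match(targets, data$persons, data, spec, "matched_date", visit_mode = FALSE)
}

#' Match unvaccinated comparators on a visit date
#'
#' As [match_arbitrary_date()], with the additional requirement that the
#' comparator has a health care visit on the target's index calendar date
#' (strict same-day by default; `visit_date_tolerance` in the
#' [match_spec()] relaxes this to the nearest visit within +/- d days). The
#' comparator's index date is that visit's date.
#'
#' @inheritParams match_arbitrary_date
#' @return comparator CohortTable (anchor_type `"matched_visit"`), with
#'   [attrition()].
#' @export
match_visit_date <- function(targets, data, spec = match_spec()) {
  stopifnot(inherits(data, "population_dataset"), inherits(spec, "match_spec"))
  .greedy_match(targets, data$persons, data, spec, "matched_visit", visit_mode = TRUE)
}

#' Self-controlled control anchors: prior date or prior visit
#'
#' For each vaccinated target, anchors a control comparison time for the
#' *same person* on a date sampled uniformly among eligible days
#' (`prior_date`) or eligible visit days (`prior_visit`) in the window
#' `[vaccination - window_days[2], vaccination - window_days[1]]` before
#' vaccination. The control index must itself admit the configured lookback;
#' persons with no eligible day (or visit) are excluded from the design and
#' counted in attrition (the caller drops the corresponding case rows, e.g.
#' via [complete_pairs()]).
#'
#' Sampling contract (stable for reproduction): persons are processed in
#' ascending `person_id` order under `withr::with_seed(seed)`, one
#' `sample.int` draw per person over the ascending vector of eligible days.
#'
#' @param targets vaccination-anchored CohortTable.
#' @param data the `population_dataset`.
#' @param mode `"prior_date"` or `"prior_visit"`.
#' @param window_days c(min, max) days before vaccination, default c(180, 450).
#' @param lookback_required_days lookback the control index must admit.
#' @param seed integer seed.
#' @return control CohortTable (anchor_type = `mode`, match_group_id = the
#'   person's own case row), with [attrition()] and a `dropped_person_ids`
#'   attribute.
#' @export
self_controlled_anchors <- function(targets, data,
                                    mode = c("prior_date", "prior_visit"),
                                    window_days = c(180L, 450L),
                                    lookback_required_days = 450L,
                                    seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "population_dataset"),
            all(targets$anchor_type == "vaccination"),
            length(window_days) == 2, window_days[1] <= window_days[2])
  obs0 <- data$observation_start
  t <- copy(targets)[order(person_id)]
  t[, day := as.integer(index_date - obs0)]

  vis <- data$visits[person_id %in% t$person_id]
  vis[, day := as.integer(visit_date - obs0)]
  visits_by_person <- split(as.integer(vis$day), vis$person_id)

  res_person <- integer(0)
  res_day <- integer(0)
  res_group <- integer(0)
  dropped <- integer(0)

  withr::with_seed(as.integer(seed), {
    for (i in seq_len(nrow(t))) {
      vd <- t$day[i]
      lo <- max(vd - as.integer(window_days[2]), as.integer(lookback_required_days))
      hi <- vd - as.integer(window_days[1])
      if (lo > hi) { dropped <- c(dropped, t$person_id[i]); next }
      if (mode == "prior_date") {
        pick <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      } else {
        vdays <- visits_by_person[[as.character(t$person_id[i])]]
        vdays <- sort(vdays[vdays >= lo & vdays <= hi])
        if (length(vdays) == 0L) { dropped <- c(dropped, t$person_id[i]); next }
        pick <- vdays[sample.int(length(vdays), 1L)]
      }
      res_person <- c(res_person, t$person_id[i])
      res_day <- c(res_day, pick)
      res_group <- c(res_group, t$match_group_id[i])
    }
  })

  att <- data.table(stage = c("targets_in", "anchored", "excluded_no_eligible_day"),
                    n = c(nrow(t), length(res_person), length(dropped)))
  out <- new_cohort(res_person, obs0 + res_day, rep(mode, length(res_person)),
                    res_group, att)
  setattr(out, "dropped_person_ids", dropped)
  out
}

#' Restrict targets to complete pairs
#'
#' Drops target rows whose match group has no comparator row (complete-pair
#' analysis): unmatched targets, or self-controlled cases whose person had no
#' eligible control day.
#'
#' @param targets target CohortTable.
#' @param comparators comparator/control CohortTable.
#' @return the subset of `targets` with a comparator, attrition attached.
#' @export
complete_pairs <- function(targets, comparators) {
  keep <- targets$match_group_id %in% comparators$match_group_id
  out <- targets[keep]
  att <- data.table(stage = c("targets_in", "paired", "dropped_unpaired"),
                    n = c(nrow(targets), sum(keep), sum(!keep)))
  setattr(out, "attrition", att)
  out[]
}
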