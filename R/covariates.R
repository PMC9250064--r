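#' Covariate universe of a dataset
#'
#' All (domain, concept) pairs observed anywhere in the dataset's events.
#' Both cohorts of a comparison share this universe, so a concept never
#' recorded for one cohort still appears with proportion 0 (absence counts
#' as 0, not missing).
#'
#' @param data a `population_dataset`.
#' @return data.table(covariate_id, domain, concept_id), sorted.
#' @export
covariate_universe <- function(data) {
  u <- unique(data$events[, .(domain, concept_id)])
  u[, covariate_id := paste0(domain, "_", concept_id)]
  setorder(u, covariate_id)
  u[, .(covariate_id, domain, concept_id)]
}

#' Extract windowed baseline covariates for a cohort
#'
#' For each covariate concept and each window: the binary statistic is the
#' fraction of cohort rows with at least one event of that concept in the
#' window (within-person duplicates counted once), with dispersion
#' `sqrt(p * (1 - p))`. The continuous covariate `visit_count` is the mean
#' and (sample) SD of the per-person number of distinct visit days in the
#' window. Day offsets are calendar-day differences `event_date -
#' index_date`; the index day itself belongs to no lookback window except
#' `day0`.
#'
#' @param cohort a CohortTable; every index date must admit the full
#'   lookback spanned by the windows.
#' @param data the `population_dataset` the cohort was drawn from.
#' @param windows a window set, default [default_windows()].
#' @param cohort_id label stamped on the output rows.
#' @return a CovariateSummary: data.table(cohort_id, window_name,
#'   covariate_id, covariate_kind, n_persons, statistic, dispersion), one
#'   row per covariate x window (plus `visit_count` per window).
#' @export
extract_covariates <- function(cohort, data, windows = default_windows(),
                               cohort_id = "cohort") {
  validate_windows(windows)
  stopifnot(inherits(data, "population_dataset"))
  empty <- data.table(cohort_id = character(), window_name = character(),
                      covariate_id = character(), covariate_kind = character(),
                      n_persons = integer(), statistic = numeric(),
                      dispersion = numeric())
  if (nrow(cohort) == 0L) {
    warning("empty cohort: returning empty covariate summary")
    return(empty)
  }
  lo_min <- min(vapply(windows, `[`, numeric(1), 1L))
  first_ok <- as.integer(cohort$index_date - data$observation_start) + lo_min >= 0
  if (!all(first_ok)) {
    stop("cohort index dates do not admit the full lookback required by the windows")
  }

  ch <- copy(cohort)[, row_id := .I]
  n <- nrow(ch)
  cid <- cohort_id
  uni <- covariate_universe(data)

  ev <- merge(ch[, .(row_id, person_id, index_date)], data$events,
              by = "person_id", allow.cartesian = TRUE)
  ev[, offset := as.integer(event_date - index_date)]
  ev[, covariate_id := paste0(domain, "_", concept_id)]
  vis <- merge(ch[, .(row_id, person_id, index_date)], data$visits,
               by = "person_id", allow.cartesian = TRUE)
  vis[, offset := as.integer(visit_date - index_date)]

  out <- vector("list", length(windows))
  for (wi in seq_along(windows)) {
    w <- windows[[wi]]
    wname <- names(windows)[wi]
    sub <- unique(ev[offset >= w[1] & offset <= w[2], .(row_id, covariate_id)])
    cnt <- sub[, .(N = .N), by = covariate_id]
    bin <- merge(uni[, .(covariate_id)], cnt, by = "covariate_id", all.x = TRUE)
    bin[is.na(N), N := 0L]
    bin[, p := N / n]
    binary_rows <- bin[, .(cohort_id = cid, window_name = wname,
                           covariate_id, covariate_kind = "binary",
                           n_persons = n, statistic = p,
                           dispersion = sqrt(p * (1 - p)))]
    vc <- vis[offset >= w[1] & offset <= w[2], .(N = uniqueN(offset)), by = row_id]
    counts <- rep(0L, n)
    if (nrow(vc)) counts[vc$row_id] <- vc$N
    cont_row <- data.table(cohort_id = cohort_id, window_name = wname,
                           covariate_id = "visit_count",
                           covariate_kind = "continuous",
                           n_persons = n, statistic = mean(counts),
                           dispersion = if (n > 1) sd(counts) else 0)
    out[[wi]] <- rbind(binary_rows, cont_row)
  }
  res <- rbindlist(out)
  setorder(res, window_name, covariate_id)
  res[]
}
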