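#' Standardized difference of two proportions
#'
#' Pooled-variance standardized mean difference for a binary covariate,
#' using Bernoulli variances:
#' `(p1 - p2) / sqrt((p1 (1 - p1) + p2 (1 - p2)) / 2)`.
#' Returns 0 whenever `p1 == p2` (including both 0 or both 1) and a
#' non-finite value (`Inf`/`-Inf`) when `p1 != p2` but the pooled variance is
#' 0 (e.g. 1 vs 0); downstream imbalance counting treats non-finite as
#' imbalanced.
#'
#' @param p1,p2 proportions in `[0, 1]` (vectorized).
#' @return numeric vector of signed SMDs.
#' @export
smd_binary <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE))
    stop("proportions must lie in [0, 1]")
  v <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
  ifelse(p1 == p2, 0, (p1 - p2) / sqrt(v))
}

#' Standardized difference of two means
#'
#' Pooled-SD standardized mean difference for a continuous covariate:
#' `(m1 - m2) / sqrt((s1^2 + s2^2) / 2)`. Returns 0 when `m1 == m2`; a
#' non-finite value when `m1 != m2` with both SDs 0.
#'
#' @param m1,m2 group means (vectorized).
#' @param s1,s2 group standard deviations, `>= 0`.
#' @return numeric vector of signed SMDs.
#' @export
smd_continuous <- function(m1, s1, m2, s2) {
  if (any(s1 < 0 | s2 < 0, na.rm = TRUE)) stop("standard deviations must be nonnegative")
  v <- (s1^2 + s2^2) / 2
  ifelse(m1 == m2, 0, (m1 - m2) / sqrt(v))
}

#' Compare two cohorts' covariate summaries
#'
#' Routes binary covariates to [smd_binary()] and continuous covariates to
#' [smd_continuous()], one row per covariate x window. Both summaries must
#' cover the same covariate universe and windows (extract both from the same
#' dataset to guarantee this).
#'
#' @param summary_target,summary_comparator CovariateSummary tables from
#'   [extract_covariates()].
#' @param comparison_id label for the comparison; defaults to
#'   `"<target> vs <comparator>"` from the summaries' cohort_id.
#' @return a BalanceTable: data.table(comparison_id, window_name,
#'   covariate_id, covariate_kind, stat_target, stat_comparator, smd). The
#'   SMD is signed (target minus comparator); swapping the arguments negates
#'   the column.
#' @export
compare_cohorts <- function(summary_target, summary_comparator,
                            comparison_id = NULL) {
  key <- c("window_name", "covariate_id", "covariate_kind")
  a <- as.data.table(summary_target)
  b <- as.data.table(summary_comparator)
  ka <- a[, key, with = FALSE][order(window_name, covariate_id)]
  kb <- b[, key, with = FALSE][order(window_name, covariate_id)]
  if (!isTRUE(all.equal(ka, kb, check.attributes = FALSE)))
    stop("mismatched covariate universes or windows between the two summaries")
  if (is.null(comparison_id)) {
    comparison_id <- paste(a$cohort_id[1], "vs", b$cohort_id[1])
  }
  m <- merge(a[, .(window_name, covariate_id, covariate_kind,
                   stat_target = statistic, sd_target = dispersion)],
             b[, .(window_name, covariate_id, covariate_kind,
                   stat_comparator = statistic, sd_comparator = dispersion)],
             by = key)
  m[, smd := NA_real_]
  m[covariate_kind == "binary", smd := smd_binary(stat_target, stat_comparator)]
  m[covariate_kind == "continuous",
    smd := smd_continuous(stat_target, sd_target, stat_comparator, sd_comparator)]
  out <- m[, .(comparison_id = comparison_id, window_name, covariate_id,
               covariate_kind, stat_target, stat_comparator, smd)]
  setorder(out, window_name, covariate_id)
  out[]
}

#' Count imbalanced covariates per comparison and window
#'
#' A covariate is imbalanced when `|SMD| >= threshold` (default rule; the
#' complementary convention is that covariates are balanced iff SMD < 0.1)
#' or when its SMD is non-finite (degenerate pooled variance with unequal
#' statistics). Non-finite SMDs are also reported separately. With
#' `rule = "gt"` the strict `|SMD| > threshold` variant is used instead.
#'
#' @param balance a BalanceTable from [compare_cohorts()].
#' @param threshold positive imbalance threshold, default 0.1.
#' @param rule `"gte"` (default, imbalanced iff `|SMD| >= threshold`) or
#'   `"gt"` (strict).
#' @return an ImbalanceReport: data.table(comparison_id, window_name,
#'   n_imbalanced, n_total, fraction, n_nonfinite). Monotone nonincreasing
#'   in `threshold`.
#' @export
count_imbalanced <- function(balance, threshold = 0.1, rule = c("gte", "gt")) {
  rule <- match.arg(rule)
  stopifnot(threshold > 0)
  b <- copy(as.data.table(balance))
  b[, imb := !is.finite(smd) |
      (if (rule == "gte") abs(smd) >= threshold else abs(smd) > threshold)]
  out <- b[, .(n_imbalanced = sum(imb), n_total = .N,
               fraction = sum(imb) / .N,
               n_nonfinite = sum(!is.finite(smd))),
           by = .(comparison_id, window_name)]
  setorder(out, comparison_id, window_name)
  out[]
}

#' Plot-ready covariate proportion scatter data
#'
#' One row per binary covariate x window with the two cohorts' proportions —
#' the data behind proportion-vs-proportion scatter panels in which each dot
#' is a covariate and departures from the diagonal show anchoring effects.
#'
#' @inheritParams compare_cohorts
#' @return data.table(covariate_id, window_name, proportion_target,
#'   proportion_comparator).
#' @export
export_scatter <- function(summary_target, summary_comparator) {
  a <- as.data.table(summary_target)[covariate_kind == "binary"]
  b <- as.data.table(summary_comparator)[covariate_kind == "binary"]
  out <- merge(a[, .(covariate_id, window_name, proportion_target = statistic)],
               b[, .(covariate_id, window_name, proportion_comparator = statistic)],
               by = c("covariate_id", "window_name"))
  setorder(out, window_name, covariate_id)
  out[]
}

#' Render an imbalance report as a table-shaped matrix
#'
#' One row per comparison, one column per window, cells formatted as
#' `"n/N (pct)"` — the conventional layout for reporting counts of
#' covariates crossing the balance threshold per target-comparator pair.
#'
#' @param report an ImbalanceReport from [count_imbalanced()].
#' @param markdown if TRUE, return a character vector of markdown table
#'   lines instead of a wide data.table.
#' @return wide data.table of formatted cells, or markdown lines.
#' @export
render_imbalance_matrix <- function(report, markdown = FALSE) {
  r <- copy(as.data.table(report))
  r[, cell := sprintf("%d/%d (%.1f%%)", n_imbalanced, n_total, 100 * fraction)]
  wide <- dcast(r, comparison_id ~ window_name, value.var = "cell")
  if (!markdown) return(wide[])
  hdr <- names(wide)
  c(paste0("| ", paste(hdr, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"),
    vapply(seq_len(nrow(wide)), function(i) {
      paste0("| ", paste(unlist(wide[i]), collapse = " | "), " |")
    }, character(1)))
}
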