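#!/usr/bin/env Rscript
# Step 2: anchor the comparators.
#
# For each simulated regime, builds the vaccinated target cohort and the four
# anchored comparators: matched arbitrary-date and matched visit-date
# (cohort design), and prior-date / prior-visit controls for the same
# persons (self-controlled design). Writes cohort tables and attrition
# accounting under results/cohorts/.

suppressPackageStartupMessages({
  library(anchorsim)
  library(data.table)
})

seed <- 2026L
dir.create("results/cohorts", recursive = TRUE, showWarnings = FALSE)

for (preset in c("influenza_like", "covid_like")) {
  pop <- read_population(file.path("scratch", "data", preset), format = "csv")
  spec <- match_spec(seed = seed)
  targets <- build_vaccinated_cohort(pop, spec)
  cat(sprintf("%s: %d eligible vaccinated targets\n", preset, nrow(targets)))

  cohorts <- list(
    target = targets,
    cohort_arbitrary_date = match_arbitrary_date(targets, pop, spec),
    cohort_visit = match_visit_date(targets, pop, spec),
    self_prior_date = self_controlled_anchors(targets, pop, "prior_date", seed = seed),
    self_prior_visit = self_controlled_anchors(targets, pop, "prior_visit", seed = seed))

  att <- rbindlist(lapply(names(cohorts), function(nm) {
    a <- attrition(cohorts[[nm]])
    if (is.null(a)) return(NULL)
    copy(a)[, cohort := nm][]
  }), use.names = TRUE)
  for (nm in names(cohorts)) {
    fwrite(cohorts[[nm]], sprintf("results/cohorts/%s_%s.csv", preset, nm))
    n_att <- attrition(cohorts[[nm]])
    if (nm != "target") {
      cat(sprintf("  %-22s %6d rows (%s)\n", nm, nrow(cohorts[[nm]]),
                  paste(sprintf("%s=%d", n_att$stage, n_att$n), collapse = ", ")))
    }
  }
  fwrite(att, sprintf("results/cohorts/%s_attrition.csv", preset))
}
cat("wrote cohort and attrition tables under results/cohorts/\n")
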