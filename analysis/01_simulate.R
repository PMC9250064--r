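#!/usr/bin/env Rscript
# Step 1: simulate the two vaccination regimes.
#
# Generates synthetic EHR populations (n = 20,000 each) under the
# influenza-like regime (visit-coupled vaccination, kappa = 0.558, sicker
# people vaccinated more often) and the COVID-like regime (visit-decoupled,
# kappa = 0.027, healthier people vaccinated more often). The raw tables go
# to scratch/data/ (they are large); a compact per-regime summary goes to
# results/.

suppressPackageStartupMessages({
  library(anchorsim)
  library(data.table)
})

seed <- 2026L
n <- 20000L
dir.create("results", showWarnings = FALSE)

summaries <- list()
for (preset in c("influenza_like", "covid_like")) {
  cfg <- make_scenario(preset, n_persons = n, seed = seed)
  pop <- generate_population(cfg)
  out <- file.path("scratch", "data", preset)
  write_population(pop, out, format = "csv")
  write_scenario(cfg, file.path(out, "scenario_config.yaml"))

  vac <- pop$vaccinations
  has_visit <- !is.na(pop$visits[vac,
    on = c("person_id", visit_date = "vaccination_date"),
    nomatch = NA, which = TRUE])
  is_vac <- pop$persons$person_id %in% vac$person_id
  summaries[[preset]] <- data.table(
    scenario = preset,
    n_persons = n,
    n_vaccinated = nrow(vac),
    pct_vaccinated = round(100 * nrow(vac) / n, 1),
    pct_sameday_visit = round(100 * mean(has_visit), 1),
    mean_burden_vaccinated = round(mean(pop$persons$latent_burden[is_vac]), 3),
    mean_burden_unvaccinated = round(mean(pop$persons$latent_burden[!is_vac]), 3),
    n_visits = nrow(pop$visits),
    n_events = nrow(pop$events))
  cat(sprintf(
    "%s: %d/%d vaccinated (%.1f%%); %.1f%% had a visit on the vaccination day; mean burden vacc %.2f vs unvacc %.2f\n",
    preset, nrow(vac), n, 100 * nrow(vac) / n, 100 * mean(has_visit),
    mean(pop$persons$latent_burden[is_vac]),
    mean(pop$persons$latent_burden[!is_vac])))
}

fwrite(rbindlist(summaries), "results/01_scenario_summary.csv")
cat("wrote results/01_scenario_summary.csv and raw tables under scratch/data/\n")
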