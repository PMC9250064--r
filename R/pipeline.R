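#' Experiment specification
#'
#' Bundles everything a full anchoring experiment needs: the data-generating
#' scenario, which anchoring designs to run, the matching specification, the
#' imbalance threshold and the master seed (propagated to every stochastic
#' stage).
#'
#' @param scenario a `scenario_config` or a preset name understood by
#'   [make_scenario()].
#' @param designs subset of `"cohort_arbitrary_date"`, `"cohort_visit"`,
#'   `"self_prior_date"`, `"self_prior_visit"` (at least one).
#' @param match a [match_spec()]; its seed is overridden by `seed`.
#' @param threshold imbalance threshold on |SMD|, default 0.1.
#' @param windows a window set, default [default_windows()].
#' @param output_dir directory for run artifacts, or NULL for in-memory only.
#' @param seed master integer seed.
#' @return an object of class `experiment_spec`.
#' @export
experiment_spec <- function(scenario = "null",
                            designs = c("cohort_arbitrary_date", "cohort_visit",
                                        "self_prior_date", "self_prior_visit"),
                            match = match_spec(), threshold = 0.1,
                            windows = default_windows(),
                            output_dir = NULL, seed = 1L) {
  all_designs <- c("cohort_arbitrary_date", "cohort_visit",
                   "self_prior_date", "self_prior_visit")
  designs <- match.arg(designs, all_designs, several.ok = TRUE)
  stopifnot(length(designs) >= 1, threshold > 0)
  validate_windows(windows)
  structure(list(scenario = scenario, designs = designs, match = match,
                 threshold = threshold, windows = windows,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "experiment_spec")
}

.stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run an end-to-end anchoring experiment
#'
#' Generates (or accepts) a population, builds the vaccinated target cohort,
#' and for each requested design builds the anchored comparator, restricts
#' targets to complete pairs, extracts windowed covariates for both sides,
#' computes the balance table, the imbalance report and the scatter export.
#' When `spec$output_dir` is set, all tables, the resolved configuration and
#' a JSON run manifest are written there.
#'
#' @param spec an [experiment_spec()].
#' @param data optionally, a pre-generated `population_dataset` (skips
#'   generation; the scenario in `spec` is then ignored).
#' @param verbose log stage boundaries with row counts.
#' @return (invisibly) a list of class `anchor_experiment` with elements
#'   `manifest`, `config`, `data`, `targets`, `comparators`, `summaries`,
#'   `balance`, `imbalance`, `scatter`, `attrition`.
#' @export
run_experiment <- function(spec, data = NULL, verbose = TRUE) {
  stopifnot(inherits(spec, "experiment_spec"))
  config <- NULL
  if (is.null(data)) {
    config <- if (is.character(spec$scenario)) {
      make_scenario(spec$scenario, seed = spec$seed)
    } else {
      cfg <- spec$scenario
      cfg$seed <- spec$seed
      validate_scenario(cfg)
    }
    .stage_log(verbose, "simulate: generating %d persons (seed %d)",
               config$n_persons, config$seed)
    data <- generate_population(config)
  } else {
    config <- data$config
  }
  .stage_log(verbose, "simulate: %d visits, %d events, %d vaccinated",
             nrow(data$visits), nrow(data$events), nrow(data$vaccinations))

  mspec <- spec$match
  mspec$seed <- spec$seed
  targets <- build_vaccinated_cohort(data, mspec)
  .stage_log(verbose, "cohorts: %d eligible vaccinated targets", nrow(targets))

  comparators <- list()
  summaries <- list()
  balance <- list()
  scatter <- list()
  attr_list <- list(targets = attrition(targets))
  imb <- list()

  for (design in spec$designs) {
    comp <- switch(design,
      cohort_arbitrary_date = match_arbitrary_date(targets, data, mspec),
      cohort_visit = match_visit_date(targets, data, mspec),
      self_prior_date = self_controlled_anchors(
        targets, data, "prior_date",
        lookback_required_days = mspec$lookback_required_days, seed = spec$seed),
      self_prior_visit = self_controlled_anchors(
        targets, data, "prior_visit",
        lookback_required_days = mspec$lookback_required_days, seed = spec$seed)
    )
    tpair <- complete_pairs(targets, comp)
    .stage_log(verbose, "%s: %d comparator rows, %d complete pairs",
               design, nrow(comp), nrow(tpair))
    st <- extract_covariates(tpair, data, spec$windows,
                             cohort_id = paste0(design, "_target"))
    sc <- extract_covariates(comp, data, spec$windows,
                             cohort_id = paste0(design, "_comparator"))
    bal <- compare_cohorts(st, sc, comparison_id = design)
    rep_i <- count_imbalanced(bal, spec$threshold)
    .stage_log(verbose, "%s: imbalanced day0 %d/%d",
               design, rep_i[window_name == "day0"]$n_imbalanced,
               rep_i[window_name == "day0"]$n_total)
    comparators[[design]] <- comp
    summaries[[paste0(design, "_target")]] <- st
    summaries[[paste0(design, "_comparator")]] <- sc
    balance[[design]] <- bal
    scatter[[design]] <- export_scatter(st, sc)
    attr_list[[design]] <- attrition(comp)
    imb[[design]] <- rep_i
  }
  imbalance <- rbindlist(imb)

  manifest <- list(
    scenario = if (is.character(spec$scenario)) spec$scenario else "custom",
    seed = spec$seed,
    threshold = spec$threshold,
    n_persons = nrow(data$persons),
    n_vaccinated = nrow(data$vaccinations),
    n_targets = nrow(targets),
    designs = spec$designs,
    windows = lapply(spec$windows, as.integer),
    attrition = lapply(attr_list, function(a) as.list(stats::setNames(a$n, a$stage))),
    imbalance = split(imbalance[, .(window_name, n_imbalanced, n_total, fraction)],
                      imbalance$comparison_id),
    paths = list()
  )

  if (!is.null(spec$output_dir)) {
    manifest$paths <- .write_run_artifacts(spec, config, data, targets,
                                           comparators, summaries, balance,
                                           imbalance, scatter, manifest)
  }

  out <- structure(list(manifest = manifest, config = config, data = data,
                        targets = targets, comparators = comparators,
                        summaries = summaries, balance = balance,
                        imbalance = imbalance, scatter = scatter,
                        attrition = attr_list),
                   class = "anchor_experiment")
  invisible(out)
}

.write_run_artifacts <- function(spec, config, data, targets, comparators,
                                 summaries, balance, imbalance, scatter,
                                 manifest) {
  dir.create(spec$output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(spec$output_dir, ...)
  paths <- list()
  if (!is.null(config)) {
    write_scenario(config, p("scenario_config.yaml"))
    paths$config <- p("scenario_config.yaml")
  }
  fwrite(targets, p("cohort_target.csv"))
  paths$targets <- p("cohort_target.csv")
  for (design in names(comparators)) {
    fwrite(comparators[[design]], p(sprintf("cohort_%s.csv", design)))
    fwrite(balance[[design]], p(sprintf("balance_%s.csv", design)))
    fwrite(scatter[[design]], p(sprintf("scatter_%s.csv", design)))
  }
  fwrite(imbalance, p("imbalance_report.csv"))
  paths$imbalance <- p("imbalance_report.csv")
  writeLines(render_imbalance_matrix(count_imbalanced(rbindlist(balance),
                                                      spec$threshold),
                                     markdown = TRUE),
             p("imbalance_matrix.md"))
  paths$imbalance_matrix <- p("imbalance_matrix.md")
  jsonlite::write_json(manifest[names(manifest) != "paths"],
                       p("manifest.json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths$manifest <- p("manifest.json")
  paths
}

#' Null-scenario calibration of the imbalance fraction
#'
#' Repeats the null experiment (random vaccination, background visit
#' coupling) over independent seeds and collects the fraction of covariates
#' with `|SMD| >= threshold` in every window. Under the null, anchoring
#' introduces no systematic difference, so these fractions are bounded by
#' sampling error at the simulated cohort size.
#'
#' @param n_seeds number of independent replicates.
#' @param n_persons persons per replicate.
#' @param base_seed replicate i uses seed `base_seed + i`.
#' @param design which anchoring design to calibrate (default arbitrary date).
#' @param threshold imbalance threshold.
#' @return data.table(seed, window_name, n_imbalanced, n_total, fraction).
#' @export
run_null_calibration <- function(n_seeds = 20L, n_persons = 4000L,
                                 base_seed = 100L,
                                 design = "cohort_arbitrary_date",
                                 threshold = 0.1) {
  out <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    s <- as.integer(base_seed + i)
    cfg <- make_scenario("null", n_persons = n_persons, seed = s)
    res <- run_experiment(experiment_spec(cfg, designs = design,
                                          threshold = threshold, seed = s),
                          verbose = FALSE)
    out[[i]] <- copy(res$imbalance)[, seed := s]
  }
  rbindlist(out)[, .(seed, window_name, n_imbalanced, n_total, fraction)]
}

#' @export
print.anchor_experiment <- function(x, ...) {
  cat("<anchor_experiment>\n")
  cat(sprintf("  scenario: %s, seed: %d, persons: %d, targets: %d\n",
              x$manifest$scenario, x$manifest$seed, x$manifest$n_persons,
              x$manifest$n_targets))
  cat("  imbalanced covariates (n/N) by design and window:\n")
  m <- render_imbalance_matrix(x$imbalance)
  print(m, row.names = FALSE)
  invisible(x)
}
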