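#' Write a population dataset as flat tables
#'
#' Writes `persons`, `visits`, `events` and `vaccinations` plus a small
#' `meta.yaml` (observation period) to a directory, as CSV (dates in
#' ISO-8601) or as Parquet columnar files (requires the arrow package).
#'
#' @param pop a `population_dataset`.
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"parquet"`.
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  stopifnot(inherits(pop, "population_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("persons", "visits", "events", "vaccinations")
  if (format == "csv") {
    for (tb in tables) fwrite(pop[[tb]], file.path(dir, paste0(tb, ".csv")))
  } else {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("parquet export requires the 'arrow' package")
    for (tb in tables)
      arrow::write_parquet(pop[[tb]], file.path(dir, paste0(tb, ".parquet")))
  }
  yaml::write_yaml(list(observation_start = format(pop$observation_start),
                        observation_end = format(pop$observation_end)),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a population dataset written by [write_population()]
#'
#' @param dir directory containing the tables and `meta.yaml`.
#' @param format `"csv"` or `"parquet"`.
#' @return a validated `population_dataset` (config is NULL).
#' @export
read_population <- function(dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  rd <- function(tb) {
    if (format == "csv") {
      out <- fread(file.path(dir, paste0(tb, ".csv")))
    } else {
      if (!requireNamespace("arrow", quietly = TRUE))
        stop("parquet import requires the 'arrow' package")
      out <- as.data.table(arrow::read_parquet(file.path(dir, paste0(tb, ".parquet"))))
    }
    for (col in intersect(names(out), c("visit_date", "event_date", "vaccination_date")))
      out[, (col) := as.Date(get(col))]
    out
  }
  population_dataset(rd("persons"), rd("visits"), rd("events"), rd("vaccinations"),
                     as.Date(meta$observation_start), as.Date(meta$observation_end))
}

#' Serialize a scenario configuration to YAML
#'
#' Round-trippable: [read_scenario()] reconstructs an identical validated
#' `scenario_config` (dates and integer fields restored to their classes).
#'
#' @param config a `scenario_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(config, path) {
  validate_scenario(config)
  x <- unclass(config)
  x$observation_start <- format(x$observation_start)
  x$observation_end <- format(x$observation_end)
  x$vaccination_window <- format(x$vaccination_window)
  x$age_distribution <- list(age = x$age_distribution$age,
                             prob = x$age_distribution$prob)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Read a scenario configuration written by [write_scenario()]
#'
#' @param path YAML file path.
#' @return a validated `scenario_config`.
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  x$observation_start <- as.Date(x$observation_start)
  x$observation_end <- as.Date(x$observation_end)
  x$vaccination_window <- as.Date(unlist(x$vaccination_window))
  x$age_distribution <- data.frame(age = as.integer(x$age_distribution$age),
                                   prob = as.numeric(x$age_distribution$prob))
  do.call(scenario_config, x)
}
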