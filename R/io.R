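# CSV readers/writers for the parameter tables and YAML scenario files.

world_files <- function() {
  c(population = "population.csv", disease_epi = "disease_epi.csv",
    bmi = "bmi_params.csv", rr = "rr_table.csv",
    disability = "disability_weights.csv", costs = "disease_costs.csv")
}

#' Write a world to a directory of CSV files
#'
#' Serialises all six parameter tables (population, disease epidemiology,
#' BMI parameters, relative risks, disability weights, disease costs)
#' plus a small `world.yaml` carrying scalars.
#'
#' @param world A `pmslt_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "pmslt_world"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- world_files()
  for (nm in names(files)) {
    readr::write_csv(world[[nm]], file.path(dir, files[[nm]]))
  }
  yaml::write_yaml(list(baseline_yld = world$baseline_yld),
                   file.path(dir, "world.yaml"))
  invisible(dir)
}

#' Load a world from a directory of CSV files
#'
#' Reads and validates the six parameter tables written by
#' [write_world()].  Invariant violations (negative rates, mortality
#' outside (0,1), RR below 0, costs below 0) raise errors naming the
#' offending table.
#'
#' @param dir Directory containing the CSV files.
#' @return A `pmslt_world`.
#' @export
load_world <- function(dir) {
  files <- world_files()
  paths <- file.path(dir, files)
  missing <- files[!file.exists(paths)]
  if (length(missing)) {
    abort(paste0("missing world file(s): ", paste(missing, collapse = ", ")))
  }
  spec <- list(
    population = readr::cols(
      sex = readr::col_character(), age_lo = readr::col_integer(),
      age_group = readr::col_character(), count = readr::col_double(),
      mortality_rate = readr::col_double()),
    disease_epi = readr::cols(
      disease = readr::col_character(), sex = readr::col_character(),
      age_lo = readr::col_integer(), incidence = readr::col_double(),
      case_fatality = readr::col_double(), remission = readr::col_double()),
    bmi = readr::cols(
      sex = readr::col_character(), age_lo = readr::col_integer(),
      mean_bmi = readr::col_double(), sd_bmi = readr::col_double(),
      mean_height = readr::col_double()),
    rr = readr::cols(
      disease = readr::col_character(), sex = readr::col_character(),
      age_lo = readr::col_double(), age_hi = readr::col_double(),
      rr = readr::col_double(), lo95 = readr::col_double(),
      hi95 = readr::col_double()),
    disability = readr::cols(
      disease = readr::col_character(), sex = readr::col_character(),
      weight = readr::col_double()),
    costs = readr::cols(
      disease = readr::col_character(), sex = readr::col_character(),
      age_lo = readr::col_integer(), cost = readr::col_double(),
      basis = readr::col_character())
  )
  tabs <- purrr::imap(spec, function(cs, nm) {
    tb <- readr::read_csv(file.path(dir, files[[nm]]), col_types = cs)
    prob <- readr::problems(tb)
    if (nrow(prob)) {
      abort(sprintf("%s: %d parse problem(s), first at row %d",
                    files[[nm]], nrow(prob), prob$row[1]))
    }
    tb
  })
  validate_population(tabs$population)
  validate_disease_epi(tabs$disease_epi,
                       diseases = unique(tabs$disease_epi$disease))
  if (any(tabs$rr$rr < 0)) abort("rr_table.csv: rr must be >= 0")
  if (any(tabs$bmi$sd_bmi <= 0)) abort("bmi_params.csv: sd_bmi must be > 0")
  if (any(tabs$costs$cost < 0)) abort("disease_costs.csv: cost must be >= 0")
  if (any(tabs$disability$weight < 0 | tabs$disability$weight > 1)) {
    abort("disability_weights.csv: weights must lie in [0, 1]")
  }
  meta_path <- file.path(dir, "world.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  world <- c(tabs, list(baseline_yld = meta$baseline_yld %||% 0.10,
                        config = NULL))
  class(world) <- "pmslt_world"
  world
}

#' Load a scenario from a YAML file
#'
#' Reads scenario keys (`drug`, `discount_rate`, `uptake`,
#' `regain_rate_kg_per_month` or a preset name under `regain_rate`,
#' `regain_mode`, `permanent_fraction`, `utility_per_bmi_unit`,
#' `disease_free_baseline`, `age_range`, `threshold`) and builds a
#' [scenario_config()]; unknown keys raise an error.
#'
#' @param path Path to a YAML file.
#' @return A `pmslt_scenario`.
#' @export
load_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$regain_rate_kg_per_month)) {
    y$regain_rate <- y$regain_rate_kg_per_month
    y$regain_rate_kg_per_month <- NULL
  }
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    abort(paste0("unknown scenario key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(scenario_config, y)
}

#' Write run results to disk
#'
#' Emits `results.csv` (per-perspective summary) and `results.json`
#' (aggregate DALYs, costs, ICERs) for a deterministic run or a PSA.
#'
#' @param x A `pmslt_run` or `pmslt_cea`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tb <- tidy(x)
  readr::write_csv(tb, file.path(dir, "results.csv"))
  jsonlite::write_json(as.list(glance(x)), file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
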