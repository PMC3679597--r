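#' Read the disease table
#'
#' Parses a CSV of clinically important diseases, one row per disease.
#' Expected columns: `disease_id`, `name`, `transmission`, `agent`,
#' `worldwide`, `endemic_countries` (";"-delimited ISO 3166-1 alpha-3
#' codes, empty for worldwide diseases), `pubmed_hits`,
#' `prevalence_records_per_country` (empty if never surveyed
#' systematically), `reservoir_or_vector_bounded`, `option_override`
#' (1-5 or empty), `override_note`. An optional `r0_annotation` column is
#' carried through verbatim and never computed on.
#'
#' Unknown transmission or agent labels are an error naming the offending
#' rows; structural invariants that span tables (referential integrity)
#' are checked by [validate_corpus()].
#'
#' @param path Path to a diseases CSV file.
#' @return A tibble with `endemic_countries` as a list-column of
#'   character vectors.
#' @seealso [read_maps()], [read_population()], [load_corpus()]
#' @export
read_diseases <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    disease_id = readr::col_character(),
    name = readr::col_character(),
    transmission = readr::col_character(),
    agent = readr::col_character(),
    worldwide = readr::col_logical(),
    endemic_countries = readr::col_character(),
    pubmed_hits = readr::col_double(),
    prevalence_records_per_country = readr::col_double(),
    reservoir_or_vector_bounded = readr::col_logical(),
    option_override = readr::col_integer(),
    override_note = readr::col_character(),
    .default = readr::col_character()
  ), na = c("", "NA"), progress = FALSE, show_col_types = FALSE)
  required <- c("disease_id", "name", "transmission", "agent", "worldwide",
                "endemic_countries", "pubmed_hits",
                "prevalence_records_per_country",
                "reservoir_or_vector_bounded", "option_override",
                "override_note")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("diseases file %s is missing column(s): %s",
                  path, paste(missing_cols, collapse = ", ")),
          class = "cartoaudit_schema_error")
  }
  assert_enum(df$transmission, transmission_classes(), "transmission", path)
  assert_enum(df$agent, agent_classes(), "agent", path)
  df$endemic_countries <- split_codes(df$endemic_countries)
  if (!"r0_annotation" %in% names(df)) df$r0_annotation <- NA_character_
  df[c(required, "r0_annotation")]
}

#' Read the map-evidence table
#'
#' Parses a CSV of previously published maps, one row per map of a
#' disease, its vector or its reservoir. Expected columns: `map_id`,
#' `disease_id`, `target` (disease/vector/reservoir), `year_known`,
#' `most_recent_year`, `multi_period` (country-level estimates surveyed
#' across different time periods), `diagnostic`, `serology_support`,
#' `geo`, `method`, `countries_covered` (";"-delimited codes),
#' `citation`.
#'
#' @param path Path to a maps CSV file.
#' @return A tibble with `countries_covered` as a list-column.
#' @export
read_maps <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    map_id = readr::col_character(),
    disease_id = readr::col_character(),
    target = readr::col_character(),
    year_known = readr::col_logical(),
    most_recent_year = readr::col_integer(),
    multi_period = readr::col_logical(),
    diagnostic = readr::col_character(),
    serology_support = readr::col_logical(),
    geo = readr::col_character(),
    method = readr::col_character(),
    countries_covered = readr::col_character(),
    citation = readr::col_character()
  ), na = c("", "NA"), progress = FALSE, show_col_types = FALSE)
  required <- c("map_id", "disease_id", "target", "year_known",
                "most_recent_year", "multi_period", "diagnostic",
                "serology_support", "geo", "method", "countries_covered",
                "citation")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("maps file %s is missing column(s): %s",
                  path, paste(missing_cols, collapse = ", ")),
          class = "cartoaudit_schema_error")
  }
  assert_enum(df$target, map_targets(), "target", path)
  assert_enum(df$diagnostic, diagnostic_categories(), "diagnostic", path)
  assert_enum(df$geo, geo_categories(), "geo", path)
  assert_enum(df$method, map_methods(), "method", path)
  df$countries_covered <- split_codes(df$countries_covered)
  df[required]
}

#' Read the country population table
#'
#' Parses a CSV with columns `country_code` and `population` (persons).
#' The table's codes double as the territory list against which endemic
#' country sets are resolved; a national population is the unit in which
#' a map's geographic scope is measured.
#'
#' @param path Path to a population CSV file.
#' @return A tibble with columns `country_code` and `population`.
#' @export
read_population <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    country_code = readr::col_character(),
    population = readr::col_double()
  ), na = c("", "NA"), progress = FALSE, show_col_types = FALSE)
  if (!all(c("country_code", "population") %in% names(df))) {
    abort(sprintf("population file %s must have columns country_code, population",
                  path), class = "cartoaudit_schema_error")
  }
  df[c("country_code", "population")]
}

#' Load and validate a full audit corpus
#'
#' Reads the three input tables and establishes referential integrity:
#' every map must cite a disease present in the corpus and every country
#' code used by a disease or map must resolve against the population
#' table. Any violation aborts with the record keys and rule names; use
#' [validate_corpus()] directly to collect violations as data instead.
#'
#' @param diseases_path,maps_path,population_path CSV file paths.
#' @return A list of class `carto_corpus` with elements `diseases`,
#'   `maps` and `population`.
#' @examples
#' corpus <- generate_corpus(generator_params(n_diseases = 5, seed = 1))
#' dir <- tempfile(); dir.create(dir)
#' write_corpus(corpus, dir)
#' reloaded <- load_corpus(file.path(dir, "diseases.csv"),
#'                         file.path(dir, "maps.csv"),
#'                         file.path(dir, "population.csv"))
#' nrow(reloaded$diseases)
#' @export
load_corpus <- function(diseases_path, maps_path, population_path) {
  corpus <- new_corpus(read_diseases(diseases_path),
                       read_maps(maps_path),
                       read_population(population_path))
  violations <- validate_corpus(corpus)
  if (nrow(violations) > 0) {
    abort(paste0(
      "corpus failed validation:\n",
      paste(sprintf("  [%s] %s: %s", violations$rule, violations$record_id,
                    violations$message), collapse = "\n")
    ), class = "cartoaudit_validation_error")
  }
  corpus
}

#' Assemble a corpus from in-memory tables
#'
#' @param diseases,maps,population Tibbles in the shapes produced by
#'   [read_diseases()], [read_maps()] and [read_population()].
#' @return A list of class `carto_corpus`.
#' @export
new_corpus <- function(diseases, maps, population) {
  structure(list(diseases = diseases, maps = maps, population = population),
            class = "carto_corpus")
}

#' @export
print.carto_corpus <- function(x, ...) {
  cat("<carto_corpus>\n")
  cat("  diseases:  ", nrow(x$diseases), "\n")
  cat("  maps:      ", nrow(x$maps), "\n")
  cat("  territories:", nrow(x$population), "\n")
  invisible(x)
}

#' Write a corpus back to its three CSV files
#'
#' Inverse of [load_corpus()]: writes `diseases.csv`, `maps.csv` and
#' `population.csv` under `dir` with fixed column order, ";"-joined
#' list cells and empty strings for missing values, so that loading the
#' written files reproduces the corpus field by field.
#'
#' @param corpus A `carto_corpus`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- corpus$diseases
  d$endemic_countries <- join_codes(d$endemic_countries)
  d$r0_annotation <- NULL
  m <- corpus$maps
  m$countries_covered <- join_codes(m$countries_covered)
  paths <- c(diseases = file.path(dir, "diseases.csv"),
             maps = file.path(dir, "maps.csv"),
             population = file.path(dir, "population.csv"))
  readr::write_csv(d, paths[["diseases"]], na = "", progress = FALSE)
  readr::write_csv(m, paths[["maps"]], na = "", progress = FALSE)
  readr::write_csv(corpus$population, paths[["population"]], na = "",
                   progress = FALSE)
  invisible(paths)
}

#' The shipped territory list
#'
#' An editable 275-entry list of country and territory codes: the 249
#' officially assigned ISO 3166-1 alpha-3 codes plus 26 codes from the
#' user-assigned range (`XAA`-`XAZ`) standing in for territories that
#' clinical databases distinguish beyond the ISO list. The `synthetic`
#' column marks the user-assigned block. Pass a different table to the
#' generator or to [thumbnail_endemicity()] to override.
#'
#' @return A tibble with columns `country_code` and `synthetic`.
#' @export
default_territories <- function() {
  path <- system.file("extdata", "territories.csv", package = "cartoaudit",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    country_code = readr::col_character(),
    synthetic = readr::col_logical()
  ), progress = FALSE, show_col_types = FALSE)
}

#' Write score and summary outputs
#'
#' Writes `scores.csv` (every score breakdown, fixed column order,
#' half-point subscores printed with one decimal, ratios with four and
#' metascores with two), `summary.json` (the corpus summary) and
#' `radial.csv` (the best-metascore-per-disease series, descending).
#' Output bytes are a pure function of the inputs.
#'
#' @param scores Tibble of score breakdowns from [score_corpus()].
#' @param summary A `carto_summary` from [summarize_corpus()].
#' @param radial Radial series tibble from [radial_series()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a manifest tibble with columns `file`, `path`,
#'   `md5`.
#' @export
write_outputs <- function(scores, summary, radial, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  scores_path <- file.path(out_dir, "scores.csv")
  summary_path <- file.path(out_dir, "summary.json")
  radial_path <- file.path(out_dir, "radial.csv")

  fmt <- tibble::tibble(
    map_id = scores$map_id,
    disease_id = scores$disease_id,
    contemporariness = sprintf("%.1f", scores$contemporariness),
    diagnostic = sprintf("%.1f", scores$diagnostic),
    geopositional = sprintf("%.1f", scores$geopositional),
    quality = sprintf("%.1f", scores$quality),
    scope_pct = sprintf("%.2f", scores$scope_pct),
    option_used = scores$option_used,
    option_potential = scores$option_potential,
    option_ratio = sprintf("%.4f", scores$option_ratio),
    metascore = sprintf("%.2f", scores$metascore),
    satisfactory = scores$satisfactory
  )
  readr::write_csv(fmt, scores_path, na = "", progress = FALSE)

  jsonlite::write_json(unclass(summary), summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  rad <- tibble::tibble(
    disease_id = radial$disease_id,
    best_metascore = sprintf("%.2f", radial$best_metascore)
  )
  readr::write_csv(rad, radial_path, na = "", progress = FALSE)

  paths <- c(scores_path, summary_path, radial_path)
  invisible(tibble::tibble(
    file = basename(paths),
    path = paths,
    md5 = unname(tools::md5sum(paths))
  ))
}

# ";"-delimited cell <-> character vector helpers
split_codes <- function(x) {
  lapply(x, function(cell) {
    if (is.na(cell) || !nzchar(cell)) character(0)
    else strsplit(cell, ";", fixed = TRUE)[[1]]
  })
}

join_codes <- function(x) {
  vapply(x, function(codes) paste(codes, collapse = ";"), character(1))
}
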