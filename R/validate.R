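#' Collect corpus validation violations
#'
#' Checks every record-level invariant and cross-table constraint and
#' returns the violations as data rather than raising: duplicate keys,
#' non-worldwide diseases with empty endemic sets, duplicated country
#' codes within a set, negative or missing counts, out-of-range expert
#' overrides, unknown category labels, temporal-evidence consistency
#' (a most recent year is present exactly when the year is known, and a
#' multi-period country database implies a known year), the serology
#' half-point being attached only to survey/confirmed-case evidence,
#' non-positive populations, and referential integrity from maps to
#' diseases and from every country code to the population table.
#'
#' @param corpus A `carto_corpus`, or a diseases tibble when `maps` and
#'   `population` are supplied separately.
#' @param maps,population Optional tibbles when `corpus` is a diseases
#'   tibble.
#' @return A tibble with columns `record_id`, `rule`, `message`; zero
#'   rows when the corpus is valid.
#' @examples
#' corpus <- generate_corpus(generator_params(n_diseases = 10, seed = 1))
#' nrow(validate_corpus(corpus))
#' @export
validate_corpus <- function(corpus, maps = NULL, population = NULL) {
  if (inherits(corpus, "carto_corpus")) {
    diseases <- corpus$diseases
    maps <- corpus$maps
    population <- corpus$population
  } else {
    diseases <- corpus
  }
  v <- list()
  add <- function(record_id, rule, message) {
    v[[length(v) + 1]] <<- tibble::tibble(
      record_id = as.character(record_id), rule = rule, message = message)
  }

  # --- diseases -------------------------------------------------------
  if (!is.null(diseases) && nrow(diseases) > 0) {
    dup <- diseases$disease_id[duplicated(diseases$disease_id)]
    for (id in unique(dup)) {
      add(id, "disease-id-duplicate",
          sprintf("disease_id '%s' occurs more than once", id))
    }
    for (i in seq_len(nrow(diseases))) {
      id <- diseases$disease_id[i]
      endemic <- diseases$endemic_countries[[i]]
      if (isFALSE(diseases$worldwide[i]) && length(endemic) == 0) {
        add(id, "endemic-set-empty",
            "non-worldwide disease has no endemic countries")
      }
      if (anyDuplicated(endemic)) {
        add(id, "endemic-codes-duplicate",
            sprintf("duplicated country code(s): %s",
                    paste(unique(endemic[duplicated(endemic)]),
                          collapse = ", ")))
      }
      if (is.na(diseases$pubmed_hits[i]) || diseases$pubmed_hits[i] < 0) {
        add(id, "pubmed-hits-invalid",
            "pubmed_hits must be a non-negative count")
      }
      prev <- diseases$prevalence_records_per_country[i]
      if (!is.na(prev) && prev < 0) {
        add(id, "prevalence-negative",
            "prevalence_records_per_country must be non-negative")
      }
      ov <- diseases$option_override[i]
      if (!is.na(ov) && !(ov %in% mapping_options())) {
        add(id, "override-out-of-range",
            sprintf("option_override %s is not in 1..5", ov))
      }
      if (!diseases$transmission[i] %in% transmission_classes()) {
        add(id, "transmission-unknown-label",
            sprintf("unknown transmission class '%s'",
                    diseases$transmission[i]))
      }
      if (!diseases$agent[i] %in% agent_classes()) {
        add(id, "agent-unknown-label",
            sprintf("unknown agent class '%s'", diseases$agent[i]))
      }
    }
  }

  # --- maps -----------------------------------------------------------
  if (!is.null(maps) && nrow(maps) > 0) {
    dup <- maps$map_id[duplicated(maps$map_id)]
    for (id in unique(dup)) {
      add(id, "map-id-duplicate",
          sprintf("map_id '%s' occurs more than once", id))
    }
    known_diseases <- if (is.null(diseases)) character(0) else diseases$disease_id
    for (i in seq_len(nrow(maps))) {
      id <- maps$map_id[i]
      if (!maps$disease_id[i] %in% known_diseases) {
        add(id, "map-disease-unresolved",
            sprintf("row %d: disease_id '%s' not present in the disease table",
                    i, maps$disease_id[i]))
      }
      if (isFALSE(maps$year_known[i]) && !is.na(maps$most_recent_year[i])) {
        add(id, "year-without-known",
            "most_recent_year given although year_known is false")
      }
      if (isTRUE(maps$year_known[i]) && is.na(maps$most_recent_year[i])) {
        add(id, "year-missing-when-known",
            "year_known is true but most_recent_year is missing")
      }
      if (isTRUE(maps$multi_period[i]) && !isTRUE(maps$year_known[i])) {
        add(id, "multi-period-without-known",
            "a multi-period country database implies a known year")
      }
      if (isTRUE(maps$serology_support[i]) &&
          !identical(maps$diagnostic[i], "survey_or_confirmed_case")) {
        add(id, "serology-outside-survey",
            "serology_support applies only to survey_or_confirmed_case evidence")
      }
      if (!maps$target[i] %in% map_targets()) {
        add(id, "target-unknown-label",
            sprintf("unknown target '%s'", maps$target[i]))
      }
      if (!maps$diagnostic[i] %in% diagnostic_categories()) {
        add(id, "diagnostic-unknown-label",
            sprintf("unknown diagnostic category '%s'", maps$diagnostic[i]))
      }
      if (!maps$geo[i] %in% geo_categories()) {
        add(id, "geo-unknown-label",
            sprintf("unknown geo-positional category '%s'", maps$geo[i]))
      }
      if (!maps$method[i] %in% map_methods()) {
        add(id, "method-unknown-label",
            sprintf("unknown mapping method '%s'", maps$method[i]))
      }
    }
  }

  # --- population and referential country codes -----------------------
  if (!is.null(population) && nrow(population) > 0) {
    dup <- population$country_code[duplicated(population$country_code)]
    for (code in unique(dup)) {
      add(code, "population-code-duplicate",
          sprintf("country_code '%s' occurs more than once", code))
    }
    bad <- population$country_code[
      is.na(population$population) | population$population <= 0]
    for (code in bad) {
      add(code, "population-nonpositive",
          "population must be a positive number")
    }
  }
  known_codes <- if (is.null(population)) character(0) else population$country_code
  check_codes <- function(tbl, col, id_col) {
    if (is.null(tbl) || nrow(tbl) == 0) return()
    for (i in seq_len(nrow(tbl))) {
      unknown <- setdiff(tbl[[col]][[i]], known_codes)
      if (length(unknown) > 0) {
        add(tbl[[id_col]][i], "country-not-in-population",
            sprintf("code(s) %s missing from the population table",
                    paste(unknown, collapse = ", ")))
      }
    }
  }
  check_codes(diseases, "endemic_countries", "disease_id")
  check_codes(maps, "countries_covered", "map_id")

  if (length(v) == 0) {
    tibble::tibble(record_id = character(0), rule = character(0),
                   message = character(0))
  } else {
    dplyr::bind_rows(v)
  }
}
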