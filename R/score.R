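#' Contemporariness subscore
#'
#' First leg of the 9-point evidence-quality rubric: how recent the
#' mapped data are, measured against the assessment year. Data under 10
#' years old earn 3 points, 10 to under 20 years 2 points, 20 years or
#' older 1 point, and an unidentifiable age none. For sources reporting
#' a date range the most recent year is scored, except for databases of
#' country-specific estimates surveyed across different time periods,
#' which earn 2.5 (the 2-point band plus a half point).
#'
#' @param year_known Is a data year identifiable?
#' @param most_recent_year The most recent data year (ignored when
#'   `year_known` is `FALSE`).
#' @param multi_period Country-specific estimates surveyed across
#'   different time periods?
#' @param assessment_year Year the audit is performed in.
#' @return A score in \{0, 1, 2, 2.5, 3\}.
#' @examples
#' score_contemporariness(TRUE, 2005, FALSE, 2011) # age 6 -> 3
#' score_contemporariness(TRUE, 1996, FALSE, 2011) # age 15 -> 2
#' @export
score_contemporariness <- function(year_known, most_recent_year,
                                   multi_period, assessment_year = 2011) {
  if (isTRUE(multi_period)) {
    if (!isTRUE(year_known)) {
      abort("a multi-period country database implies a known data year",
            class = "cartoaudit_score_error")
    }
    return(2.5)
  }
  if (!isTRUE(year_known)) return(0)
  if (is.na(most_recent_year)) {
    abort("year_known is TRUE but most_recent_year is missing",
          class = "cartoaudit_score_error")
  }
  age <- assessment_year - most_recent_year
  if (age < 0) {
    abort(sprintf("data year %d postdates the assessment year %d",
                  most_recent_year, assessment_year),
          class = "cartoaudit_score_error")
  }
  if (age < 10) 3 else if (age < 20) 2 else 1
}

#' Diagnostic-accuracy subscore
#'
#' Second rubric leg: how the mapped cases were diagnosed. Genotype/PCR
#' confirmation (or, for vector maps, advanced modelling on many
#' occurrence points) earns 3; hospital or national health surveys and
#' confirmed case reports earn 2, plus half a point when serological or
#' immunological data supported them; simple interpolation of vector
#' occurrence earns 2; cited literature, routine HMIS or presumptive
#' diagnosis, and expert opinion on vector maps earn 1; non-specific
#' numerical data earns 0.5; an unknown source earns nothing. The
#' result is capped at 3.
#'
#' @param category One of [diagnostic_categories()].
#' @param serology_support Serological/immunological support (applies
#'   only to `survey_or_confirmed_case`).
#' @return A score in \{0, 0.5, 1, 2, 2.5, 3\}.
#' @export
score_diagnostic <- function(category, serology_support = FALSE) {
  base <- c(genotype_pcr = 3, vector_advanced_model = 3,
            survey_or_confirmed_case = 2, vector_interpolation = 2,
            cited_literature = 1, hmis_or_presumptive = 1,
            nonspecific_numeric = 0.5, vector_expert_opinion = 1,
            unknown = 0)
  if (!category %in% names(base)) {
    abort(sprintf("unknown diagnostic category '%s'", category),
          class = "cartoaudit_enum_error")
  }
  s <- base[[category]]
  if (isTRUE(serology_support)) {
    if (!identical(category, "survey_or_confirmed_case")) {
      abort("the serology half-point applies only to survey_or_confirmed_case",
            class = "cartoaudit_score_error")
    }
    s <- s + 0.5
  }
  min(s, 3)
}

#' Geo-positional-accuracy subscore
#'
#' Third rubric leg: how precisely the data were located. GPS
#' coordinates earn 3; coordinates derivable from supporting maps or
#' admin-level-1 data earn 2, rising to 2.5 when admin level 2 or named
#' towns/villages were used; approximate or country-level coordinates
#' earn 1; expert-opinion ranges from cited literature earn 0.5; no
#' geo-positional information earns nothing.
#'
#' @param category One of [geo_categories()].
#' @return A score in \{0, 0.5, 1, 2, 2.5, 3\}.
#' @export
score_geopositional <- function(category) {
  tbl <- c(gps_coordinates = 3, derived_coords_or_admin1 = 2,
           admin2_or_town = 2.5, approximate_or_country_level = 1,
           expert_opinion_range = 0.5, none = 0)
  if (!category %in% names(tbl)) {
    abort(sprintf("unknown geo-positional category '%s'", category),
          class = "cartoaudit_enum_error")
  }
  tbl[[category]]
}

#' Total data-quality score of a map
#'
#' Sum of the three rubric subscores, out of 9.
#'
#' @param map A one-row maps tibble.
#' @param config An [audit_config()].
#' @return A score in \[0, 9\].
#' @export
quality_score <- function(map, config = audit_config()) {
  score_contemporariness(map$year_known[[1]], map$most_recent_year[[1]],
                         map$multi_period[[1]], config$assessment_year) +
    score_diagnostic(map$diagnostic[[1]], map$serology_support[[1]]) +
    score_geopositional(map$geo[[1]])
}

#' Geographic scope of a map as population-at-risk coverage
#'
#' The share of the disease's endemic population the map covers,
#' expressed as a percentage out of 100. Both the endemic set and the
#' map's coverage are resolved at national level; countries the map
#' covers outside the endemic set are ignored (intersection semantics),
#' so scope depends only on endemic countries reached.
#'
#' @param countries_covered Character vector of covered country codes.
#' @param endemic_countries Character vector of endemic country codes
#'   (non-empty).
#' @param population Population tibble (`country_code`, `population`).
#' @return Percentage in \[0, 100\].
#' @examples
#' pop <- tibble::tibble(country_code = c("AAA", "BBB"),
#'                       population = c(3e7, 1e7))
#' scope_score("AAA", c("AAA", "BBB"), pop) # 75
#' @export
scope_score <- function(countries_covered, endemic_countries, population) {
  if (length(endemic_countries) == 0) {
    abort("scope is undefined for an empty endemic set",
          class = "cartoaudit_scope_error")
  }
  pop <- setNames(population$population, population$country_code)
  missing <- setdiff(endemic_countries, names(pop))
  if (length(missing) > 0) {
    abort(sprintf("no population entry for endemic code(s): %s",
                  paste(missing, collapse = ", ")),
          class = "cartoaudit_scope_error")
  }
  total <- sum(pop[endemic_countries])
  covered <- sum(pop[intersect(endemic_countries, countries_covered)])
  100 * covered / total
}

#' Mapping option realized by a map's method
#'
#' Plotting occurrence points realizes Option 2; an extent/range map of
#' reservoir or vector bounds realizes Option 3; niche/occurrence
#' modelling realizes Option 4; geostatistical endemicity mapping
#' realizes Option 5.
#'
#' @param method One of [map_methods()].
#' @return An integer mapping option in \{2, 3, 4, 5\}.
#' @export
option_used_of <- function(method) {
  tbl <- c(occurrence_points = 2L, extent_range_map = 3L,
           niche_model = 4L, geostatistical_endemicity = 5L)
  if (!method %in% names(tbl)) {
    abort(sprintf("unknown mapping method '%s'", method),
          class = "cartoaudit_enum_error")
  }
  tbl[[method]]
}

#' The metascore
#'
#' Composite 0-100 index of how well one map assesses a disease's global
#' distribution: `quality / 9 * scope_pct * min(used / potential, 1)`.
#' Full data quality (9), complete population-at-risk scope (100%) and a
#' method matching the disease's assessed potential yield the maximum of
#' 100. The option ratio is capped at 1 so a map exceeding the assessed
#' potential cannot score above the maximum. Diseases at Option 1 have
#' no mapping rationale and are not metascored.
#'
#' @param quality Data-quality score in \[0, 9\].
#' @param scope_pct Geographic scope percentage in \[0, 100\].
#' @param used Mapping option realized by the map (2-5).
#' @param potential The disease's assessed potential option (2-5).
#' @return Metascore points in \[0, 100\].
#' @examples
#' metascore(9, 100, 4, 4) # 100
#' metascore(9, 100, 2, 4) # 50: occurrence-point map of an Option 4 disease
#' @export
metascore <- function(quality, scope_pct, used, potential) {
  stopifnot(quality >= 0, quality <= 9, scope_pct >= 0, scope_pct <= 100,
            used %in% 2:5)
  if (!potential %in% 2:5) {
    abort("a disease without a mapping rationale (Option 1) is not metascored",
          class = "cartoaudit_score_error")
  }
  quality / 9 * scope_pct * min(used / potential, 1)
}

#' Satisfactory-assessment threshold
#'
#' @param score Metascore points.
#' @param config An [audit_config()].
#' @return `TRUE` when `score` is greater than or equal to the
#'   configured threshold (default 75).
#' @export
is_satisfactory <- function(score, config = audit_config()) {
  score >= config$satisfactory_threshold
}

#' Score one map against its disease
#'
#' Assembles the full score breakdown: the three rubric subscores, their
#' 9-point quality total, the population-at-risk scope, the option used
#' (from the map's method) against the disease's potential option, and
#' the metascore with its satisfactory flag. Vector and reservoir maps
#' are scored with the same rubric, with scope still measured against
#' the disease's endemic population.
#'
#' @param map One-row maps tibble.
#' @param disease One-row diseases tibble for the same `disease_id`.
#' @param potential The disease's potential mapping option from
#'   [classify_option()]; must be 2-5.
#' @param population Population tibble.
#' @param config An [audit_config()].
#' @return A one-row score-breakdown tibble.
#' @export
score_map <- function(map, disease, potential, population,
                      config = audit_config()) {
  if (!identical(map$disease_id[[1]], disease$disease_id[[1]])) {
    abort(sprintf("map '%s' does not belong to disease '%s'",
                  map$map_id[[1]], disease$disease_id[[1]]),
          class = "cartoaudit_score_error")
  }
  contemporariness <- score_contemporariness(
    map$year_known[[1]], map$most_recent_year[[1]], map$multi_period[[1]],
    config$assessment_year)
  diagnostic <- score_diagnostic(map$diagnostic[[1]],
                                 map$serology_support[[1]])
  geopositional <- score_geopositional(map$geo[[1]])
  quality <- contemporariness + diagnostic + geopositional
  scope <- scope_score(map$countries_covered[[1]],
                       disease$endemic_countries[[1]], population)
  used <- option_used_of(map$method[[1]])
  ms <- metascore(quality, scope, used, potential)
  tibble::tibble(
    map_id = map$map_id[[1]],
    disease_id = map$disease_id[[1]],
    contemporariness = contemporariness,
    diagnostic = diagnostic,
    geopositional = geopositional,
    quality = quality,
    scope_pct = scope,
    option_used = used,
    option_potential = as.integer(potential),
    option_ratio = min(used / potential, 1),
    metascore = ms,
    satisfactory = is_satisfactory(ms, config)
  )
}

#' Score every map of a corpus
#'
#' Joins each map to its disease and the disease's classified potential
#' option, and scores it. Maps of diseases classified as Option 1 are
#' not metascorable; they are dropped with a warning naming them.
#'
#' @param corpus A `carto_corpus`.
#' @param classifications Output of [classify_corpus()] for the corpus.
#' @param config An [audit_config()].
#' @return A tibble of score breakdowns, one row per scoreable map, in
#'   map input order.
#' @examples
#' corpus <- generate_corpus(generator_params(n_diseases = 20, seed = 1))
#' cls <- classify_corpus(corpus$diseases)
#' scores <- score_corpus(corpus, cls)
#' @export
score_corpus <- function(corpus, classifications, config = audit_config()) {
  empty <- tibble::tibble(
    map_id = character(0), disease_id = character(0),
    contemporariness = numeric(0), diagnostic = numeric(0),
    geopositional = numeric(0), quality = numeric(0),
    scope_pct = numeric(0), option_used = integer(0),
    option_potential = integer(0), option_ratio = numeric(0),
    metascore = numeric(0), satisfactory = logical(0))
  maps <- corpus$maps
  if (nrow(maps) == 0) return(empty)
  potential <- setNames(classifications$option, classifications$disease_id)
  unscoreable <- maps$map_id[potential[maps$disease_id] == 1L]
  if (length(unscoreable) > 0) {
    warn(sprintf(
      "dropping %d map(s) of Option 1 diseases (no mapping rationale): %s",
      length(unscoreable), paste(unscoreable, collapse = ", ")))
  }
  rows <- purrr::map(seq_len(nrow(maps)), function(i) {
    m <- maps[i, ]
    p <- potential[[m$disease_id]]
    if (p == 1L) return(NULL)
    d <- corpus$diseases[corpus$diseases$disease_id == m$disease_id, ]
    score_map(m, d, p, corpus$population, config)
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) empty else out
}

#' Best map per disease
#'
#' Selects, for each disease present in `scores`, the breakdown with the
#' highest metascore; ties keep the earliest row in input order, the
#' order maps were listed in.
#'
#' @param scores Score-breakdown tibble from [score_corpus()].
#' @return A tibble with one row per disease that has at least one
#'   scored map.
#' @export
best_metascores <- function(scores) {
  if (nrow(scores) == 0) return(scores)
  scores |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(disease_id) |>
    dplyr::slice_max(metascore, n = 1, with_ties = TRUE) |>
    dplyr::slice_min(.row, n = 1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.row) |>
    dplyr::select(-".row")
}
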