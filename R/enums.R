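#' Controlled vocabularies of the audit framework
#'
#' The framework works over fixed category sets: 11 transmission routes,
#' 7 aetiological agent classes, 5 mapping options, the evidence-rubric
#' categories for diagnostic and geo-positional accuracy, the map-method
#' categories, and the three map targets (disease, vector, reservoir).
#' These accessors return the admissible labels; any other label in an
#' input file is a parse error.
#'
#' @return A character vector of admissible labels (for
#'   `mapping_options()`, an integer vector `1:5`).
#' @examples
#' transmission_classes()
#' agent_classes()
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
transmission_classes <- function() {
  c("animal_contact", "blood_body_fluid_contact", "direct_contact",
    "endogenous", "food_water_borne", "respiratory", "sexual_contact",
    "soil_contact", "unknown", "vector_borne", "water_contact")
}

#' @rdname vocabularies
#' @export
agent_classes <- function() {
  c("virus", "bacterium", "parasite", "fungus", "protoctist", "alga",
    "unknown")
}

#' @rdname vocabularies
#' @export
mapping_options <- function() 1:5

#' @rdname vocabularies
#' @export
diagnostic_categories <- function() {
  c("genotype_pcr", "vector_advanced_model", "survey_or_confirmed_case",
    "vector_interpolation", "cited_literature", "hmis_or_presumptive",
    "nonspecific_numeric", "vector_expert_opinion", "unknown")
}

#' @rdname vocabularies
#' @export
geo_categories <- function() {
  c("gps_coordinates", "derived_coords_or_admin1", "admin2_or_town",
    "approximate_or_country_level", "expert_opinion_range", "none")
}

#' @rdname vocabularies
#' @export
map_methods <- function() {
  c("occurrence_points", "extent_range_map", "niche_model",
    "geostatistical_endemicity")
}

#' @rdname vocabularies
#' @export
map_targets <- function() c("disease", "vector", "reservoir")

# Check a character vector against a vocabulary; stop with row loci on
# failure. `what` names the column in the message.
assert_enum <- function(x, vocabulary, what, file = NULL) {
  bad <- !is.na(x) & !(x %in% vocabulary)
  if (any(bad)) {
    rows <- which(bad)
    abort(sprintf(
      "unknown %s label%s %s at row%s %s%s",
      what, if (sum(bad) > 1) "s" else "",
      paste(sQuote(unique(x[bad])), collapse = ", "),
      if (sum(bad) > 1) "s" else "",
      paste(rows, collapse = ", "),
      if (is.null(file)) "" else paste0(" of ", file)
    ), class = "cartoaudit_enum_error")
  }
  invisible(x)
}
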