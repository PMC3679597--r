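# Independent oracles, written as literal table transcriptions of the
# decision rules and the evidence rubric. They share no code with the
# implementation: the classifier oracle enumerates the full categorical
# grid as data, the rubric oracles are flat lookup tables.

# Decision-table oracle over the categorical grid
# {worldwide} x {bounded} x {density below/at/above cutoff}
#              x {prevalence none/at/above cutoff}.
# Worldwide dominates; below-cutoff density splits on boundedness; at-
# or above-cutoff density splits on prevalence strictly above the cutoff.
decision_grid <- function() {
  g <- expand.grid(
    worldwide = c(TRUE, FALSE),
    bounded = c(TRUE, FALSE),
    density = c("below", "at", "above"),
    prevalence = c("none", "at", "above"),
    stringsAsFactors = FALSE)
  g$expected <- NA_integer_
  for (i in seq_len(nrow(g))) {
    r <- g[i, ]
    g$expected[i] <-
      if (r$worldwide) 1L
      else if (r$density == "below") (if (r$bounded) 3L else 2L)
      else if (r$prevalence == "above") 5L
      else 4L
  }
  g
}

# materialize one grid cell as a disease record (cutoff-relative values)
grid_disease <- function(worldwide, bounded, density, prevalence,
                         cutoff = 25) {
  n_endemic <- 4
  hits <- switch(density,
                 below = (cutoff - 1) * n_endemic,
                 at = cutoff * n_endemic,
                 above = (cutoff + 10) * n_endemic)
  prev <- switch(prevalence,
                 none = NA_real_, at = cutoff, above = cutoff + 5)
  make_disease(
    id = "grid", worldwide = worldwide, bounded = bounded,
    endemic = if (worldwide) character(0) else c("KEN", "UGA", "TZA", "ETH"),
    hits = hits, prev = prev)
}

# Rubric oracle tables (flat transcriptions of every clause).
oracle_contemporariness <- function(year_known, age, multi_period) {
  if (multi_period) return(2.5)
  if (!year_known) return(0)
  if (age < 10) 3 else if (age < 20) 2 else 1
}

oracle_diagnostic_table <- c(
  genotype_pcr = 3, vector_advanced_model = 3, survey_or_confirmed_case = 2,
  vector_interpolation = 2, cited_literature = 1, hmis_or_presumptive = 1,
  nonspecific_numeric = 0.5, vector_expert_opinion = 1, unknown = 0)

oracle_geo_table <- c(
  gps_coordinates = 3, derived_coords_or_admin1 = 2, admin2_or_town = 2.5,
  approximate_or_country_level = 1, expert_opinion_range = 0.5, none = 0)

oracle_method_option <- c(
  occurrence_points = 2L, extent_range_map = 3L, niche_model = 4L,
  geostatistical_endemicity = 5L)
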