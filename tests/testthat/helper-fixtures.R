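# In-code fixtures: small record builders and the published marginal
# tables used as generator inputs.

make_disease <- function(id = "d1", name = id, transmission = "vector_borne",
                         agent = "virus", worldwide = FALSE,
                         endemic = c("KEN", "UGA"), hits = 100,
                         prev = NA_real_, bounded = FALSE,
                         override = NA_integer_, note = NA_character_) {
  tibble::tibble(
    disease_id = id, name = name, transmission = transmission, agent = agent,
    worldwide = worldwide, endemic_countries = list(endemic),
    pubmed_hits = hits, prevalence_records_per_country = prev,
    reservoir_or_vector_bounded = bounded, option_override = override,
    override_note = note, r0_annotation = NA_character_)
}

make_map <- function(id = "m1", disease_id = "d1", target = "disease",
                     year_known = TRUE, year = 2005L, multi = FALSE,
                     diagnostic = "genotype_pcr", serology = FALSE,
                     geo = "gps_coordinates", method = "niche_model",
                     covered = c("KEN", "UGA"), citation = "synthetic") {
  tibble::tibble(
    map_id = id, disease_id = disease_id, target = target,
    year_known = year_known,
    most_recent_year = if (year_known) as.integer(year) else NA_integer_,
    multi_period = multi, diagnostic = diagnostic,
    serology_support = serology, geo = geo, method = method,
    countries_covered = list(covered), citation = citation)
}

empty_maps_fixture <- function() make_map()[0, ]

pop_table <- function(codes = c("KEN", "UGA"), pops = c(4e7, 3e7)) {
  tibble::tibble(country_code = codes, population = pops)
}

# published per-option counts (181 do-not-map ... 10 geostatistical)
option_targets_published <- c(`1` = 181, `2` = 64, `3` = 32, `4` = 68, `5` = 10)

# published transmission-route marginals: (total, with-rationale) pairs
table1_transmission <- tibble::tibble(
  category = c("animal_contact", "blood_body_fluid_contact", "direct_contact",
               "endogenous", "food_water_borne", "respiratory",
               "sexual_contact", "soil_contact", "unknown", "vector_borne",
               "water_contact"),
  total = c(20, 14, 23, 35, 82, 39, 11, 21, 11, 88, 11),
  rationale = c(9, 5, 7, 0, 36, 9, 2, 14, 4, 80, 8))

# published agent-class marginals
agent_marginals <- tibble::tibble(
  category = c("virus", "bacterium", "parasite", "fungus", "protoctist",
               "alga", "unknown"),
  total = c(101, 128, 96, 17, 2, 1, 10),
  rationale = c(62, 36, 61, 9, 2, 0, 4))
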