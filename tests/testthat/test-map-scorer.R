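test_that("contemporariness bands close at 10 and 20 years as stated", {
  sc <- function(year) score_contemporariness(TRUE, year, FALSE, 2011)
  expect_identical(sc(2005), 3)   # age 6
  expect_identical(sc(1996), 2)   # age 15
  expect_identical(sc(1985), 1)   # age 26
  expect_identical(sc(2001), 2)   # age exactly 10 -> lower band
  expect_identical(sc(1991), 1)   # age exactly 20 -> lower band
  expect_identical(score_contemporariness(FALSE, NA, FALSE, 2011), 0)
  expect_identical(score_contemporariness(TRUE, 2000, TRUE, 2011), 2.5)
  expect_error(sc(2012), class = "cartoaudit_score_error")
})

test_that("the three rubric legs match their oracle tables on every category", {
  for (cat in names(oracle_diagnostic_table)) {
    expect_identical(score_diagnostic(cat), oracle_diagnostic_table[[cat]],
                     label = cat)
  }
  expect_identical(score_diagnostic("survey_or_confirmed_case", TRUE), 2.5)
  expect_error(score_diagnostic("cited_literature", TRUE),
               class = "cartoaudit_score_error")

  for (cat in names(oracle_geo_table)) {
    expect_identical(score_geopositional(cat), oracle_geo_table[[cat]],
                     label = cat)
  }

  for (known in c(TRUE, FALSE)) for (multi in c(TRUE, FALSE)) {
    if (multi && !known) next
    for (age in c(0, 5, 9, 10, 15, 19, 20, 40)) {
      expect_identical(
        score_contemporariness(known, if (known) 2011L - age else NA,
                               multi, 2011),
        oracle_contemporariness(known, age, multi))
    }
  }

  # subscores live on the half-point lattice within [0, 3]
  lattice <- seq(0, 3, by = 0.5)
  expect_true(all(oracle_diagnostic_table %in% lattice))
  all_diag <- vapply(diagnostic_categories(), score_diagnostic, numeric(1))
  all_geo <- vapply(geo_categories(), score_geopositional, numeric(1))
  expect_true(all(c(all_diag, all_geo) %in% lattice))
})

test_that("quality sums the three subscores out of nine", {
  best <- make_map(year = 2005L, diagnostic = "genotype_pcr",
                   geo = "gps_coordinates")
  expect_identical(quality_score(best), 9)
  mid <- make_map(year = 2000L, multi = TRUE,
                  diagnostic = "survey_or_confirmed_case", serology = TRUE,
                  geo = "derived_coords_or_admin1")
  expect_identical(quality_score(mid), 7)  # 2.5 + 2.5 + 2
  worst <- make_map(year_known = FALSE, diagnostic = "unknown", geo = "none")
  expect_identical(quality_score(worst), 0)
})

test_that("scope is the endemic population share reached, out of 100", {
  pop <- pop_table(c("AAA", "BBB", "CCC"), c(3e7, 1e7, 5e8))
  expect_equal(scope_score(c("AAA", "BBB"), c("AAA", "BBB"), pop), 100)
  expect_equal(scope_score("AAA", c("AAA", "BBB"), pop), 75)
  expect_equal(scope_score("CCC", c("AAA", "BBB"), pop), 0)
  # countries covered outside the endemic set never change the score
  expect_equal(scope_score(c("AAA", "CCC"), c("AAA", "BBB"), pop),
               scope_score("AAA", c("AAA", "BBB"), pop))
  expect_error(scope_score("AAA", c("AAA", "ZZZ"), pop),
               class = "cartoaudit_scope_error")
  expect_error(scope_score("AAA", character(0), pop),
               class = "cartoaudit_scope_error")
})

test_that("each mapping method realizes its option", {
  for (m in names(oracle_method_option)) {
    expect_identical(option_used_of(m), oracle_method_option[[m]])
  }
})

test_that("the metascore reproduces its worked examples", {
  expect_equal(metascore(9, 100, 4, 4), 100)
  expect_equal(metascore(9, 100, 2, 4), 50)
  expect_equal(metascore(0, 100, 4, 4), 0)
  expect_equal(metascore(4.5, 50, 3, 4), 18.75)
  expect_error(metascore(9, 100, 2, 1), class = "cartoaudit_score_error")
})

test_that("metascore is bounded, monotone and annihilated by zero factors", {
  set.seed(2024)
  for (i in 1:200) {
    q <- sample(seq(0, 9, by = 0.5), 1)
    s <- runif(1, 0, 100)
    u <- sample(2:5, 1)
    p <- sample(2:5, 1)
    m <- metascore(q, s, u, p)
    expect_gte(m, 0); expect_lte(m, 100)
    expect_identical(m == 0, q == 0 || s == 0)
    # monotone non-decreasing in each factor
    expect_gte(metascore(min(q + 0.5, 9), s, u, p), m)
    expect_gte(metascore(q, min(s + 1, 100), u, p), m)
    expect_gte(metascore(q, s, min(u + 1L, 5L), p), m)
  }
  # structured monotonicity and the scope-only limit
  for (q in seq(0, 9, by = 1.5)) {
    expect_equal(metascore(q, 100, 4, 4), q / 9 * 100)
    expect_gte(metascore(q, 80, 3, 4), metascore(q, 60, 3, 4))
    expect_gte(metascore(q, 80, 4, 4), metascore(q, 80, 2, 4))
  }
  # the used/potential ratio is capped at one
  expect_equal(metascore(9, 100, 5, 2), 100)
})

test_that("the satisfactory threshold is inclusive at 75", {
  expect_true(is_satisfactory(75))
  expect_false(is_satisfactory(74.99))
  expect_true(is_satisfactory(100))
})

test_that("score_map assembles a consistent breakdown", {
  pop <- pop_table()
  d <- make_disease("lassa", hits = 2000, prev = NA_real_)
  # occurrence-point map of full quality and scope for an Option 4 disease
  m <- make_map("m1", disease_id = "lassa", method = "occurrence_points")
  b <- score_map(m, d, potential = 4L, population = pop)
  expect_equal(b$quality, 9)
  expect_equal(b$scope_pct, 100)
  expect_equal(b$option_ratio, 0.5)
  expect_equal(b$metascore, 50)
  expect_false(b$satisfactory)
  expect_equal(b$quality, b$contemporariness + b$diagnostic + b$geopositional)

  # a method matching the potential reaches the maximum
  full <- score_map(make_map("m2", disease_id = "lassa",
                             method = "niche_model"),
                    d, 4L, pop)
  expect_equal(full$metascore, 100)
  expect_true(full$satisfactory)

  # all-unknown evidence scores zero
  blank <- score_map(make_map("m3", disease_id = "lassa",
                              year_known = FALSE, diagnostic = "unknown",
                              geo = "none", method = "niche_model"),
                     d, 4L, pop)
  expect_equal(blank$metascore, 0)

  expect_error(score_map(make_map("m4", disease_id = "other"), d, 4L, pop),
               class = "cartoaudit_score_error")
})

test_that("best_metascores keeps the maximum with first-in-order ties", {
  mk <- function(id, disease, ms) {
    tibble::tibble(map_id = id, disease_id = disease, metascore = ms)
  }
  scores <- dplyr::bind_rows(mk("a", "d1", 30), mk("b", "d1", 60),
                             mk("c", "d2", 60), mk("d", "d2", 60))
  best <- best_metascores(scores)
  expect_identical(best$map_id[best$disease_id == "d1"], "b")
  expect_identical(best$map_id[best$disease_id == "d2"], "c")
  expect_identical(nrow(best_metascores(scores[0, ])), 0L)
})
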