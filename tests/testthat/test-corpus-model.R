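test_that("a written corpus reloads field-by-field identical", {
  for (seed in c(1, 42, 99)) {
    corpus <- generate_corpus(generator_params(n_diseases = 8, seed = seed))
    dir <- withr::local_tempdir()
    write_corpus(corpus, dir)
    reloaded <- load_corpus(file.path(dir, "diseases.csv"),
                            file.path(dir, "maps.csv"),
                            file.path(dir, "population.csv"))
    expect_equal(as.data.frame(reloaded$diseases),
                 as.data.frame(corpus$diseases))
    expect_equal(as.data.frame(reloaded$maps), as.data.frame(corpus$maps))
    expect_equal(as.data.frame(reloaded$population),
                 as.data.frame(corpus$population))
  }
})

test_that("loading rejects broken referential integrity and unknown labels", {
  corpus <- new_corpus(
    make_disease("d1"),
    make_map("m1", disease_id = "ghost"),
    pop_table())
  dir <- withr::local_tempdir()
  write_corpus(corpus, dir)
  expect_error(
    load_corpus(file.path(dir, "diseases.csv"), file.path(dir, "maps.csv"),
                file.path(dir, "population.csv")),
    "map-disease-unresolved", class = "cartoaudit_validation_error")

  # unknown transmission label is a parse-time error naming the row
  bad <- make_disease("d2", transmission = "airborne")
  bad$endemic_countries <- "KEN;UGA"
  bad$r0_annotation <- NULL
  path <- file.path(dir, "bad-diseases.csv")
  readr::write_csv(bad, path, na = "")
  expect_error(read_diseases(path), "airborne",
               class = "cartoaudit_enum_error")
  expect_error(read_diseases(path), "row")
})

test_that("validate_corpus classifies violations without raising", {
  good <- new_corpus(make_disease("d1"), make_map("m1"), pop_table())
  expect_identical(nrow(validate_corpus(good)), 0L)

  diseases <- dplyr::bind_rows(
    make_disease("dup"), make_disease("dup"),
    make_disease("empty", worldwide = FALSE, endemic = character(0)),
    make_disease("neg", hits = -1),
    make_disease("ovr", override = 9L))
  v <- validate_corpus(new_corpus(diseases, make_map("m1", disease_id = "dup"),
                                  pop_table()))
  expect_setequal(
    v$rule,
    c("disease-id-duplicate", "endemic-set-empty", "pubmed-hits-invalid",
      "override-out-of-range"))
  expect_identical(v$record_id[v$rule == "endemic-set-empty"], "empty")

  # temporal-evidence and serology consistency are map-level rules
  maps <- dplyr::bind_rows(
    make_map("bad-year", year_known = FALSE) |>
      dplyr::mutate(most_recent_year = 2000L),
    make_map("bad-multi", year_known = FALSE, multi = TRUE),
    make_map("bad-missing", year_known = TRUE) |>
      dplyr::mutate(most_recent_year = NA_integer_),
    make_map("bad-sero", diagnostic = "cited_literature", serology = TRUE),
    make_map("bad-code", covered = "ZZZ"))
  v2 <- validate_corpus(new_corpus(make_disease("d1"), maps, pop_table()))
  expect_setequal(
    v2$rule,
    c("year-without-known", "year-missing-when-known",
      "multi-period-without-known", "serology-outside-survey",
      "country-not-in-population"))
})

test_that("score/summary outputs are deterministic and round-trip", {
  corpus <- generate_corpus(generator_params(n_diseases = 30, seed = 7))
  cls <- classify_corpus(corpus$diseases)
  scores <- suppressWarnings(score_corpus(corpus, cls))
  best <- best_metascores(scores)
  summary <- summarize_corpus(cls, corpus$diseases, best)
  radial <- radial_series(best, cls$disease_id[cls$rationale])

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- write_outputs(scores, summary, radial, d1)
  m2 <- write_outputs(scores, summary, radial, d2)
  expect_identical(m1$md5, m2$md5)

  reread <- readr::read_csv(file.path(d1, "scores.csv"),
                            show_col_types = FALSE)
  expect_equal(reread$metascore, scores$metascore, tolerance = 0.005)
  expect_equal(reread$quality, scores$quality)

  # empty inputs give header-only CSV and a zero-count summary
  empty_scores <- scores[0, ]
  empty_summary <- summarize_corpus(cls[0, ], corpus$diseases[0, ])
  d3 <- withr::local_tempdir()
  write_outputs(empty_scores, empty_summary, radial[0, ], d3)
  lines <- readLines(file.path(d3, "scores.csv"))
  expect_length(lines, 1)
  expect_identical(empty_summary$n_diseases, 0L)
})

test_that("the shipped territory list has 275 unique codes", {
  terr <- default_territories()
  expect_identical(nrow(terr), 275L)
  expect_false(anyDuplicated(terr$country_code) > 0)
  expect_identical(sum(!terr$synthetic), 249L)
})
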