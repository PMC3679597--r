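test_that("reported percentages round half up to whole percent", {
  expect_identical(rationale_percentage(174, 355), 49L)
  expect_identical(rationale_percentage(7, 174), 4L)
  expect_identical(rationale_percentage(0, 10), 0L)
  expect_identical(rationale_percentage(1, 200), 1L)   # 0.5 rounds up
  expect_error(rationale_percentage(1, 0),
               class = "cartoaudit_summary_error")
})

test_that("an empty corpus summarizes to all-zero counts", {
  corpus <- generate_corpus(generator_params(n_diseases = 0, seed = 1))
  s <- summarize_corpus(classify_corpus(corpus$diseases), corpus$diseases)
  expect_identical(s$n_diseases, 0L)
  expect_identical(sum(unlist(s$by_option)), 0L)
  expect_identical(s$n_rationale, 0L)
  expect_identical(s$n_satisfactory, 0L)
})

test_that("summary counts partition the corpus and agree across views", {
  corpus <- generate_corpus(generator_params(n_diseases = 80, seed = 5))
  cls <- classify_corpus(corpus$diseases)
  scores <- suppressWarnings(score_corpus(corpus, cls))
  s <- summarize_corpus(cls, corpus$diseases, best_metascores(scores))
  expect_identical(sum(unlist(s$by_option)), s$n_diseases)
  expect_identical(s$n_rationale,
                   sum(unlist(s$by_option[as.character(2:5)])))
  expect_identical(sum(s$by_transmission$total), s$n_diseases)
  expect_identical(sum(s$by_transmission$rationale), s$n_rationale)
  expect_identical(sum(s$by_agent$total), s$n_diseases)
  expect_identical(sum(s$by_agent$rationale), s$n_rationale)
  expect_lte(s$n_satisfactory, s$n_rationale)
})

test_that("published marginals are reconstructed exactly by the aggregator", {
  spec <- marginal_spec(by_option = option_targets_published,
                        by_transmission = table1_transmission,
                        by_agent = agent_marginals)
  corpus <- generate_from_marginals(spec, seed = 17)
  cls <- classify_corpus(corpus$diseases)
  s <- summarize_corpus(cls, corpus$diseases)
  expect_identical(s$n_diseases, 355L)
  expect_identical(s$n_rationale, 174L)
  expect_identical(unlist(s$by_option),
                   setNames(as.integer(option_targets_published),
                            names(option_targets_published)))
  expect_identical(s$by_transmission$total,
                   as.integer(table1_transmission$total))
  expect_identical(s$by_transmission$rationale,
                   as.integer(table1_transmission$rationale))
  expect_identical(s$by_agent$total, as.integer(agent_marginals$total))
  expect_identical(s$by_agent$rationale,
                   as.integer(agent_marginals$rationale))
  expect_identical(s$pct_rationale, 49L)
})

test_that("the radial series orders rationale diseases by best metascore", {
  best <- tibble::tibble(map_id = c("m1", "m2"),
                         disease_id = c("d1", "d2"),
                         metascore = c(20, 80))
  r <- radial_series(best, c("d1", "d2", "d3"))
  expect_identical(r$disease_id, c("d2", "d1", "d3"))
  expect_identical(r$best_metascore, c(80, 20, 0))  # unmapped -> 0
  expect_true(all(diff(r$best_metascore) <= 0))

  tied <- tibble::tibble(map_id = c("m1", "m2"),
                         disease_id = c("db", "da"), metascore = c(50, 50))
  expect_identical(radial_series(tied, c("db", "da"))$disease_id,
                   c("da", "db"))
})

test_that("thumbnail coding covers the territory list with binary endemicity", {
  terr <- c("AAA", "BBB", "CCC")
  t1 <- thumbnail_endemicity(make_disease(endemic = c("AAA", "BBB")), terr)
  expect_identical(t1$country_code, terr)
  expect_identical(t1$endemic, c(1L, 1L, 0L))

  ww <- thumbnail_endemicity(
    make_disease(worldwide = TRUE, endemic = character(0)), terr)
  expect_identical(ww$endemic, rep(1L, 3))

  # coverage count equals the endemic-territory intersection
  corpus <- generate_corpus(generator_params(n_diseases = 15, seed = 9))
  terr_full <- corpus$population$country_code
  for (i in seq_len(nrow(corpus$diseases))) {
    d <- corpus$diseases[i, ]
    tt <- thumbnail_endemicity(d, terr_full)
    expected <- if (d$worldwide[[1]]) length(terr_full)
                else length(intersect(d$endemic_countries[[1]], terr_full))
    expect_identical(sum(tt$endemic), as.integer(expected))
  }

  expect_error(thumbnail_endemicity(make_disease(endemic = "ZZZ"), terr),
               class = "cartoaudit_summary_error")
  expect_error(thumbnail_endemicity(make_disease(), character(0)),
               class = "cartoaudit_summary_error")
})
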