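# Evaluate expr with a locally seeded RNG, restoring the caller's state.
# A fixed generator triple keeps output stable across platforms and
# R versions; every record attribute is drawn in a fixed field order.
with_local_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

empty_diseases <- function() {
  tibble::tibble(
    disease_id = character(0), name = character(0),
    transmission = character(0), agent = character(0),
    worldwide = logical(0), endemic_countries = list(),
    pubmed_hits = numeric(0), prevalence_records_per_country = numeric(0),
    reservoir_or_vector_bounded = logical(0), option_override = integer(0),
    override_note = character(0), r0_annotation = character(0))
}

empty_maps <- function() {
  tibble::tibble(
    map_id = character(0), disease_id = character(0), target = character(0),
    year_known = logical(0), most_recent_year = integer(0),
    multi_period = logical(0), diagnostic = character(0),
    serology_support = logical(0), geo = character(0), method = character(0),
    countries_covered = list(), citation = character(0))
}

#' Parameters of the synthetic corpus generator
#'
#' Defines the study conditions a simulated corpus emulates. The
#' defaults reproduce the audited corpus in the aggregate: 355 diseases;
#' transmission-route weights proportional to the published per-route
#' totals (20, 14, 23, 35, 82, 39, 11, 21, 11, 88, 11 across the 11
#' routes); agent weights proportional to the published agent partition
#' (101 viral, 128 bacterial, 96 parasitic, 17 fungal, 2 protoctistan,
#' 1 algal, 10 unknown); a 181/355 probability of worldwide occurrence;
#' a heavy-tailed negative-binomial occurrence-hit distribution spanning
#' zero-hit rarities to hundred-thousand-scale literatures; endemic
#' country counts 1 plus a negative binomial, truncated to the 275
#' available territories; a one-third chance that a data-poor disease
#' has a range-bounding reservoir or vector; prevalence-survey density
#' as a zero-inflated lognormal; and a Poisson number of published maps
#' per non-worldwide disease.
#'
#' @param n_diseases Number of diseases to generate.
#' @param seed Integer seed; identical seeds give byte-identical corpora.
#' @param transmission_weights,agent_weights Named probability vectors
#'   over [transmission_classes()] and [agent_classes()].
#' @param p_worldwide Probability a disease occurs worldwide.
#' @param hit_distribution List `(size, mu)` of the negative-binomial
#'   occurrence-hit law.
#' @param endemic_count_distribution List `(size, mu)`; endemic country
#'   counts are `1 + rnbinom(size, mu)` truncated to `n_territories`.
#' @param p_bounded Probability of a known range-bounding reservoir or
#'   vector distribution.
#' @param prevalence_density_distribution List `(p_positive, meanlog,
#'   sdlog)` of the zero-inflated lognormal prevalence-record density.
#' @param maps_per_disease_distribution List `(lambda)` of the Poisson
#'   map count per non-worldwide disease.
#' @param n_territories Number of territories in the generated
#'   population table.
#' @return A list of class `carto_generator_params`.
#' @export
generator_params <- function(n_diseases = 355,
                             seed = 20100101,
                             transmission_weights = NULL,
                             agent_weights = NULL,
                             p_worldwide = 181 / 355,
                             hit_distribution = list(size = 0.35, mu = 300),
                             endemic_count_distribution = list(size = 0.8, mu = 19),
                             p_bounded = 1 / 3,
                             prevalence_density_distribution =
                               list(p_positive = 0.2, meanlog = 2.5, sdlog = 1.2),
                             maps_per_disease_distribution = list(lambda = 1.2),
                             n_territories = 275) {
  if (is.null(transmission_weights)) {
    transmission_weights <- setNames(
      c(20, 14, 23, 35, 82, 39, 11, 21, 11, 88, 11) / 355,
      transmission_classes())
  }
  if (is.null(agent_weights)) {
    agent_weights <- setNames(c(101, 128, 96, 17, 2, 1, 10) / 355,
                              agent_classes())
  }
  stopifnot(
    n_diseases >= 0,
    length(seed) == 1, is.finite(seed),
    setequal(names(transmission_weights), transmission_classes()),
    setequal(names(agent_weights), agent_classes()),
    abs(sum(transmission_weights) - 1) < 1e-8,
    abs(sum(agent_weights) - 1) < 1e-8,
    p_worldwide >= 0, p_worldwide <= 1,
    p_bounded >= 0, p_bounded <= 1,
    hit_distribution$size > 0, hit_distribution$mu >= 0,
    n_territories >= 1
  )
  structure(list(
    n_diseases = as.integer(n_diseases), seed = as.integer(seed),
    transmission_weights = transmission_weights[transmission_classes()],
    agent_weights = agent_weights[agent_classes()],
    p_worldwide = p_worldwide,
    hit_distribution = hit_distribution,
    endemic_count_distribution = endemic_count_distribution,
    p_bounded = p_bounded,
    prevalence_density_distribution = prevalence_density_distribution,
    maps_per_disease_distribution = maps_per_disease_distribution,
    n_territories = as.integer(n_territories)
  ), class = "carto_generator_params")
}

# territory codes for a synthetic table: the shipped list first, then
# numeric user-assigned codes if more are requested
territory_codes <- function(n) {
  codes <- default_territories()$country_code
  if (n <= length(codes)) return(codes[seq_len(n)])
  c(codes, sprintf("X%03d", seq_len(n - length(codes))))
}

# heavy-tailed national populations, in persons (unseeded draw)
draw_population <- function(n) {
  codes <- territory_codes(n)
  pop <- pmax(1000, round(rlnorm(n, meanlog = 15.2, sdlog = 1.9)))
  tibble::tibble(country_code = codes, population = pop)
}

#' Generate a synthetic population table
#'
#' A stand-in for national population-at-risk denominators: one row per
#' territory with a heavy-tailed positive population (lognormal, median
#' about 4 million persons, upper tail reaching the billion scale).
#'
#' @param n_territories Number of territories (default 275).
#' @param seed Integer seed.
#' @return A population tibble (`country_code`, `population`).
#' @export
generate_population_table <- function(n_territories = 275, seed = 20100101) {
  stopifnot(n_territories >= 1)
  with_local_seed(seed, draw_population(n_territories))
}

#' Generate a synthetic audit corpus
#'
#' Draws a full corpus — diseases, published-map records and a
#' population table — under the conditions in `params`. Record
#' attributes are drawn field by field in a fixed order from a single
#' seeded stream, so a given seed always yields the same corpus. Map
#' records are generated for non-worldwide diseases and span every
#' rubric category with positive probability. Generated corpora always
#' pass [validate_corpus()].
#'
#' @param params A [generator_params()].
#' @return A `carto_corpus`.
#' @examples
#' corpus <- generate_corpus(generator_params(n_diseases = 25, seed = 42))
#' corpus
#' @export
generate_corpus <- function(params = generator_params()) {
  stopifnot(inherits(params, "carto_generator_params"))
  with_local_seed(params$seed, {
    n <- params$n_diseases
    population <- draw_population(params$n_territories)
    codes <- population$country_code
    if (n == 0) {
      return(new_corpus(empty_diseases(), empty_maps(), population))
    }
    id <- sprintf("D%04d", seq_len(n))
    transmission <- sample(transmission_classes(), n, replace = TRUE,
                           prob = params$transmission_weights)
    agent <- sample(agent_classes(), n, replace = TRUE,
                    prob = params$agent_weights)
    worldwide <- runif(n) < params$p_worldwide
    k <- pmin(1 + rnbinom(n, size = params$endemic_count_distribution$size,
                          mu = params$endemic_count_distribution$mu),
              params$n_territories)
    endemic <- lapply(seq_len(n), function(i) {
      if (worldwide[i]) character(0) else sort(sample(codes, k[i]))
    })
    hits <- rnbinom(n, size = params$hit_distribution$size,
                    mu = params$hit_distribution$mu)
    bounded <- runif(n) < params$p_bounded
    pd <- params$prevalence_density_distribution
    prev_positive <- runif(n) < pd$p_positive
    prev_value <- round(rlnorm(n, pd$meanlog, pd$sdlog), 1)
    prevalence <- ifelse(prev_positive, prev_value, NA_real_)
    diseases <- tibble::tibble(
      disease_id = id,
      name = sprintf("Synthetic disease %d", seq_len(n)),
      transmission = transmission, agent = agent, worldwide = worldwide,
      endemic_countries = endemic, pubmed_hits = as.numeric(hits),
      prevalence_records_per_country = prevalence,
      reservoir_or_vector_bounded = bounded,
      option_override = NA_integer_, override_note = NA_character_,
      r0_annotation = NA_character_)

    map_rows <- list()
    lambda <- params$maps_per_disease_distribution$lambda
    for (i in seq_len(n)) {
      if (worldwide[i]) next
      n_maps <- rpois(1, lambda)
      for (j in seq_len(n_maps)) {
        year_known <- runif(1) < 0.85
        multi_period <- year_known && runif(1) < 0.15
        diagnostic <- sample(diagnostic_categories(), 1)
        covered <- endemic[[i]][runif(length(endemic[[i]])) < 0.7]
        map_rows[[length(map_rows) + 1]] <- tibble::tibble(
          map_id = sprintf("M%s-%02d", id[i], j),
          disease_id = id[i],
          target = sample(map_targets(), 1, prob = c(0.8, 0.15, 0.05)),
          year_known = year_known,
          most_recent_year = if (year_known)
            sample(1970:2010, 1) else NA_integer_,
          multi_period = multi_period,
          diagnostic = diagnostic,
          serology_support = diagnostic == "survey_or_confirmed_case" &&
            runif(1) < 0.5,
          geo = sample(geo_categories(), 1),
          method = sample(map_methods(), 1),
          countries_covered = list(covered),
          citation = sprintf("Synthetic citation for %s map %d", id[i], j))
      }
    }
    maps <- if (length(map_rows) == 0) empty_maps()
            else dplyr::bind_rows(map_rows)
    new_corpus(diseases, maps, population)
  })
}

#' Marginal targets for constructive corpus generation
#'
#' Declares the exact counts a generated corpus must reproduce when
#' classified and summarized: diseases per mapping option, and
#' optionally `(total, rationale)` pairs per transmission route and per
#' agent class. Targets must be jointly consistent: category totals sum
#' to the option totals and category rationale counts to the Option 2-5
#' total, whenever both are given.
#'
#' @param by_option Named counts over options `"1"`-`"5"` (missing
#'   options count 0).
#' @param by_transmission,by_agent Optional data frames with columns
#'   `category`, `total`, `rationale`, or named lists of
#'   `c(total, rationale)` pairs.
#' @return A list of class `carto_marginal_spec`.
#' @examples
#' marginal_spec(by_option = c(`1` = 2, `2` = 3))
#' @export
marginal_spec <- function(by_option = NULL, by_transmission = NULL,
                          by_agent = NULL) {
  norm_pairs <- function(x, levels, what) {
    if (is.null(x)) return(NULL)
    if (!is.data.frame(x)) {
      x <- tibble::tibble(
        category = names(x),
        total = vapply(x, function(p) p[[1]], numeric(1)),
        rationale = vapply(x, function(p) p[[2]], numeric(1)))
    }
    stopifnot(all(c("category", "total", "rationale") %in% names(x)))
    bad <- setdiff(x$category, levels)
    if (length(bad) > 0) {
      abort(sprintf("unknown %s category: %s", what,
                    paste(bad, collapse = ", ")),
            class = "cartoaudit_enum_error")
    }
    full <- tibble::tibble(category = levels) |>
      dplyr::left_join(x, by = "category") |>
      dplyr::mutate(total = ifelse(is.na(.data$total), 0, .data$total),
                    rationale = ifelse(is.na(.data$rationale), 0,
                                       .data$rationale))
    if (any(full$total < 0) || any(full$rationale < 0) ||
        any(full$rationale > full$total)) {
      abort(sprintf("%s marginals need 0 <= rationale <= total", what),
            class = "cartoaudit_marginal_error")
    }
    full
  }
  opt <- setNames(rep(0, 5), as.character(1:5))
  if (!is.null(by_option)) {
    if (is.null(names(by_option)) ||
        !all(names(by_option) %in% names(opt))) {
      abort("by_option must be named with options \"1\"..\"5\"",
            class = "cartoaudit_marginal_error")
    }
    if (any(by_option < 0)) {
      abort("option targets must be non-negative",
            class = "cartoaudit_marginal_error")
    }
    opt[names(by_option)] <- by_option
  }
  spec <- structure(list(
    by_option = opt,
    by_transmission = norm_pairs(by_transmission, transmission_classes(),
                                 "transmission"),
    by_agent = norm_pairs(by_agent, agent_classes(), "agent")
  ), class = "carto_marginal_spec")

  # derive option targets from category marginals when none were given
  derive_from <- spec$by_transmission %||% spec$by_agent
  if (is.null(by_option) && !is.null(derive_from)) {
    spec$by_option["1"] <- sum(derive_from$total - derive_from$rationale)
    spec$by_option["2"] <- sum(derive_from$rationale)
  }
  check <- function(tbl, what) {
    if (is.null(tbl)) return()
    if (sum(tbl$total) != sum(spec$by_option) ||
        sum(tbl$rationale) != sum(spec$by_option[as.character(2:5)])) {
      abort(sprintf(
        "%s marginals are inconsistent with the option targets", what),
        class = "cartoaudit_marginal_error")
    }
  }
  if (!is.null(by_option) || !is.null(spec$by_transmission) ||
      !is.null(spec$by_agent)) {
    check(spec$by_transmission, "transmission")
    check(spec$by_agent, "agent")
  }
  spec
}

#' Construct a corpus matching marginal targets exactly
#'
#' Builds a disease corpus whose classification under the default
#' configuration reproduces every requested marginal count exactly.
#' Matching is constructive, not sampled: each target cell is filled
#' with diseases whose worldwide flag, hit density, boundedness and
#' prevalence density force the intended option (worldwide for
#' Option 1; 10 hits per country, unbounded, for Option 2; the same but
#' range-bounded for Option 3; 60 hits per country for Option 4; 60
#' hits per country plus a prevalence density above the cutoff for
#' Option 5), transmission and agent labels are dealt to the rationale
#' and non-rationale strata to meet the category marginals, and the
#' rows are then shuffled with the seed. The map table is empty; the
#' corpus carries a seeded synthetic population table.
#'
#' @param spec A [marginal_spec()].
#' @param seed Integer seed for the row shuffle and population table.
#' @return A `carto_corpus` that passes [validate_corpus()].
#' @examples
#' corpus <- generate_from_marginals(
#'   marginal_spec(by_option = c(`1` = 3, `2` = 2, `5` = 1)), seed = 1)
#' table(classify_corpus(corpus$diseases)$option)
#' @export
generate_from_marginals <- function(spec, seed = 20100101) {
  stopifnot(inherits(spec, "carto_marginal_spec"))
  targets <- spec$by_option
  n <- sum(targets)
  population <- generate_population_table(275, seed)
  if (n == 0) {
    return(new_corpus(empty_diseases(), empty_maps(), population))
  }
  option <- rep(1:5, times = targets)
  rationale <- option != 1L

  assign_categories <- function(tbl, fallback_levels) {
    if (is.null(tbl)) {
      return(rep_len(fallback_levels, n))
    }
    out <- character(n)
    out[rationale] <- rep(tbl$category, times = tbl$rationale)
    out[!rationale] <- rep(tbl$category, times = tbl$total - tbl$rationale)
    out
  }
  transmission <- assign_categories(spec$by_transmission,
                                    transmission_classes())
  agent <- assign_categories(spec$by_agent, agent_classes())

  codes <- population$country_code
  n_codes <- length(codes)
  per_option <- list(
    `1` = list(worldwide = TRUE, k = 0, hits = 500, bounded = FALSE,
               prev = NA_real_),
    `2` = list(worldwide = FALSE, k = 4, hits = 40, bounded = FALSE,
               prev = NA_real_),
    `3` = list(worldwide = FALSE, k = 4, hits = 40, bounded = TRUE,
               prev = NA_real_),
    `4` = list(worldwide = FALSE, k = 2, hits = 120, bounded = FALSE,
               prev = NA_real_),
    `5` = list(worldwide = FALSE, k = 2, hits = 120, bounded = FALSE,
               prev = 30))
  cell <- function(i) per_option[[as.character(option[i])]]
  endemic <- lapply(seq_len(n), function(i) {
    p <- cell(i)
    if (p$k == 0) return(character(0))
    idx <- ((7 * i + seq_len(p$k) - 1) %% n_codes) + 1
    sort(codes[idx])
  })
  diseases <- tibble::tibble(
    disease_id = sprintf("SD%04d", seq_len(n)),
    name = sprintf("Synthetic marginal disease %d", seq_len(n)),
    transmission = transmission,
    agent = agent,
    worldwide = vapply(seq_len(n), function(i) cell(i)$worldwide, logical(1)),
    endemic_countries = endemic,
    pubmed_hits = vapply(seq_len(n), function(i) cell(i)$hits, numeric(1)),
    prevalence_records_per_country =
      vapply(seq_len(n), function(i) cell(i)$prev, numeric(1)),
    reservoir_or_vector_bounded =
      vapply(seq_len(n), function(i) cell(i)$bounded, logical(1)),
    option_override = NA_integer_,
    override_note = NA_character_,
    r0_annotation = NA_character_)
  perm <- with_local_seed(seed, sample(n))
  new_corpus(diseases[perm, ], empty_maps(), population)
}
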