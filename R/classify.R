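#' Occurrence-literature density per endemic country
#'
#' The data-availability statistic behind the mapping-option rules: the
#' number of occurrence-literature records (PubMed hits for the disease
#' name) divided by the number of endemic countries. The division is
#' exact; rounding is presentation-only via [display_hits()], so a
#' disease sitting on the cutoff is classified from the unrounded value.
#'
#' @param pubmed_hits Non-negative count(s) of occurrence-literature
#'   records.
#' @param n_endemic Positive count(s) of endemic countries.
#' @return `pubmed_hits / n_endemic`, unrounded.
#' @examples
#' hits_per_country(90, 11) # ~8.18, displayed as "about 8 per country"
#' @export
hits_per_country <- function(pubmed_hits, n_endemic) {
  if (any(is.na(n_endemic)) || any(n_endemic < 1)) {
    abort("hits-per-country density is undefined without endemic countries",
          class = "cartoaudit_density_error")
  }
  if (any(is.na(pubmed_hits)) || any(pubmed_hits < 0)) {
    abort("pubmed_hits must be non-negative",
          class = "cartoaudit_density_error")
  }
  pubmed_hits / n_endemic
}

#' @rdname hits_per_country
#' @param density A density from [hits_per_country()].
#' @export
display_hits <- function(density) round_half_up(density)

#' Does a mapping option carry a rationale for mapping?
#'
#' Option 1 ("do not map") is reserved for diseases occurring worldwide
#' with no sustained spatial variation; every other option implies the
#' disease's distribution is worth mapping.
#'
#' @param option Integer vector of mapping options (1-5).
#' @return Logical vector, `FALSE` exactly for Option 1.
#' @export
has_mapping_rationale <- function(option) {
  stopifnot(all(option %in% mapping_options()))
  option != 1L
}

#' Assign a mapping option to one disease
#'
#' Applies the decision rules in fixed order:
#'
#' 1. an expert `option_override` (recorded when richer systematic
#'    occurrence searches are known than the literature counts reflect)
#'    takes absolute precedence;
#' 2. worldwide occurrence means no sustained spatial variation:
#'    Option 1, do not map;
#' 3. fewer hits per endemic country than the cutoff with no known
#'    reservoir/vector bound: Option 2, map observed occurrence;
#' 4. the same data paucity but a reservoir or vector distribution that
#'    bounds the range: Option 3, map the maximum potential range;
#' 5. adequate occurrence data (at or above the cutoff) and more than
#'    the cutoff of systematically recorded prevalence records per
#'    country: Option 5, geostatistical endemicity mapping;
#' 6. adequate occurrence data otherwise: Option 4, niche/occurrence
#'    modelling.
#'
#' Density exactly at the cutoff falls on the adequate side, since only
#' "fewer than" the cutoff is defined as paucity; absent prevalence data
#' counts as zero.
#'
#' @param disease A one-row diseases tibble (or list with the same
#'   fields).
#' @param config An [audit_config()].
#' @return A one-row tibble: `disease_id`, `option`, `hits_per_country`
#'   (`NA` for worldwide diseases with no endemic list), `rationale`,
#'   `overridden`, `rule_trace` (";"-separated rule names).
#' @examples
#' d <- generate_corpus(generator_params(n_diseases = 3, seed = 1))$diseases
#' classify_option(d[1, ], audit_config())
#' @export
classify_option <- function(disease, config = audit_config()) {
  id <- disease$disease_id[[1]]
  worldwide <- isTRUE(disease$worldwide[[1]])
  endemic <- disease$endemic_countries[[1]]
  hits <- disease$pubmed_hits[[1]]
  prev <- disease$prevalence_records_per_country[[1]]
  if (is.na(prev)) prev <- 0
  bounded <- isTRUE(disease$reservoir_or_vector_bounded[[1]])
  override <- disease$option_override[[1]]

  density <- if (length(endemic) >= 1) hits_per_country(hits, length(endemic))
             else NA_real_

  trace <- character(0)
  if (!is.na(override)) {
    option <- as.integer(override)
    trace <- c("expert-override", paste0("option-", option))
    overridden <- TRUE
  } else {
    overridden <- FALSE
    if (worldwide) {
      option <- 1L
      trace <- c("worldwide", "option-1")
    } else {
      if (is.na(density)) {
        abort(sprintf(
          "disease '%s': density undefined (no endemic countries); run validate_corpus first",
          id), class = "cartoaudit_density_error")
      }
      if (density < config$hits_cutoff) {
        trace <- "data-poor"
        if (bounded) {
          option <- 3L
          trace <- c(trace, "reservoir-or-vector-bounded", "option-3")
        } else {
          option <- 2L
          trace <- c(trace, "unbounded", "option-2")
        }
      } else {
        trace <- "data-adequate"
        if (prev > config$hits_cutoff) {
          option <- 5L
          trace <- c(trace, "prevalence-rich", "option-5")
        } else {
          option <- 4L
          trace <- c(trace, "prevalence-scarce", "option-4")
        }
      }
    }
  }
  tibble::tibble(
    disease_id = id,
    option = option,
    hits_per_country = density,
    rationale = has_mapping_rationale(option),
    overridden = overridden,
    rule_trace = paste(trace, collapse = ";")
  )
}

#' Classify every disease of a corpus
#'
#' Applies [classify_option()] to each disease, preserving input order.
#' A pure function of its inputs: permuting the diseases permutes the
#' results identically.
#'
#' @param diseases Diseases tibble (validated).
#' @param config An [audit_config()].
#' @return A tibble with one classification row per disease.
#' @examples
#' corpus <- generate_corpus(generator_params(n_diseases = 10, seed = 1))
#' table(classify_corpus(corpus$diseases)$option)
#' @export
classify_corpus <- function(diseases, config = audit_config()) {
  if (nrow(diseases) == 0) {
    return(tibble::tibble(
      disease_id = character(0), option = integer(0),
      hits_per_country = numeric(0), rationale = logical(0),
      overridden = logical(0), rule_trace = character(0)))
  }
  purrr::map_dfr(seq_len(nrow(diseases)),
                 function(i) classify_option(diseases[i, ], config))
}
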