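#' Integer percentage with round-half-up
#'
#' Reported percentages use round-half-up to whole percent (so 174 of
#' 355 prints as 49 and 7 of 174 as 4); raw rationals are retained
#' wherever the summary is serialized.
#'
#' @param numerator,denominator Counts; `denominator` must be positive.
#' @return An integer percent.
#' @examples
#' rationale_percentage(174, 355) # 49
#' rationale_percentage(7, 174)   # 4
#' @export
rationale_percentage <- function(numerator, denominator) {
  if (any(denominator < 1)) {
    abort("percentage undefined for a zero denominator",
          class = "cartoaudit_summary_error")
  }
  as.integer(round_half_up(100 * numerator / denominator))
}

#' Corpus-level summary
#'
#' Aggregates the audit: disease counts by mapping option, by
#' transmission route and by agent class (each with its
#' rationale-for-mapping subset), the number and percentage of diseases
#' with a mapping rationale, and how many of those have at least one
#' satisfactory map. A rationale disease with no scored map contributes
#' a best metascore of 0 and is therefore never satisfactory.
#'
#' @param classifications Output of [classify_corpus()].
#' @param diseases The diseases tibble the classifications came from.
#' @param best_scores Optional tibble from [best_metascores()]; omit
#'   (or pass zero rows) when no maps were scored.
#' @param config An [audit_config()].
#' @return A list of class `carto_summary`: `n_diseases`, `by_option`
#'   (named counts over options 1-5), `by_transmission` and `by_agent`
#'   (tibbles with `total` and `rationale` per category, every category
#'   present), `n_rationale`, `n_satisfactory`, `pct_rationale`,
#'   `pct_satisfactory_of_rationale`.
#' @examples
#' corpus <- generate_corpus(generator_params(n_diseases = 30, seed = 2))
#' cls <- classify_corpus(corpus$diseases)
#' summarize_corpus(cls, corpus$diseases)
#' @export
summarize_corpus <- function(classifications, diseases, best_scores = NULL,
                             config = audit_config()) {
  if (!setequal(classifications$disease_id, diseases$disease_id) ||
      nrow(classifications) != nrow(diseases)) {
    abort("classifications and diseases cover different disease keys",
          class = "cartoaudit_summary_error")
  }
  n <- nrow(diseases)
  by_option <- vapply(mapping_options(), function(o) {
    sum(classifications$option == o)
  }, integer(1))
  names(by_option) <- as.character(mapping_options())
  n_rationale <- sum(classifications$rationale)

  rationale_of <- setNames(classifications$rationale,
                           classifications$disease_id)
  category_table <- function(values, levels) {
    r <- rationale_of[diseases$disease_id]
    tibble::tibble(
      category = levels,
      total = unname(vapply(levels, function(l) sum(values == l),
                            integer(1))),
      rationale = unname(vapply(levels, function(l) sum(values == l & r),
                                integer(1)))
    )
  }
  by_transmission <- category_table(diseases$transmission,
                                    transmission_classes())
  by_agent <- category_table(diseases$agent, agent_classes())

  rationale_ids <- classifications$disease_id[classifications$rationale]
  best <- setNames(rep(0, length(rationale_ids)), rationale_ids)
  if (!is.null(best_scores) && nrow(best_scores) > 0) {
    hit <- intersect(best_scores$disease_id, rationale_ids)
    best[hit] <- best_scores$metascore[match(hit, best_scores$disease_id)]
  }
  n_satisfactory <- sum(is_satisfactory(best, config))

  structure(list(
    n_diseases = n,
    by_option = as.list(by_option),
    by_transmission = by_transmission,
    by_agent = by_agent,
    n_rationale = n_rationale,
    n_satisfactory = n_satisfactory,
    pct_rationale = if (n > 0) rationale_percentage(n_rationale, n) else 0L,
    pct_rationale_raw = if (n > 0) 100 * n_rationale / n else 0,
    pct_satisfactory_of_rationale =
      if (n_rationale > 0) rationale_percentage(n_satisfactory, n_rationale)
      else 0L,
    pct_satisfactory_of_rationale_raw =
      if (n_rationale > 0) 100 * n_satisfactory / n_rationale else 0
  ), class = "carto_summary")
}

#' @export
print.carto_summary <- function(x, ...) {
  cat("<carto_summary>\n")
  cat(sprintf("  %d diseases; %d (%d%%) with a rationale for mapping\n",
              x$n_diseases, x$n_rationale, x$pct_rationale))
  cat("  by option:",
      paste(sprintf("%s:%d", names(x$by_option), unlist(x$by_option)),
            collapse = "  "), "\n")
  cat(sprintf("  %d (%d%%) of rationale diseases satisfactorily mapped\n",
              x$n_satisfactory, x$pct_satisfactory_of_rationale))
  invisible(x)
}

#' Best-metascore radial series
#'
#' The series behind the radial information-deficit plots: one entry
#' per disease with a mapping rationale, carrying its best metascore
#' (0 when no map has been scored), ordered by descending metascore
#' with ties broken by `disease_id`.
#'
#' @param best_scores Tibble from [best_metascores()] (may be `NULL` or
#'   empty).
#' @param rationale_ids Character vector of disease ids with a mapping
#'   rationale.
#' @return A tibble (`disease_id`, `best_metascore`) in plotting order.
#' @export
radial_series <- function(best_scores, rationale_ids) {
  best <- setNames(rep(0, length(rationale_ids)), rationale_ids)
  if (!is.null(best_scores) && nrow(best_scores) > 0) {
    hit <- intersect(best_scores$disease_id, rationale_ids)
    best[hit] <- best_scores$metascore[match(hit, best_scores$disease_id)]
  }
  tibble::tibble(disease_id = names(best), best_metascore = unname(best)) |>
    dplyr::arrange(dplyr::desc(best_metascore), disease_id)
}

#' Binary country-level endemicity coding
#'
#' The thumbnail-map data layer: each territory coded 1 if the disease
#' is endemic there (every territory for a worldwide disease) and 0
#' otherwise.
#'
#' @param disease One-row diseases tibble.
#' @param territory_list Character vector of territory codes, or a
#'   tibble with a `country_code` column (default: the shipped
#'   275-territory list).
#' @return A tibble (`disease_id`, `country_code`, `endemic`) covering
#'   the full territory list in its order.
#' @export
thumbnail_endemicity <- function(disease,
                                 territory_list = default_territories()) {
  if (is.data.frame(territory_list)) {
    territory_list <- territory_list$country_code
  }
  if (length(territory_list) == 0) {
    abort("territory list is empty", class = "cartoaudit_summary_error")
  }
  endemic <- disease$endemic_countries[[1]]
  worldwide <- isTRUE(disease$worldwide[[1]])
  if (!worldwide) {
    outside <- setdiff(endemic, territory_list)
    if (length(outside) > 0) {
      abort(sprintf("endemic code(s) absent from the territory list: %s",
                    paste(outside, collapse = ", ")),
            class = "cartoaudit_summary_error")
    }
  }
  tibble::tibble(
    disease_id = disease$disease_id[[1]],
    country_code = territory_list,
    endemic = if (worldwide) 1L else as.integer(territory_list %in% endemic)
  )
}
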