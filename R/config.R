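#' Audit configuration
#'
#' Bundles the framework's constants. The defaults are the published
#' values of the audit: occurrence literature is deemed scarce below 25
#' PubMed hits per endemic country, a map is a satisfactory global
#' assessment at a metascore of 75 points or more, contemporariness bands
#' close at 10 and 20 years of data age, and maps are assessed as of 2011.
#'
#' @param hits_cutoff Positive number; hits-per-endemic-country threshold
#'   separating data-poor diseases (Options 2-3) from data-rich ones
#'   (Options 4-5). Density exactly at the cutoff counts as adequate.
#'   The same cutoff bounds the prevalence-record density required for
#'   Option 5 (strictly greater than the cutoff).
#' @param satisfactory_threshold Metascore points in (0, 100]; scores
#'   greater than or equal to this are satisfactory.
#' @param contemporary_bands Increasing pair of year counts closing the
#'   3-point and 2-point contemporariness bands.
#' @param assessment_year Calendar year the audit is performed in; data
#'   age is measured against it.
#' @return A list of class `carto_config`.
#' @examples
#' cfg <- audit_config()
#' cfg$hits_cutoff
#' @export
audit_config <- function(hits_cutoff = 25,
                         satisfactory_threshold = 75,
                         contemporary_bands = c(10, 20),
                         assessment_year = 2011) {
  stopifnot(
    is.numeric(hits_cutoff), length(hits_cutoff) == 1, hits_cutoff > 0,
    is.numeric(satisfactory_threshold), length(satisfactory_threshold) == 1,
    satisfactory_threshold > 0, satisfactory_threshold <= 100,
    is.numeric(contemporary_bands), length(contemporary_bands) == 2,
    contemporary_bands[1] > 0, contemporary_bands[1] < contemporary_bands[2],
    is.numeric(assessment_year), length(assessment_year) == 1
  )
  structure(
    list(hits_cutoff = hits_cutoff,
         satisfactory_threshold = satisfactory_threshold,
         quality_max = 9,
         contemporary_bands = contemporary_bands,
         assessment_year = assessment_year),
    class = "carto_config"
  )
}

#' @export
print.carto_config <- function(x, ...) {
  cat("<carto_config>\n")
  cat("  hits cutoff:            ", x$hits_cutoff, "hits per endemic country\n")
  cat("  satisfactory threshold: ", x$satisfactory_threshold, "metascore points\n")
  cat("  quality maximum:        ", x$quality_max, "\n")
  cat("  contemporary bands:     ", paste(x$contemporary_bands, collapse = "/"),
      "years\n")
  cat("  assessment year:        ", x$assessment_year, "\n")
  invisible(x)
}

# round-half-up to integer, the convention used for reported percentages
round_half_up <- function(x) floor(x + 0.5)
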