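# cartoaudit

Most clinically important infectious diseases have never been reliably
mapped. **cartoaudit** is an R implementation of a quantitative
framework for auditing that gap, for spatial epidemiologists and public
health cartographers: given a curated table of diseases, a table of
previously published maps, and national populations, it decides what
kind of global map each disease's data could support and scores how
well existing maps meet that potential.

## The framework

**Mapping options.** Each disease is classified by fixed-order decision
rules into one of five cartographic strategies:

| Option | Strategy | Rule |
|---|---|---|
| 1 | do not map | occurs worldwide, no sustained spatial variation |
| 2 | map observed occurrence | hits/endemic country < cutoff (25), range unbounded |
| 3 | map maximum potential range | hits/country < cutoff, known reservoir/vector bound |
| 4 | niche/occurrence modelling | hits/country ≥ cutoff |
| 5 | geostatistical endemicity mapping | additionally prevalence records/country > cutoff |

An expert override (documented richer occurrence searches) takes
precedence and is logged. Options 2–5 constitute a *rationale for
mapping*.

**Metascore.** Every published map is scored

```
metascore = quality/9 × scope% × min(option used / option potential, 1)   ∈ [0, 100]
```

where *quality* (0–9) sums three half-point-lattice subscores —
contemporariness (3 points for data < 10 years old, 2 for 10–<20, 1 for
≥ 20, 2.5 for multi-period country databases, 0 unknown), diagnostic
accuracy (3 genotype/PCR … 0 unknown source, +0.5 for serology on
survey data) and geo-positional accuracy (3 GPS … 0 none) — *scope* is
the percentage of the endemic population at risk the map covers at
national resolution, and the option ratio compares the method used
(occurrence points → 2, range map → 3, niche model → 4, geostatistics →
5) with the disease's assessed potential. Scores ≥ 75 denote a
satisfactory global assessment.

Corpus summaries count diseases per option, transmission route and
agent class (with rationale subsets), build the best-map radial series,
and export binary country-level endemicity codings. A seeded synthetic
generator — including exact constructive matching of requested marginal
counts — replaces the proprietary source database.

## Worked example

An occurrence-point map of full data quality and complete scope, for a
disease whose rich literature (2000 hits over 2 endemic countries)
supports niche modelling:

```r
library(cartoaudit)

pop <- tibble::tibble(country_code = c("NGA", "SLE"),
                      population = c(158e6, 5.8e6))
lassa <- tibble::tibble(
  disease_id = "lassa", name = "Lassa-like fever",
  transmission = "animal_contact", agent = "virus", worldwide = FALSE,
  endemic_countries = list(c("NGA", "SLE")), pubmed_hits = 2000,
  prevalence_records_per_country = NA_real_,
  reservoir_or_vector_bounded = TRUE, option_override = NA_integer_,
  override_note = NA_character_, r0_annotation = NA_character_)

(cls <- classify_option(lassa))
#>   disease_id option hits_per_country rationale overridden rule_trace
#> 1 lassa           4             1000 TRUE      FALSE      data-adequate;prevalence-scarce;option-4

occ_map <- tibble::tibble(
  map_id = "m1", disease_id = "lassa", target = "disease",
  year_known = TRUE, most_recent_year = 2005L, multi_period = FALSE,
  diagnostic = "genotype_pcr", serology_support = FALSE,
  geo = "gps_coordinates", method = "occurrence_points",
  countries_covered = list(c("NGA", "SLE")), citation = "example")

score_map(occ_map, lassa, cls$option, pop)[
  , c("quality", "scope_pct", "option_ratio", "metascore", "satisfactory")]
#>   quality scope_pct option_ratio metascore satisfactory
#> 1       9       100          0.5        50 FALSE
```

Perfect data plotted with the wrong technique: option ratio 2/4,
metascore 50, not satisfactory. At corpus scale, a synthetic corpus
constructed to published per-option counts classifies back exactly:

```r
corpus <- generate_from_marginals(
  marginal_spec(by_option = c(`1` = 181, `2` = 64, `3` = 32,
                              `4` = 68, `5` = 10)), seed = 1)
summarize_corpus(classify_corpus(corpus$diseases), corpus$diseases)
#> <carto_summary>
#>   355 diseases; 174 (49%) with a rationale for mapping
#>   by option: 1:181  2:64  3:32  4:68  5:10
#>   0 (0%) of rationale diseases satisfactorily mapped
```

(The constructed corpus carries no map records, so no disease is
satisfactorily mapped.) `run_pipeline()` — or the
`inst/scripts/cartoaudit.R` command-line front end — chains simulate →
validate → classify → score → summarize into one reproducible run with
a digest manifest.

## Package layout

- `R/` — corpus model and I/O, validation, option classifier, map
  scorer, aggregation, synthetic generator, pipeline.
- `inst/extdata/territories.csv` — editable 275-entry territory list
  (ISO 3166-1 alpha-3 plus flagged synthetic placeholders).
- `inst/scripts/cartoaudit.R` — CLI subcommands
  `simulate|classify|score|summarize|thumbnail|run`.
- `vignettes/cartoaudit-methods.Rmd` — the model, its assumptions,
  parameter choices and limitations.
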