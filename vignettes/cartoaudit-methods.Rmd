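---
title: "Auditing disease cartography: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing disease cartography: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartoaudit)
```

## The problem

For most infectious diseases of clinical importance, we do not have a
reliable map of where they occur. cartoaudit implements a quantitative
audit of that gap. It answers two questions per disease: *what kind of
map could be made with the data that exist?* (the mapping option), and
*how good are the maps that have been made?* (the metascore). The audit
is driven entirely by curated tabular inputs — a disease table, a table
of previously published maps, and a country population table — so it is
reproducible and re-runnable as the evidence base grows.

## The mapping-option decision rules

Each disease is assigned one of five cartographic strategies from
data-availability rules, applied in a fixed order:

1. **Option 1 — do not map.** The disease occurs worldwide and shows no
   sustained spatial variation in occurrence (cosmopolitan sexually
   transmitted, endogenous and common respiratory infections). There is
   no rationale for global occurrence mapping.
2. **Option 2 — map observed occurrence.** Occurrence literature is
   scarce — fewer hits per endemic country than the cutoff (default
   25) — and nothing bounds the potential range.
3. **Option 3 — map the maximum potential range.** The same data
   paucity, but a known reservoir or vector distribution bounds where
   the disease can occur.
4. **Option 4 — niche/occurrence modelling.** Adequate occurrence data
   (at or above the cutoff per endemic country) support
   presence/pseudo-absence ecological niche modelling.
5. **Option 5 — geostatistical endemicity mapping.** On top of adequate
   occurrence data, systematically recorded prevalence surveys exceed
   the cutoff per country, enabling model-based geostatistics with full
   uncertainty.

An expert override field takes absolute precedence over the rules and
is logged: it records cases where richer systematic occurrence searches
are known than the raw literature counts reflect. Every classification
carries a `rule_trace` naming the rules fired.

Two boundary choices are deliberate and configuration-visible. The hit
density is used unrounded (rounding is presentation-only, so a disease
with 90 hits over 11 countries classifies from 8.18, displayed as "8"),
and a density of exactly the cutoff falls on the *adequate* side,
because only densities strictly below the cutoff are defined as data
paucity. The Option 5 prevalence criterion is strict (`> cutoff`), and
absent prevalence data counts as zero. How prevalence-record density
should be counted is genuinely open (per endemic country from any
systematic source is one reading); we treat it as a curated input with
exactly those semantics.

## The metascore

Every published map of a disease, its vector or its reservoir is scored

$$\text{metascore} = \frac{\text{quality}}{9} \times \text{scope}\,(\%)
  \times \min\!\left(\frac{\text{option used}}{\text{option potential}}, 1\right)
  \in [0, 100],$$

with 75 points or more deemed a satisfactory global assessment
(inclusive threshold).

**Quality (0–9)** sums three subscores on a half-point lattice:

* *Contemporariness* — 3 for data under 10 years old at the assessment
  year (default 2011), 2 for 10 to under 20 years, 1 for 20 years or
  older, 0 when no age is identifiable; multi-period country databases
  score 2.5. Exactly-10-year-old data scores 2 and exactly-20-year-old
  data scores 1: the bands close on the side their stated inequalities
  dictate.
* *Diagnostic accuracy* — 3 for genotype/PCR confirmation (or advanced
  modelling on many occurrence points, for vector maps), 2 for health
  surveys/confirmed cases (+0.5 when serology supported them; the
  half-point attaches to this category only, and half-points are not
  stacked across categories), 2 for interpolated vector occurrence, 1
  for cited literature, routine HMIS/presumptive diagnosis or vector
  expert opinion, 0.5 for non-specific numerical data (read as its own
  category), 0 for unknown sources. Capped at 3.
* *Geo-positional accuracy* — 3 for GPS coordinates, 2 for derived
  coordinates or admin level 1, 2.5 when admin level 2 or named towns
  were used, 1 for approximate or country-level positions, 0.5 for
  expert-opinion ranges, 0 for none.

**Scope (0–100%)** is population at risk covered: the summed national
population of endemic countries the map reaches, as a percentage of the
total endemic population, both resolved at national level. Countries a
map covers outside the endemic set are ignored, so scope depends only
on the intersection. Scope enters the product as a 0–100 percentage —
the only reading under which full quality, full scope and a matched
option reach the stated maximum of 100.

**Option ratio** relates the option the map's method realizes
(occurrence points → 2, extent/range map → 3, niche model → 4,
geostatistical endemicity → 5) to the disease's assessed potential. It
is capped at 1 so a map exceeding its disease's assessed potential
cannot score above 100. Vector and reservoir maps are scored with the
same formula, with scope still measured against the *disease's*
endemic population — the rubric never states a separate denominator for
them, and the disease's population at risk is the audit's common
currency. Maps of Option 1 diseases are rejected (dropped with a
warning at corpus level) rather than silently scored: the framework
only metascores diseases with a mapping rationale, and a disease with
no scored map contributes a best metascore of 0 to reporting.

Reported integer percentages use round-half-up (so 174 of 355 prints as
49%), while serialized summaries retain the raw rationals; the radial
series breaks metascore ties lexicographically by disease id, a rule
the framework fixes because plots need a deterministic order.

## Worked example

```{r worked}
pop <- tibble::tibble(country_code = c("NGA", "SLE"),
                      population = c(158e6, 5.8e6))
lassa <- tibble::tibble(
  disease_id = "lassa", name = "Lassa-like fever",
  transmission = "animal_contact", agent = "virus", worldwide = FALSE,
  endemic_countries = list(c("NGA", "SLE")), pubmed_hits = 2000,
  prevalence_records_per_country = NA_real_,
  reservoir_or_vector_bounded = TRUE, option_override = NA_integer_,
  override_note = NA_character_, r0_annotation = NA_character_)
cls <- classify_option(lassa)          # rich literature -> Option 4
cls$option
occ_map <- tibble::tibble(
  map_id = "m1", disease_id = "lassa", target = "disease",
  year_known = TRUE, most_recent_year = 2005L, multi_period = FALSE,
  diagnostic = "genotype_pcr", serology_support = FALSE,
  geo = "gps_coordinates", method = "occurrence_points",
  countries_covered = list(c("NGA", "SLE")), citation = "example")
score_map(occ_map, lassa, cls$option, pop)[, c("quality", "scope_pct",
                                               "option_ratio", "metascore")]
```

A perfect-quality, full-scope occurrence-point map of an Option 4
disease achieves the option ratio 2/4 and a metascore of 50 — good data,
wrong technique, hence unsatisfactory.

## The synthetic corpus generator

The underlying clinical disease database is proprietary, so the
generator emulates its structure instead of redistributing it. The
defaults are the audited corpus's aggregate conditions: 355 diseases;
transmission-route weights proportional to the published per-route
totals (20, 14, 23, 35, 82, 39, 11, 21, 11, 88, 11); agent weights
proportional to the published partition (101 viral, 128 bacterial, 96
parasitic, 17 fungal, 2 protoctistan, 1 algal, 10 unknown); worldwide
probability 181/355; and a 275-territory population table. Where the
source conditions are not stated numerically we fixed, once, values a
field epidemiologist would call realistic and did not revisit them:

* occurrence hits follow a negative binomial with `size = 0.35`,
  `mu = 300` — heavily right-skewed, spanning zero-hit rarities to
  literatures of tens of thousands, mimicking the spread from obscure
  zoonoses to malaria-scale corpora;
* endemic-country counts are `1 + NB(size = 0.8, mu = 19)`, truncated
  to the territory list — most diseases are endemic in a handful of
  countries, a minority in a hundred or more;
* a data-poor disease has a range-bounding reservoir/vector with
  probability 1/3 (the published ratio of maximum-potential-range to
  observed-occurrence classifications);
* prevalence-survey density is a zero-inflated lognormal
  (`p_positive = 0.2`, `meanlog = 2.5`, `sdlog = 1.2`), making
  endemicity-mappable diseases the small minority they are;
* each non-worldwide disease carries a Poisson(1.2) number of map
  records whose rubric categories are drawn so every category occurs
  with positive probability;
* national populations are lognormal (`meanlog = 15.2`,
  `sdlog = 1.9`), median around four million with a billion-scale tail.

All attributes are drawn field by field in a fixed order from a single
seeded Mersenne-Twister stream (the generator triple is pinned), so a
seed identifies a corpus byte-for-byte across platforms, and the
caller's RNG state is restored afterwards.

`generate_from_marginals()` is different in kind: it *constructs* a
corpus that reproduces requested per-option, per-transmission-route and
per-agent `(total, rationale)` counts exactly, by filling each target
cell with diseases whose fields force the intended option (worldwide
for Option 1; 10 hits per country unbounded/bounded for Options 2/3;
60 hits per country without/with supra-cutoff prevalence density for
Options 4/5), dealing category labels to the rationale and
non-rationale strata, then shuffling rows with the seed. Exactness is
guaranteed by construction, not by rejection sampling; the classifier
and aggregator act as the checking oracles. Its map table is empty —
the marginals constrain diseases, not maps.

What passing tests on synthetic corpora show — and do not show: they
verify the decision rules, rubric arithmetic, aggregation identities
and reproducibility of the printed marginal counts; they cannot
validate the curated judgements (worldwide status, boundedness, rubric
category assignment) that a real audit encodes in its inputs, nor the
per-disease contents of the proprietary source. The shipped
275-territory list is likewise a stand-in (249 officially assigned ISO
3166-1 alpha-3 codes plus 26 user-assigned `XA*` codes, flagged
`synthetic`), not a reconstruction of any specific licensed list; it is
an editable data file and every function accepts an override.

## Numerical and degenerate-input choices

* Classification uses exact rational densities; only display rounds.
* Integer percentages round half up (`floor(x + 0.5)`), matching the
  reporting style; R's default banker's rounding would differ at `.5`.
* Scores are serialized with fixed precision (subscores to one decimal,
  scope and metascore to two, ratios to four) so outputs are
  byte-stable; two runs on identical inputs produce identical digests,
  which the run manifest records.
* An empty corpus summarizes to all-zero counts; a rationale percentage
  over a zero denominator is an error, not `NaN`.
* Best-map ties keep the first map in input order; radial-series ties
  order by disease id.
* A non-worldwide disease with no endemic countries has an undefined
  hit density: validation reports it (`endemic-set-empty`) and the
  classifier refuses it, rather than guessing.
* Validation is total — it returns violations as data and never throws
  on parseable input; strict loading and the pipeline turn violations
  into errors (or, leniently, exclusions) at the boundary.

## Problem sizes

The bundled tests exercise the full categorical decision grid (36
cells), every rubric category, randomized metascore and scope
properties (hundreds of draws), corpora of tens to hundreds of
diseases for pipeline round-trips, one 10,000-disease corpus for
distributional sanity, and the exact 355-disease marginal
reconstructions. These sizes were chosen to cover the combinatorics of
the rules while keeping the whole suite fast on a laptop.

## Known limitations

* Hit counts, prevalence densities and rubric categories are curated
  inputs; the package performs no literature retrieval or free-text
  inference.
* The scope denominator for vector/reservoir maps is a design choice
  (see above), as the rubric leaves it unstated.
* Endemicity exports are data layers (long CSV of 0/1 codes); map
  rendering and boundary geometries are out of scope.
* The option ratio treats option numbers as ordinal rungs; the ratio of
  two rung labels is the rubric's own convention, not an interval-scale
  claim.
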