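---
title: "Methods: ontology-enriched data packages and their analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ontology-enriched data packages and their analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oceanpack)
```

## The packaging model

A data package is a directory: one `datapackage.json` descriptor plus TSV
resources. The descriptor follows the Frictionless Data Package dialect and
adds ontology annotations on fields under the `pm:` namespace. Three terms
per column — what it measures (`rdfType`), its unit (`pm:unitRdfType`) and
the measurement device (`pm:measurementSourceRdfType`) — are what turn a
column of numbers into a reusable measurement: the first makes it
discoverable, the second makes it convertible, and the third lets a
meta-analyst decide whether, say, fluorometric and HPLC-derived chlorophyll
values should be pooled at all.

Several dialect decisions are deliberate:

* **Device-key spelling.** Descriptors in the wild carry the misspelled
  variant `pm:measurmentSourceRdfType`; both spellings are accepted on read
  and exactly one canonical spelling is emitted on write.
* **Canonical serialization.** `save_descriptor()` uses a fixed key order and
  indentation, so structurally equal descriptors are byte-identical and
  `load(save(load(text)))` is the identity on the parsed structure. Unknown
  keys at every level are preserved verbatim (forward compatibility), never
  dropped.
* **Missing values are exact strings.** The missing-value checklist is
  matched without trimming: `"NA "` is data (and will surface as a type
  error on a numeric column), `"NA"` is null. Silent tolerance here is how
  sentinel strings leak into analyses as values.
* **Typed-error cells.** A cell that fails to parse to its declared type is
  carried in-table with its raw text and coordinates rather than raised at
  load time, so the validator can report every defect with a (resource, row,
  column) address in one pass. Loading never coerces silently.
* Encoding is fixed to UTF-8 (BOM stripped); the delimiter defaults to tab.

## Validation

Three check families produce one report with deterministic issue ordering
(resource, row, column, code):

1. *Complete transferability* — every resource file exists and matches its
   declared MD5. MD5 is fixed as the checksum algorithm of the convention;
   the point is transfer-corruption detection, not cryptographic integrity.
2. *Cell conformance* — type errors, strftime-pattern conformance for
   datetime columns (only the declared pattern is accepted; no ISO-8601
   auto-detection, because preserving the source's original formatting is
   part of the contract), and inclusive numeric range constraints. Inclusive
   boundaries mean a latitude of exactly ±90 passes. Range constraints on
   coordinates are the cheap way to catch swapped latitude/longitude
   columns.
3. *Annotation audit* — every field should carry an attribute term; numeric
   fields should also carry a unit and a device term; any annotation whose
   CURIE is absent from the term graph is an error.

Severity policy: all failures are errors except incomplete annotation
triads, which are warnings — real deposited packages legitimately lack
device terms where the source repository never recorded the instrument, and
a validator that fails them outright would punish honest incompleteness.
`--strict` in the CLI promotes warnings to errors.

## The term graph

The ontology store models exactly what subsumption-aware discovery needs:
terms, labels, and is-a edges, with transitive ancestor/descendant closures.
Other OBO relations (part-of, located-in) and OWL reasoning are out of
scope. Term tables are flat TSVs (`curie`, `label`, pipe-separated
`parents`) exported from released ontologies; the bundled table covers the
ENVO/UO/OBI/CHEBI/PATO/PMO fragment used by the fixtures and examples.
Cycles are rejected at load; dangling parents are kept but flagged. Label
resolution is exact and case-insensitive, with no stemming or synonym
expansion — a failed lookup is recoverable, a silently wrong match is not.

Concentration terms are minted from a dead-simple design pattern:
`(CHEBI solute, ENVO material) -> "concentration of <solute> in <material>"`
with an equivalence expression linking the PATO concentration quality
(PATO:0000033), the solute and the material. Minted identifiers live in a
provisional `TEMP:` namespace; the package never fabricates released ENVO
numeric ids. For the same reason, the bundled term table uses
`TEMP:0000001`/`TEMP:0000002` for phosphate and silicic acid concentration
(no released identifier is recorded in it) and marks them as synthetic. The
fixture table's hierarchy placement is simplified (concentration terms sit
directly under the PATO quality; sea water directly under liquid water); the
one subsumption relation the analyses rely on — chlorophyll a concentration
under chlorophyll concentration — mirrors the released hierarchy.

## Harmonization

`build_harmonized_table()` joins attribute columns across packages into a
sample x attribute matrix. The design choices that matter:

* **Join key.** The sample identifier is the value of the
  identifier-annotated (or accession/sample-name) column, joined by exact
  string equality. No fuzzy joining: a false merge is worse than a missed
  one.
* **Exact beats general.** When both an exact-term field and a
  descendant-term field feed one cell, the exact term wins; then a source
  with a device annotation; then package order. The losing value is logged
  in `$conflicts`, never discarded silently, so the table's cell count is
  always reconcilable with its sources.
* **Units.** Conversions are affine maps composed along paths in the unit
  registry; units form dimension groups (connected components) and
  cross-group conversion is refused. Molar (micromolar) and mass-based
  (micromole per kilogram) seawater concentrations are deliberately in
  different groups: converting between them requires a density assumption,
  so `with_density_bridge(registry, density = 1.025)` must be invoked
  explicitly (1.025 kg/L is a standard surface-seawater density;
  `1.025 umol/L / 1.025 = 1.000 umol/kg`), and the assumption is recorded on
  the registry and surfaced in CLI provenance output. Over-harmonization is
  a quiet way to ruin a meta-analysis.
* **Device heterogeneity** is summarized (`device_summary()`) but never
  blocks harmonization — mixed-device columns are a fact of compiled ocean
  data; the user decides what is comparable.
* **Climate zones.** No latitude thresholds are canonical for the
  tropical/temperate/polar zone terms, so the package adopts the
  astronomical tropic and polar circles, 23.5° and 66.5°, with boundary
  latitudes going poleward. Both cutoffs are arguments of `climate_zone()`.
  The three bins partition [−90, 90] exactly.

## The statistical layer

*Stoichiometric regression.* Marine phytoplankton take up nitrate and
phosphate in an approximately 16:1 molar ratio, so with phosphate as the
response and nitrate as the predictor the expected OLS slope is
1/16 = 0.0625. The fit is ordinary least squares via `lm`; R² is computed
from sums of squares. Phosphate is fixed as the response — the slope, not
its reciprocal, is the quantity compared against 1/16.

*Rank correlation* is Pearson correlation of average ranks (`cor`,
`method = "spearman"`); constant vectors are a hard error rather than NaN.

*Ordination.* Relative abundance drops user-specified contaminant taxa
first, then samples under 100,000 reads (the shallow-sample cutoff of the
WGS profiling convention this layer consumes), then row-normalizes.
Bray–Curtis dissimilarity comes from `vegan::vegdist`. The dbRDA itself is
implemented in this package: the distance matrix is squared and
Gower-centered (`G = -1/2 J D^2 J`), the model R² for one covariate is
`(x'Gx / x'x) / tr(G)`, and significance comes from permuting the covariate
`n_perm` times under an explicit seed with the `(b+1)/(n_perm+1)` estimator,
so p is never exactly zero and every result is replayable. Implementing the
partition directly (rather than delegating) keeps the seed contract explicit
and exposes the per-taxon coefficient matrix — the least-squares slope of
each centered taxon abundance on the centered covariate — which is what a
depth-structure plot ranks; `vegan::adonis2` serves as an independent
cross-check in the test suite, where the two agree on the model R² to
within 1e-9. With Euclidean distances on univariate data the dbRDA R² equals
the classical linear-model R², which the tests verify to 1e-9 on small
instances. Ties in `top_coefficients()` break lexically by taxon name so
reported rankings are deterministic.

## Synthetic generators: what they emulate, and what they do not

The generators exist so that every pipeline stage has an offline oracle.
Each returns a manifest that fully determines the generated bytes given the
seed, and records its own ground truth (expected validation issues, true
slope, effect signs, shallow samples).

* `generate_package()` writes a two-resource package (context + nutrients)
  with complete annotation triads and correct checksums, so a clean package
  validates with zero issues by construction. Seven injection kinds plant
  single known defects; checksums are computed *before* post-checksum
  corruptions (so `CHECKSUM_MISMATCH` fires) and *after* content-level
  injections (so only the intended cell issue fires). File corruption flips
  one digit byte, changing the checksum while keeping the table parseable —
  exactly one issue per injection, which is what makes manifest/report
  multiset equality a meaningful oracle.
* `generate_redfield_data()` draws nitrate from a gamma distribution
  (shape 2, mean 16 µM, resampled above 40 µM to stay in the observed
  open-ocean regime; the family is a documented constant, not load-bearing)
  and sets phosphate = nitrate/16 + Gaussian noise (default SD 0.2 µM),
  floored at zero. Optional freshwater-lake outliers (37–40 µM nitrate,
  ≈0 µM phosphate, tagged with freshwater ENVO context) emulate
  anthropogenically influenced samples that deviate from the marine ratio
  and are removable by context filtering. The zero-floor induces a small
  attenuation of the recovered slope (about −0.0004 in a 100-seed
  simulation at n = 1000) — an order of magnitude inside the ±0.003 band the
  recovery tests use, but worth knowing: the generator is not exactly
  unbiased, because truncation is part of its contract.
* `generate_community_depth_data()` gives each taxon a log-linear relative
  abundance trend in depth (scaled to [−1, 1] over 25–125 m), renormalizes,
  and draws multinomial counts at per-sample totals, with a configurable
  number of samples forced under 100k reads. The default taxa mirror the
  North Pacific Subtropical Gyre qualitatively: low-light-adapted
  *Prochlorococcus* and ammonia-oxidizing archaea increasing with depth,
  high-light-adapted strains decreasing.

What the generators do **not** emulate: the empirical covariance structure
of real time-series data (depth-temperature-nutrient coupling, seasonal
cycles), spatial autocorrelation, overdispersion beyond multinomial
sampling, compositional zero-inflation, or realistic taxon richness. Passing
tests therefore demonstrate that the machinery is correct under its stated
model, not that real deposited packages are clean, nor that real communities
follow log-linear depth trends.

## Problem sizes and numerical choices

The test suite and acceptance script run at deliberately desk-scale sizes:
50 packages x 8 samples for the validator oracle, n = 1000 for slope
recovery (with 100-seed and n = 10,000 excursions for sampling-distribution
properties), 16–24 samples x 6 taxa with 199–999 permutations for the
ordination, and 200 replicates for the permutation-test size check, whose
empirical rejection rate is compared against the central 95% binomial
interval at the nominal 0.05 level. Unit round-trips are required to 1e-9
relative tolerance; the dbRDA/linear-model equivalence to 1e-9 absolute.
Degenerate inputs are hard, classed errors rather than silent NA: constant
predictors and covariates, all-zero row pairs in Bray–Curtis, empty
post-filter matrices, cyclic term hierarchies, cross-dimension unit
requests, contradictory injection sets.

## Known limitations

* Only is-a edges are modeled; discovery that needs part-of (e.g. water
  column structure) is out of scope.
* The unit registry bundles only the units the examples need; users supply
  their own TSV for richer systems. There is no dimensional-analysis engine
  — conversions exist only where registered.
* dbRDA supports a single covariate, matching its use here (depth); no
  strata, no multi-term designs, no UniFrac or other phylogenetic distances.
* The portal semantics of the `pm:searchable` flag (whether it gates
  discovery, display, or both in a hosting system) are not replicated; the
  flag is stored and exposed.
* Remote resources, non-tabular resources, and OWL parsing are out of scope
  by design.
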