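---
title: "Methods: soil-survey to medical-record exposure linkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soil-survey to medical-record exposure linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE, include = FALSE}
library(geolink)
```

## Overview

`geolink` turns a table of soil survey points — site coordinates on a
projected national grid and per-element concentrations in mg/kg — into
per-postcode residential exposure estimates, links those estimates to
patient records by postcode without revealing any location, and validates
the representativeness of the linked cohort against census population
distributions. This vignette documents the model, the parameters that
matter, the numerical conventions, and what the synthetic-data generator
does and does not emulate.

## Interpolation model

The exposure surface for each element is built by radius-limited inverse
distance weighting (IDW). At a query point $q$, let $S_R$ be the survey
sites within the search radius $R$ of $q$. The estimate is

$$\hat z(q) = \frac{\sum_{i \in S_R} d_i^{-p}\, z_i}{\sum_{i \in S_R} d_i^{-p}},$$

with three deliberate conventions:

* **Empty neighbourhood → missing.** If $S_R$ is empty the result is a
  missing value, not zero. Missingness propagates to the exposure table
  and ultimately to the `no_coverage` match category, so interpolation
  never fabricates values outside survey coverage.
* **Coincidence rule.** Sites within `coincidenceEpsilon` (1 m default)
  of the query are averaged arithmetically. This resolves the $d = 0$
  singularity without weight capping and makes the interpolator exact at
  site locations, which the test suite asserts.
* **Fixed radius, not fixed count.** The neighbourhood is every site
  within $R$; a $k$-nearest-neighbour rule would make the missing-value
  behaviour incoherent (the nearest site could be arbitrarily far away).

Tunable parameters (`idwConfig()`): search radius `radius` (metres,
default 5000 — matched to the survey's own sampling interval, see the
distance QC below), exponent `power` (default 2, the conventional GIS
choice; the method the pipeline reproduces is tool-default IDW and 2 is
the universal default), raster `cellSize` (metres, default 1000), and
`coincidenceEpsilon` (metres, default 1).

Raster cells are half-open squares anchored at the lower-left corner:
cell $(i, j)$ covers $[x_0 + (j{-}1)c,\, x_0 + jc) \times
[y_0 + (i{-}1)c,\, y_0 + ic)$. A centroid exactly on a shared vertical
edge therefore belongs to the cell to its east, and on a horizontal edge
to the north — every point gets exactly one cell, deterministically. Cell
values are computed at the cell centre; the source method does not state
its convention and the centre is the only symmetric choice. The kernel is
implemented in C++ behind a uniform grid-bucket index with bucket side
equal to the search radius, so the 3×3 bucket neighbourhood provably
contains every site within range and the result is *identical* to naive
all-pairs evaluation (asserted to 1e-10 in the tests); nearest-site
distances use an expanding-ring search over the same kind of index and
are exact, not approximate.

As quality control for centroid-point assignment, `nearestSiteDistances()`
reports the 50% and 97% quantiles of the centroid-to-nearest-site
distance. The method is defensible when these are comparable to the
survey's sampling interval; on the national data the published values are
1.3 km and 5 km, which motivated the 5 km default search radius.

## Detection limits

Below-detection measurements are carried as flags, with the detection
limit stored in the element panel, never as imputed numbers. The
element-exclusion rule (`lodExclusion()`) drops an element when the
below-detection fraction reaches the threshold (default 0.75 — the
cadmium situation in the national survey). For *retained* elements the
few flagged samples enter interpolation at half the detection limit, the
standard substitution for left-censored geochemical data; since retention
requires < 75 % censoring and the defaults give far less, the choice has
negligible influence, but it is explicit and configurable through the
panel's limits.

## Linkage and accounting

The within-practice match is modelled as a pure function from postcode to
element values. Emitted records contain the patient identifier and the
values — no postcode, no location; the test suite greps every serialized
output for every input postcode string to enforce this. Each patient
receives exactly one of six mutually exclusive outcomes
(`practice_not_participating`, `no_postcode`, `postcode_unmatched`,
`no_coverage`, `partial`, `complete`), which partition the cohort — an
invariant asserted on every linkage run. "Partial" means at least one
element present; "complete" means all.

Report percentages follow the published tables' conventions: practice
participation as integer percentages of active practices; patient
coverage to one decimal, with patients-at-linkage-practices as a share of
patients at active practices and partial/complete as shares of
patients-at-linkage. Patients at inactive (left/merged/closed) practices
are excluded from all denominators. Rounding is half-up in both cases;
the published values are consistent with that rule, and the test suite
reproduces every printed regional percentage exactly from the printed
counts.

## Census apportionment and weighted summaries

Each census output area's population is split equally among its
postcodes; a postcode listed as crossing an area border is first assigned
to exactly one candidate area, uniformly at random under a dedicated,
logged seed — validation runs are reproducible and the randomization is
auditable. The equal split is computed as successive differences of the
cumulative shares `pop * (0:n) / n`, which makes the per-area and global
totals conserve *exactly* in floating point (successive shares are within
a factor of two, so the telescoping differences and their ordered sum are
exact by Sterbenz's lemma); the tests assert equality with `==`, not a
tolerance.

Expected distributions weight each postcode by its apportioned
population; observed distributions give each patient unit weight (the
comparison is of patient counts against population counts, not of
weighted patients) and are restricted to patients alive and actively
registered on the census date (`activeOn()`: registration start on or
before the date, end absent or on/after it, death absent or strictly
after it). Missing exposure values are excluded element-wise, mirroring
the element-wise partial-coverage semantics of the accounting tables.

**Weighted quantile convention.** Weights are first aggregated over tied
values; each distinct value then receives the Hazen midpoint plotting
position $(C_i - w_i/2)/W$ on the weighted empirical CDF and quantiles
are read off by linear interpolation, clamped to the data range in the
tails. Merging ties first is what makes the definition exactly invariant
under weight rescaling *and* exactly equal to the plain summary of the
expanded value list when weights are integer frequencies — two properties
that are incompatible for unmerged plotting-position schemes. On tie-free
equal-weight data the convention coincides with `quantile(type = 5)`.
Whiskers are Tukey adjacent values: the most extreme observations with
positive weight inside `fence × IQR` of the quartiles (`fence = 1.5`, the
universal default, exposed as an argument), clamped to the quartiles so
the five summary numbers are always ordered even in degenerate strata.

**Restriction flag.** A region × element stratum is flagged when the
observed whisker span is below `restrictionFraction` (default 0.5) of
the expected span — the signature of a cohort that samples only part of
a region's exposure range, as happens when few practices in a region
participate. Strata present on only one side are marked incomparable
rather than silently dropped.

## The synthetic-data generator

The generator exists so that the full pipeline can run, and be tested
against a known truth, with no access to the licensed survey or medical
databases. Its defaults describe the demonstration study: a 20 × 20 km
domain with four urban centres (radius 4.8 km), survey densities of
4 per km² (urban), 1 per 2 km² (rural) and 1 per 25 km² (background)
yielding roughly 1,200 sites, ~2,000 postcodes with address counts
`1 + NB(size = 2, mu = 14)` capped at 100 (mean 15, range 1–100),
output areas of ~8 postcodes built by k-means on centroids, a 2 × 2
grid of reporting regions, 2 % border-crossing postcodes, 40 practices
(12 % inactive, 95 % participation among active), 5,000 patients, 2 %
blank and 3 % unknown postcodes, and ~45 % of patients not active on the
census date (2011-03-27). The household-size factor linking address
counts to populations defaults to 2.4 persons per address.

Element truth fields are sums of seeded Gaussian bumps on the log scale —
bump width half the correlation length (default 5 km), standardized over
a fixed probe grid to the configured log-mean and log-sd (default 0.4) —
exponentiated, and multiplied by an urban enrichment factor inside urban
discs (largest for lead, copper and zinc). This gives strictly positive,
positively skewed, spatially correlated fields at a fraction of the cost
of full geostatistical simulation. Survey sampling is a homogeneous
Poisson process per stratum, realized by thinning a process on the full
rectangle, with multiplicative lognormal measurement noise (log-sd 0.1).
Postcodes cluster into compact output areas, and border-crossers are
chosen so that every area keeps at least one non-crossing postcode —
random reassignment can then never strand a populated area, for any seed.

Every stochastic stage draws from a seed derived from the master seed and
a stage label (`derivedSeed(seed, "survey")`, `"postcodes"`,
`"population"`, `"apportion"`, `"truth:<element>"`), so a study is
reproducible bit for bit and stages can be re-run in isolation.

What the generator does **not** emulate: real national geography or
postcode grammar, the grid-stratified (rather than Poisson) layout of the
actual surveys, calibration to actual concentration ranges, multi-element
correlation (fields are independent across elements), and fine-grained
urban heterogeneity. Passing tests therefore demonstrate the pipeline's
correctness and its statistical behaviour under a controlled truth — not
that any particular real region is well covered.

## Validation experiments

Two study-level experiments are built in:

* `linkageStudy()` runs the whole chain in memory. With all failure
  rates zeroed (no blank or unknown postcodes, full participation, no
  inactive practices) every patient must come out `complete` — the
  coverage report's Total row reads 100.0 % — and with the default
  injected failure rates the recovered `no_postcode` and
  `postcode_unmatched` shares must sit within binomial noise of the
  injected 2 % and 2.94 % (3 % of the non-blank remainder).
* `representativenessRun()` compares expected and observed distributions
  on a four-region, four-element population (10 × 10 km domain, 3 km
  correlation length, 300 postcodes, cohorts of 400 per region). With
  the cohort drawn in proportion to apportioned population, observed
  distributions should track expected ones and restriction flags should
  stay at the nominal rate; with one region's cohort drawn only from its
  lowest-exposure compact cluster (the output area with the smallest
  maximum first-element value, at least three postcodes), the flag must
  fire in that region and nowhere else. The cluster-based restriction
  emulates the real failure mode — a region covered by very few
  practices — and, through spatial correlation, restricts several
  elements at once rather than just the one used to pick the cluster.

Problem sizes throughout the tests (200 × 500 point IDW oracle grids,
100 apportionment configurations, 1,000 expansion-oracle cases, 20
replicates per representativeness condition) were chosen as the smallest
sizes at which the checks are statistically meaningful.

## Known limitations

* The urban enrichment step changes the field discontinuously at the
  disc boundary, so interpolated estimates just outside an urban centre
  are biased by enriched urban samples inside the search radius. Closed-
  loop recovery is therefore assessed at rural density on rural-only
  configurations (median absolute relative error under 15 %) and at
  urban density on centroids inside urban centres (under 8 %).
* Exposure is assigned at the postcode centroid; within-postcode
  variation and non-residential exposure are out of scope, as are
  kriging and machine-learning interpolation alternatives.
* Postcode matching is exact-string on non-blank codes; the real
  postcode grammar, fuzzy matching, and the split of unmatched patients
  between invalid and newly created postcodes (indistinguishable in the
  source accounting) are not modelled.
* The comparison of expected and observed distributions is descriptive
  (boxplot summaries and span ratios), not a formal two-sample test.
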