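---
title: "Methods: heat vulnerability indexing and planting prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heat vulnerability indexing and planting prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbancanopy)
```

# The problem

Urban heat kills, and it kills unevenly. Tree canopy is one of the cheapest
levers a city has against the urban heat island, but canopy (and plantable
land) is itself unevenly distributed. `urbancanopy` implements the
computational core of a planting decision-support workflow for census
tracts: score every tract's *heat vulnerability* (who is most susceptible to
heat-related morbidity and mortality), measure its *heat exposure* (summer
land surface temperature, LST) and its *planting feasibility* (how much
grass/shrub land could hold trees today), flag priority tracts, and then
filter an approved species list against hyper-local site constraints.

# The Heat Vulnerability Index

## Indicators

The default schema (`default_schema()`) carries 13 tract-level indicators:
nine sociodemographic percentages (Hispanic, Black, foreign-born, limited
English, below poverty, over 65, over 65 living alone, disability at ages
18–64, unemployment at ages 18–64), the percentage of housing built before
1980, housing-unit density per square mile, and the percentages of
high-intensity developed and open undeveloped land. Each indicator is tagged
with a direction; open undeveloped land is the one protective
(vulnerability-decreasing) indicator, and the tag is what anchors component
signs (below).

## Model

Let \(X\) be the tracts-by-indicators matrix. The pipeline is:

1. **Standardize** each indicator to mean 0, SD 1 across the cohort
   (sample SD, \(n-1\) denominator). PCA is therefore performed on the
   correlation matrix — the only defensible choice when indicators mix
   percentages with units per square mile.
2. **Extract and retain components.** Eigendecompose the correlation
   matrix; retain components with eigenvalue > 1 (Kaiser criterion).
   "Interpretability" criteria are not algorithmic, so a fixed-`k` override
   (`retention = "fixed"`) is provided for analysts who inspect loadings.
3. **Rotate.** Varimax (orthogonal) rotation with Kaiser row
   normalization — the default in the SAS lineage of these indices.
   Rotation redistributes variance among retained components but preserves
   total retained communality (tested to 1e-6).
4. **Orient.** A rotated component's sign is arbitrary. Each component is
   oriented so that its summed loading over vulnerability-increasing
   indicators is non-negative; a high component score then always reads as
   high vulnerability.
5. **Score.** A tract's raw score on component \(c\) is
   \(\sum_v \lambda_{vc}\, z_{tv}\, s_c\): standardized values weighted by
   the full rotated loading vector (no salience cutoff by default; a
   configurable `loading_threshold` zeroes small loadings for users who
   want sparse weights).
6. **Standardize scores** per component to mean 0, SD 1 across the cohort.
7. **Band** each standardized score into categories 1–6 by whole standard
   deviations: \(z < -2 \to 1\), then one category per SD, \(z \ge 2 \to 6\).
   Interior edges are lower-closed (ties go to the *more* vulnerable band),
   giving a total, monotone, deterministic rule.
8. **Sum** the component categories into the overall HVI, range
   \([k, 6k]\) for \(k\) components.

The whole chain is deterministic; there is no randomness anywhere in the
engine.

## Weight-then-standardize: two readings

"Multiply each variable by its weight, then standardize" admits two
algebraically distinct readings: standardize the *component sum* (so factor
scores are well-defined weighted sums), or standardize each *weighted
variable* before summation — which collapses every weight to its sign,
since a standardized variable rescaled by a constant and re-standardized is
just \(\pm z\). The default is sum-then-standardize; the other reading is
kept behind `score_standardization = "per_variable"` so the choice is
explicit rather than silent.

## Numerical conventions

* Sample SD (\(n-1\)) everywhere, matching the SAS defaults this family of
  indices grew up with.
* Quantiles use the linear-interpolation convention (`stats::quantile`
  type 7) wherever a cohort cutoff is needed.
* Degenerate inputs fail loudly: constant indicators, zero-variance
  components, cohorts under 3 tracts, and all-identical cutoff inputs are
  errors with named variables, never silent NA propagation.
* Missing indicator values are rejected by default; median imputation is
  opt-in and reports every filled cell. An index that feeds policy should
  not impute silently.

# Feasibility, exposure, and the priority rule

Block-group land cover (five mutually exclusive classes, square feet) is
summed to tracts. *Potential canopy* is the vegetation (grass/shrub) class —
land plantable without demolition or depaving; impervious surface is never
potential canopy. Existing and potential canopy are reported as square feet
and as percentages of tract area (tract area being the sum of the class
areas, so percentages partition to 100 exactly).

Feasibility is binary. The default rule is cohort-relative — "high" means
potential-canopy percentage at or above the cohort median — because a
relative rule is scale-free across cities; an absolute percentage cutoff is
available in the config. Ties classify high, biasing toward the planting
recommendation, which is the tool's purpose.

The priority rule is pure boolean algebra:

\[priority = feasibility_{high} \wedge (HVI_{high} \vee LST_{high})\]

with "high" defaulting to the top quartile (q = 0.75) of the cohort for
both HVI and LST. Vulnerability and exposure are deliberately *never*
merged into one index: in a city where parks sit in lower-income
neighbourhoods the two can anti-correlate, and a combined score would
obscure exactly the trade-off a decision-maker needs to see. Low-feasibility
tracts get `alternative_interventions` (cool roofs, depaving, green
roofs/walls) rather than `plant_trees`.

# The species selector

The selector is conjunctive filtering over an attribute table of approved
species: canopy spread vs available space, light on a *tolerance* ordering
(`full_sun` < `partial` < `shade_tolerant`, so a shade-tolerant tree
satisfies any site), requested site type among the species' suitable sites,
allergenicity at or below a cap (high-pollen plantings can aggravate asthma,
undoing part of the equity benefit), optional breakage resistance (a
maintenance proxy) and minimum growth rate.

The heat-reduction flag multiplies the two drivers of canopy cooling —
relative transpiration rate and relative leaf area — and flags species at or
above the 75th percentile of that product (configurable). The packaged table
(`species_fixture_path()`) has 34 rows with real scientific names but
synthetic attribute values; results on it demonstrate mechanics, not real
horticultural rankings.

# The synthetic-data generators

Real inputs for this pipeline are census extracts, classified land cover,
and remote-sensing temperature products. The generators emulate their
statistical structure so every stage is testable offline:

* **Tract indicators** come from a three-latent-factor model — a
  sociodemographic factor over the seven race/ethnicity, language, poverty,
  disability and unemployment indicators; an urbanicity factor over housing
  age/density and development (loading negatively on open undeveloped
  land); and an age-and-isolation factor over the two over-65 indicators —
  with loadings 0.85 (−0.80 for the protective indicator), unique Gaussian
  noise of SD 0.1 and a default cohort of 500 tracts. Factor draws are
  centred and whitened so their sample covariance is exactly the identity:
  the generator *plants* the structure \( \Lambda\Lambda' + \sigma^2 I \)
  rather than that structure plus factor-sampling noise, which is what a
  recovery test should recover (measured Frobenius distance between the
  realized and implied correlation is about 0.03 at these defaults).
  Latent values are squashed into valid ranges by documented monotone maps:
  percentages via a shifted logistic `100 * plogis(y + shift)` (shifts place
  marginals at plausible levels), density via `3000 * exp(0.8 y)`. The
  squash distorts correlations mildly; recovery tolerances account for it.
* **Land cover**: per block group, a lognormal total area split across the
  five classes by a Dirichlet draw, so class areas sum to the total exactly.
* **LST**: `baseline − slope × canopy_pct + noise` with baseline 35 °C and
  slope 0.1 °C per canopy point — a linear caricature of canopy cooling,
  enough to give the priority rule a realistic anti-correlated exposure
  layer.
* **Geometries**: square WGS84 grid cells, purely for exercising the
  GeoJSON layer.

One master seed drives all generators through derived sub-seeds, so the
full input bundle is reproducible byte for byte.

What the generators do *not* emulate: spatial autocorrelation, real
marginal distributions of any particular city, non-Gaussian heavy tails,
survey measurement error, or correlation between land cover and
demographics. Passing tests therefore certify the algebra and the
statistical recovery behaviour of the pipeline — not that any real city's
index would look like the synthetic one.

# Problem sizes and test design

The test suite works at the scale the statistics require and no more:
cohorts of 500 tracts for factor-recovery checks (100 seeds), 100–300
tracts for pipeline properties, tiny hand-built tables wherever an exact
oracle exists (explicit dot-product loops, brute-force predicate scans,
sort-and-count quantile checks, truth tables over all 8 flag combinations).
Determinism is asserted as byte-identity of written outputs; the run
manifest deliberately carries no timestamp so identical configurations
produce identical files.

# Known limitations

* Component "interpretability" cannot be automated; the Kaiser criterion
  plus a fixed-`k` override is the whole retention story.
* The index is a point score — no uncertainty intervals.
* No oblique rotations; no spatial modelling; no sub-tract planting-site
  detection.
* The feasibility cutoff and the q = 0.75 "high" thresholds are
  conventions, not estimates; both are exposed in the config and should be
  stress-tested against local judgement before driving real decisions.

# A worked run

```{r example, eval = FALSE}
dir <- tempfile("bundle")
simulate_inputs(seed = 42, n_tracts = 200, dir = dir)
res <- run_all(file.path(dir, "config.yaml"))
glance(res$hvi)
head(tidy(res$hvi))
sum(res$priority$priority)
autoplot(res$hvi$model)
```
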