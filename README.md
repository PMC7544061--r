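# urbancanopy

Heat poses an urgent, unevenly distributed threat in cities, and tree
canopy is one of the cheapest mitigations a city controls — but planting
campaigns fail when trees go to the wrong places or the wrong species go
into the ground. `urbancanopy` implements the computational core of a
tract-level tree-planting decision workflow for city analysts and
urban-forestry programs:

* a **Heat Vulnerability Index (HVI)** built from 13 sociodemographic and
  land-cover indicators by varimax-rotated principal-components weighting,
  standard-deviation banding (scores 1–6 per component) and summation;
* **planting feasibility** from block-group land cover aggregated to
  tracts — potential canopy is the grass/shrub class, never impervious
  surface;
* a **priority rule** `priority = high_feasibility & (high_hvi | high_lst)`
  that keeps vulnerability and heat exposure (summer land surface
  temperature, LST) as two separate signals rather than one blended index;
* a **species selector** that filters an approved-species table by site
  constraints (space, light tolerance, site type, allergenicity, breakage
  resistance) and flags species with high heat-reduction potential
  (transpiration rate × leaf area, top quartile);
* **seed-deterministic synthetic generators** for every input — a
  three-latent-factor indicator cohort, Dirichlet land cover, linear
  canopy-cooled LST, square tract geometries and a packaged 34-row species
  fixture — so the full pipeline runs offline.

## The model in brief

With standardized indicators \(z_{tv}\), rotated loadings \(\lambda_{vc}\)
(Kaiser-retained, varimax, oriented so vulnerability-increasing indicators
load non-negatively in sum):

```
raw score:  s_tc = Σ_v λ_vc z_tv σ_c          (σ_c the orientation sign)
z-score:    standardized per component (mean 0, SD 1 across the cohort)
band:       z < −2 → 1, one category per SD, z ≥ 2 → 6 (lower-closed edges)
index:      HVI_t = Σ_c band_tc   ∈ [k, 6k] for k components
```

## Worked example

```r
library(urbancanopy)

dir <- tempfile("bundle")
simulate_inputs(seed = 42, n_tracts = 200, dir = dir)   # writes the 5 inputs + config.yaml
res <- run_all(file.path(dir, "config.yaml"))

res$hvi
#> Rotated-PCA weighting model: 13 variables, 3 retained component(s)
#> Eigenvalues (retained): 6.871, 3.668, 1.985
#> Orientation signs: -1, 1, 1
#> Scored tracts: 200 ; HVI range 7 - 17

head(tidy(res$hvi)[, c("tract_id", "z_comp1", "cat_comp1", "hvi")], 4)
#> # A tibble: 4 × 4
#>   tract_id    z_comp1 cat_comp1   hvi
#>   <chr>         <dbl>     <int> <int>
#> 1 25025000001  -0.312         3     8
#> 2 25025000002   0.685         4     9
#> 3 25025000003  -0.609         3    11
#> 4 25025000004  -0.543         3     9

sum(res$priority$priority)            # 42 of 200 tracts are planting priorities
sum(res$species$high_heat_reduction)  # 9 of 34 species flagged for cooling potential
```

Three components come back because the synthetic cohort plants three latent
dimensions (sociodemographic, urbanicity, age-and-isolation); each tract's
standardized component scores are banded 1–6 and summed, so with three
components the index lives in 3–18. A tract is flagged `priority` when it
is in the top half of tracts by plantable (grass/shrub) area **and** in the
top quartile by either HVI or LST.

Outputs land in `<dir>/out/`: `hvi.csv`, `weighting_model.csv`,
`canopy.csv`, `priority.csv`, `species_selection.csv`,
`tracts_scored.geojson` (an RFC 7946 FeatureCollection carrying every score
as feature properties) and a timestamp-free `manifest.yaml`, so reruns of
the same config are byte-identical.

A command-line wrapper ships at `inst/cli/urbancanopy`:

```sh
Rscript inst/cli/urbancanopy simulate --seed 42 -o demo/
Rscript inst/cli/urbancanopy run-all -c demo/config.yaml
Rscript inst/cli/urbancanopy select-species --site street --max-allergenicity medium --breakage-resistant
```

See `vignettes/urbancanopy-methods.Rmd` for the full account of the model,
its conventions (sample SD, type-7 quantiles, lower-closed bins, tie rules)
and what the synthetic generators do and do not emulate.

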