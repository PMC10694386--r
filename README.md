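# habiq

Habitat-quality assessment, land-use change metrics, and geographical-detector
driver attribution for categorical land-use rasters — the analysis chain used
in wetland and watershed ecosystem studies (the packaged parameterization
comes from a Poyang Lake watershed assessment), reimplemented as a tested,
scriptable R package.

## Who it is for

Landscape ecologists and ecosystem-services analysts who have two-epoch
land-cover maps and zonal covariate tables and want, without a GIS GUI:

* per-cell **habitat degradation** `D` and **habitat quality** `Q` from a
  threat distance-decay model,
* **land-use change** summaries: transfer matrices, transition shares,
  single and integrated dynamic degrees,
* **driver attribution**: the geographical-detector `q` statistic with
  significance, interaction detection, and the ecological F test,
* a **synthetic-landscape generator** with known ground truth, so every
  stage of the chain can be validated before touching real data.

## The model

Degradation of cell *x* (class *j*) accumulates the weighted,
distance-decayed impact of all threat-source cells *y* of all threats *r*:

    D_x = Σ_r Σ_y (w_r / Σ w) · r_y · i_r(d_xy) · β_x · S_jr

with linear decay `i = 1 − d/d_max` or exponential decay
`i = exp(−2.99 d/d_max)`, both zero beyond `d_max`. Quality follows a
half-saturation transform bounded by the class suitability `H_j`:

    Q_x = H_j · (1 − D_x^z / (D_x^z + k^z))        (z = 2.5, k = 0.5 or "auto")

Land-use change between epochs a and b is cross-tabulated into a transfer
matrix `P_ij` (km²), giving per-class dynamic degrees
`K_i = (U_ib − U_ia)/U_ia/T · 100%` and the integrated degree
`LC = Σ outflow_i / (2 Σ area_i) / T · 100%`. Spatial attribution uses
`q = 1 − SSW/SST` per factor, the overlay `q12` for factor pairs, and a
two-sided variance-ratio F test between factors.

## Worked example

```r
library(habiq)

# two synthetic epochs: urbanisation converts cropland near the city
cfg <- sim_config(60, 60, cell_size = 500, codes = c(1L, 3L, 6L, 7L, 10L),
                  proportions = c(.35, .3, .2, .1, .05),
                  autocorr_scale = 2000, seed = 42)
lu_2010 <- generate_landuse(cfg)
growth <- transition_model(matrix(c(
  .85, .02, .01, .10, .02,
  .05, .92, .01, .01, .01,
  .02, .01, .95, .01, .01,
    0,   0,   0,   1,   0,
    0,   0,   0,   0,   1), 5, byrow = TRUE), codes = c(1L, 3L, 6L, 7L, 10L))
lu_2020 <- evolve_landuse(lu_2010, growth, seed = 43)

D <- compute_degradation(lu_2020, poyang_threats(), poyang_sensitivity())
Q <- compute_quality(D, lu_2020, poyang_sensitivity(), k = "auto")
tidy(classify_raster(Q, quality_grades()))
#> # A tibble: 5 × 4
#>   label     cells area_km2 share_pct
#>   <chr>     <int>    <dbl>     <dbl>
#> 1 awful       705    176.      19.6
#> 2 poor       1978    494.      54.9
#> 3 fair        410    102.      11.4
#> 4 good        201     50.2      5.58
#> 5 excellent   306     76.5      8.5
```

19.6% of the 900 km² landscape sits in the worst quality band (Q < 0.1) —
the built-up cells themselves (suitability 0) plus habitat saturated by
nearby threats — while 8.5% (forest and water far from any threat) stays
excellent.

```r
glance(transfer_matrix(lu_2010, lu_2020, years = 10))
#> # A tibble: 1 × 5
#>   n_classes total_km2 changed_km2 years lc_pct
#>       <int>     <dbl>       <dbl> <dbl>  <dbl>
#> 1         5       900        72.5    10  0.403
```

72.5 km² changed class over the decade, an integrated dynamic degree of
0.40 %/yr.

```r
tab <- generate_zonal_table(
  zonal_design(500, n_strata = c(5, 4), between_fraction = c(.5, .15),
               seed = 44))
report <- run_detectors(tab, response = "y", n_perm = 199, seed = 45)
tidy(report)
#> # A tibble: 2 × 5
#>   factor     q p_value     L method
#>   <chr>  <dbl>   <dbl> <int> <chr>
#> 1 x1     0.513   0.005     5 permutation
#> 2 x2     0.141   0.005     4 permutation
report$interaction
#> # A tibble: 1 × 6
#>   factor1 factor2    q1    q2   q12 category
#>   <chr>   <chr>   <dbl> <dbl> <dbl> <chr>
#> 1 x1      x2      0.513 0.141 0.646 bi-enhance
```

The detectors recover the designed explanatory fractions (0.5 and 0.15)
from the 500-unit table, and classify the pair as mutually enhancing
(`q12 = 0.65 > max(q1, q2)` but below `q1 + q2`).

The packaged decadal transfer matrices reproduce the published worked
percentages directly, e.g.

```r
share_of(poyang_transfer("2012-2022"), "Building sites", "Arable land")
#> [1] 8.580022
```

`run_pipeline(pipeline_config(...))` chains all stages (simulate/load →
quality → change → detectors) and writes rasters, CSVs and a checksummed
manifest; `inst/cli/hq.R` exposes the same stages as an `hq` command-line
tool with `simulate | run | landchange | geodetect | all` subcommands.

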