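# forestcond

Forest ecosystem condition accounting on gridded landscapes, in the style
of the UN SEEA EA (System of Environmental-Economic Accounting — Ecosystem
Accounting) standard. The package is aimed at ecosystem accountants and
landscape ecologists who want a tested, reproducible implementation of the
full condition-account chain — from typed rasters and reference-site
polygons to account tables, change statistics, an uncertainty
classification and a parameter sensitivity analysis — exercised end-to-end
on synthetic scenes with known structure.

## The method in brief

Forest types are the cross of four forest land-cover classes with up to
eleven biogeographic regions (44 types at the full cross). Seven condition
variables per cell and accounting year (NDWI, soil organic carbon,
threatened-forest-bird richness, tree cover density, NDVI, forest area
density, landscape naturalness) are rescaled per type to `[0, 1]`
indicators between a lower reference level `V_L` (ambient minimum) and an
upper level `V_H` (maximum in reference sites):

    I = (V − V_L) / (V_H − V_L),   clamped to [0, 1]

Reference sites are primary forests and strictly protected areas (IUCN
Ia/Ib/II) holding at least 7.5 ha of forest (canopy > 20%) that lost at
most 5% of it; regions without sites borrow upper levels from a donor
region. Indicators aggregate to the forest condition index with
rank-derived weights summing to one:

    index = Σᵢ Σⱼ wⱼ xᵢⱼ / n,  w = (ndwi .08, soc .12, birds .22,
                                    trees .21, ndvi .13, fad .13, lm .11)

The two landscape variables are moving-window proportions over a 23 × 23
cell (529 ha) neighbourhood; the bird variable can be modelled from
observation tables with a forward-stepwise quasi-Poisson GLM. The account
reports per-type means, reference levels, change in index points × 100,
Mann-Whitney tests on spatially thinned samples, a four-level uncertainty
classification and a ±10% one-at-a-time sensitivity analysis of all 21
parameters per type. Details and design rationale are in
`vignettes/forest-condition-accounting.Rmd`.

## Worked example

```r
library(forestcond)

res <- run_pipeline(scene_config(grid_shape = c(96, 96), seed = 42),
                    pipeline_params(mwu_min_separation = 3))
res
#> <fc_pipeline_result> 44 forest types
#>   mean condition index, year0: 0.584
#>   mean condition index, year1: 0.605
```

The synthetic scene improves by `change_points(0.584, 0.605)` = +2.1 index
points between the two accounting years. One account row (Boreal
broad-leaved forest, year 0) shows the SEEA layout — variable means on
their native scales, the reference levels that anchor the rescaling, and
the resulting indicator means and index:

```r
dplyr::filter(res$account, type_id == 61, year == "year0")
#>   type_id forest_class region year  area_ha variable mean_value    V_L    V_H
#> 1      61 broadleaved  Boreal year0     116 ndwi          0.352  0.216  0.595
#> 2      61 broadleaved  Boreal year0     116 soc           0.313  0.087  0.482
#> 3      61 broadleaved  Boreal year0     116 birds         5.63   2.22   8.77
#> 4      61 broadleaved  Boreal year0     116 trees        52.2   24.2   94.2
#> ...                            (plus indicator_mean and index columns)
```

Change statistics, the uncertainty distribution, and the weight
redistribution used where soil data are structurally absent:

```r
res$change
#>   share_increasing share_decreasing share_unchanged mean_change_increasing ...
#> 1             77.6             21.4            0.98                   3.25

table(res$uncertainty$level)
#>  1  2  3  4
#>  4 17 16  7

redistribute_missing(default_weights(), "soc")
#>   ndwi  birds  trees   ndvi    fad     lm
#>  0.091  0.250  0.239  0.148  0.148  0.125
```

So 77.6% of the forest area improved (by 3.25 points on average), most
types sit at low-to-medium uncertainty, and dropping the SOC weight lifts
the bird weight from 0.22 to 0.22/0.88 = 0.25. `autoplot(res$index$year1)`
maps the index; `plot_type_index(res$account)` shows the per-type dot
chart; `autoplot(res$sensitivity)` summarises the sensitivity analysis.

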