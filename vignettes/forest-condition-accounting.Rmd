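---
title: "Forest condition accounting: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forest condition accounting: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestcond)
```

## The accounting model

`forestcond` implements a SEEA EA (System of Environmental-Economic
Accounting — Ecosystem Accounting) style condition account for forests on a
gridded landscape. The account follows the standard three-step structure:

1. **Variables.** Seven condition variables are carried per grid cell and
   accounting year: vegetation water content (NDWI, $[-1,1]$), soil organic
   carbon (SOC, $[0,1]$), species richness of threatened forest birds
   ($[0,22]$), tree cover density ($[0,100]$ %), productivity (NDVI,
   $[-1,1]$), forest area density (FAD, $[0,100]$ %) and landscape
   naturalness ($[0,100]$ %). The last three are computed internally (the
   bird layer can be modelled, FAD and naturalness always are); the others
   are inputs.

2. **Indicators.** Each variable $V$ is rescaled per forest type to an
   indicator

   $$I = \frac{V - V_L}{V_H - V_L},$$

   clamped to $[0,1]$: values at or below the lower reference level $V_L$
   score 0 (degraded), values at or above the upper level $V_H$ score 1
   (natural reference condition). $V_L$ is the minimum of the ambient
   distribution of the type; $V_H$ is the maximum observed in the type's
   reference sites. Both are measured on the first accounting year (the
   reference year) and applied to all years.

3. **Index.** The condition index per forest type is the weighted mean

   $$\mathrm{index} = \frac{\sum_{i=1}^{n}\sum_{j=1}^{7} w_j\,
   x_{ij}}{n}, \qquad \sum_j w_j = 1,$$

   over the type's $n$ cells, with indicator weights $w_j$ derived from
   ranking the variables against five conceptual criteria (rank sums
   converted to ratios). The default weight vector is
   `r paste(names(default_weights()), default_weights(), collapse = ", ")`.

Forest types are the cross of the four forest land-cover classes
(broad-leaved, coniferous, mixed, transitional woodland/shrub) with up to
eleven biogeographic regions; the full cross yields 44 types.

## Reference sites and levels

Upper levels come from reference sites: primary-forest polygons plus
protected-area polygons in IUCN categories Ia, Ib or II. Polygons are
screened with three filters:

* **Forest content.** Cells with canopy cover strictly above 20% count as
  forest (20% is the conventional open-habitat/woodland limit; the boundary
  is configurable). Polygons with less than 7.5 ha of forest are discarded;
  7.5 ha is the smallest treed area a 25-ha land-cover mapping unit can hold
  at the 30% canopy delineation threshold (`min_treed_area_ha()`), and a
  polygon at exactly 7.5 ha passes ("below 7.5 ha" is excluded).
* **Disturbance.** The loss summary mask ORs all annual tree-cover-loss
  layers; polygons that lost more than 5% of their forest are excluded
  (exactly 5% passes — low-moderate disturbance).
* **Membership.** Cell-in-polygon uses cell-centre containment, which is
  deterministic and resolution-consistent.

Regions without any accepted reference area borrow upper levels from a
donor region for the same forest class (Arctic from the Scandinavian Alpine
sites; Black Sea and Steppic from the Pannonian sites); borrowed rows are
flagged, and a borrowed $V_H$ falling below the type's own $V_L$ is clipped
to $V_L$ (the indicator is then 0 everywhere) so the rescaling stays well
defined. A type with no sites and no resolvable donor keeps `NA` levels and
surfaces as highest uncertainty. A degenerate pair $V_H = V_L$ rescales to
0 — an uninformative indicator is reported as degraded rather than silently
granted top condition.

## Landscape metrics

FAD and naturalness are moving-window proportions over a square
neighbourhood of 23 × 23 cells — 529 ha at the 1-ha cell size. The window
primitive is a summed-area table, exactly equal to the double-loop count
(property-tested). At map borders the window shrinks to its in-bounds part
by default (`pad-zero` is available); shrinking avoids artificially
depressed densities at the edges. FAD is classified into six connectivity
classes with the GuidosToolbox bin convention: rare $[0,10)$, patchy
$[10,40)$, transitional $[40,60)$, dominant $[60,90)$, interior $[90,100)$,
intact $\{100\}$ — the class edges are not fixed by the account definition,
so they are configurable. Naturalness reclassifies land cover into
agriculture / natural / developed, takes the windowed share of natural
cells, and snaps it to the printed twelve-category list
(100, 95, 85, …, 5, 0) by nearest value with ties resolved upward.

## The bird richness model

Threatened-forest-bird richness is modelled from a gridded observation
table with a quasi-Poisson GLM (log link, variance $\phi\mu$):

* rows with total reported richness below 3 species are dropped as
  low-quality (low sampling effort), as are excluded strata;
* predictors with pairwise $|r| > 0.7$ are pruned greedily, keeping the
  member of each offending pair with the higher absolute correlation to the
  response (this generalises the usual manual choice of dropping raw
  coordinates in favour of the climate variables they proxy);
* forward stepwise selection visits candidates in order of decreasing
  $|r|$ with the response; a term is kept when its Wald test is significant
  at $\alpha = 0.05$ *and* it raises the pseudo-$R^2$
  ($1 - D_{res}/D_{null}$) by more than `improvement_tol` (default 0.005
  absolute — the account method states "significant improvement" without a
  number, so the tolerance is explicit and configurable). After each
  accepted linear term its quadratic companion (centred before squaring,
  for conditioning) is tried under the same gates. Selection stops at the
  first failing candidate; `scan_all = TRUE` keeps scanning instead.

Dispersion is estimated from Pearson residuals. Validation uses a 70/30
hold-out split plus repeated k-fold cross-validation that refits the
*selected* formula per fold — re-running selection inside the CV would
measure a different procedure. Projection onto predictor grids is ordinary
inverse-link prediction; dynamic predictors vary by year while climate
grids are passed unchanged.

## Change, significance, uncertainty, sensitivity

**Change** is reported in absolute index points × 100: a type moving from
0.566 to 0.585 gains +1.9 points (this is the account's "%" convention;
relative change is a flag away). Area statistics report the shares of
forest area with increasing/decreasing condition and the share losing more
than 10 points.

**Significance** per type uses a two-sided Mann-Whitney U test (normal
approximation with tie correction) on cells sampled to avoid spatial
autocorrelation: greedy random thinning with a minimum pairwise distance,
default the 23-cell window size. The two years are compared as two samples
over the same thinned cell set; the account method names the goal, not the
mechanism, so the thinning distance is configurable and the greedy scheme
guarantees the pairwise constraint exactly. Types with fewer eligible cells
than the 1000-cell target use all surviving cells and are flagged.

**Uncertainty** assigns each type a level 1–4 from four criteria: reference
area (>100 km² and/or >2% of the type's forest area; no sites at all scores
4), environmental representativeness (mean absolute z-score of the
reference-site means of elevation, slope, temperature and rainfall against
the type's distribution, population SD; bins 0.3 / 0.7 / 1.2, left-closed),
and the share of the type's area — and of its reference area — whose
observed class matches the potential natural vegetation (bins 75 / 50 / 25,
exact boundaries on the higher-uncertainty side, matching the strict ">75%"
of the best class). The level is the mean of the four scores rounded to the
nearest integer with halves away from zero (ties resolve conservatively
upward). Absolute rather than signed z-scores are averaged — the criterion
reads "standard deviations from the mean", i.e. magnitude; a signed mode
exists.

**Sensitivity** is strictly one-at-a-time over the 21 parameters per type
($V_L$, $V_H$, $w_j$ × 7 indicators): $V_L$ is raised 10% (most lower
levels sit at natural lows or zero, so only the upward direction is
informative), $V_H$ lowered 10%, and each weight raised 10% with the other
weights scaled proportionally so the sum stays 1 — proportional
renormalisation is the unique choice preserving the relative ratios of the
untouched weights. Perturbations are multiplicative, so zero-valued
parameters are fixed points; types with a nominal index of 0 report
absolute instead of percentage deviation and are flagged. When a single
weight is so large that a 10% increase would reach 1, the constraint binds
and the perturbation is a no-op rather than an error.

## The synthetic scene generator

Real continental inputs are deliberately out of scope; `generate_scene()`
emulates their statistical structure so the full pipeline is testable:

* spatial autocorrelation by Gaussian smoothing of white noise
  (edge-renormalised separable kernel), the simplest controllable
  correlation structure;
* land cover thresholded from a smoothed suitability field
  (four forest classes from a quantile split, every class guaranteed
  present whenever forest exists), regions as contiguous column bands;
* reference polygons as rasterised rectangular blobs that are then
  vectorised, guaranteeing polygon/raster consistency; they are placed
  round-robin over the (region × class) pools of the regions that hold
  sites — the fallback regions (Arctic, Black Sea, Steppic) receive none,
  mirroring the structure the fallback rule exists for — with
  high-elevation bias inside each pool, so reference sites carry the
  environmental signature the representativeness criterion looks for;
* a configurable additive uplift raises every condition variable inside
  designated reference polygons (default: roughly half a field SD per
  variable), giving upper levels headroom above the ambient distribution;
* sparse loss patches depress year-1 tree cover where they strike;
* two accounting years separated by an independent smooth drift field with
  a small positive mean (defaults chosen to emulate the mildly improving
  European condition trend), so change analyses have a known sign;
* a bird table whose counts are drawn from a known log-linear truth (three
  active predictors, one centred quadratic, dispersion 2, realised as
  negative binomial with $\mathrm{size} = \mu/(\phi-1)$ so the variance is
  exactly $\phi\mu$), with longitude/latitude planted collinear with the
  climate predictors so the pruning step has real work to do.

What the generator does **not** emulate: sensor noise, cloud masks,
reprojection artefacts, realistic land-cover patch geometry, temporal
autocorrelation beyond one drift field, or non-stationary variances. Tests
passing on these scenes therefore demonstrate the correctness of the
accounting machinery — filters, rescaling, weighting, aggregation, test
calibration, parameter recovery — not the ecological fidelity of any real
map product.

## Numerical and scale choices

* Grid registration: row 1 = north, cells are 1-ha squares unless
  configured; all stages refuse shape-mismatched grids.
* Raster I/O is the plain-text ESRI ASCII grid, polygons travel as GeoJSON,
  tables as CSV, the manifest as YAML; every artifact is re-derivable from
  the manifest's configuration and seeds.
* Determinism: every stochastic step (scene, split, CV folds, thinning) is
  seeded; rerunning a configuration is byte-identical.
* Test problem sizes are deliberately desk-scale: 48 × 48 demo scenes,
  20 × 20 scenes for the 100-seed oracle-equivalence sweep, n = 5000 bird
  tables with 50 recovery replicates, 120 × 120 grids with 200 seeds for
  the Mann-Whitney calibration. These sizes give the statistical assertions
  comfortable margins while keeping the whole suite around a minute.

## Known limitations

* Land cover (hence FAD and naturalness) is held constant across the two
  accounting years; only the five continuous variables drift.
* A type without reference cells inside a region that has sites elsewhere
  is flagged missing rather than borrowing within-region (the fallback rule
  is regional, not type-wise); its index is undefined and its uncertainty
  maximal.
* The Mann-Whitney comparison treats the two years as independent samples
  at the same cells, not as pairs; with strong cell-level pairing a paired
  test would be more powerful.
* Weights from the rank matrix assume the printed five-criterion scheme;
  alternative aggregation families (e.g. geometric means) are out of scope.
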