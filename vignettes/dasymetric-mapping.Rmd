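---
title: "Random-forest dasymetric population mapping: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-forest dasymetric population mapping: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Census population counts are reported for administrative polygons, but many
applications — epidemiology, disaster response, accessibility analysis —
need population on a fine regular grid. Dasymetric mapping redistributes
each unit's count over its cells in proportion to an ancillary *weighting
layer*; only the within-unit ratios of the weights matter, so the method is
exactly mass-conserving by construction.

`dasypop` builds that weighting layer with a bagged regression-tree
ensemble (a random forest). The training table has one row per
administrative unit: the response is the natural log of population density,

$$y_u = \ln(\mathrm{pop}_u / \mathrm{area}_u\;[\mathrm{km}^2]),$$

and the predictors are per-unit aggregates (mean for continuous, mode for
binary) of a stack of 100-m raster covariates. The fitted forest is then
evaluated at *every grid cell* using the cell-level covariate values; the
per-cell mean of the trees' log-density predictions, exponentiated, is the
weighting layer. Unit counts are disaggregated as

$$\hat{p}_i = \mathrm{pop}_u \cdot \frac{w_i}{\sum_{j \in u} w_j}, \qquad i \in u.$$

A simple areal-weighting (SAW) baseline — uniform density within each unit
— is provided for validation. Projection to later years multiplies urban
cells by $e^{r_u \Delta t}$ and rural cells by $e^{r_r \Delta t}$, and a
national adjustment rescales the surface by a single factor to match an
external total.

## Covariate engineering

Land cover is recoded to a small working class set; a binary urban-extent
layer is mosaicked in so built-up cells inside the extent become class 190
(urban) and the rest class 240 (rural built-up); BLT is their union. Every
categorical presence layer spawns three covariates: `cls_<k>` (presence),
`dst_<k>` (planar Euclidean distance to the nearest presence cell, exact
two-pass distance transform), and `prp_<k>` (proportion of presence cells
within a circular 500-m window, membership by centre distance). Continuous
layers (night lights, elevation, slope, temperature, precipitation) are
"nibbled" — NoData cells inside the study area take the value of the
nearest valid cell — before zonal aggregation so no unit mean is
contaminated by missing data.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `cell_size` | 100 | m | production resolution of the published surfaces |
| `n_trees` | 500 | trees | the production configuration |
| `terminal_node_size` | 1 | obs | trees grown to purity, as in production |
| `covariates_per_split` | ⌊p/3⌋ | covariates | the conventional regression default; the source names the parameter but no value |
| focal radius | 500 | m | stated neighbourhood for `prp_` covariates |
| buffer | 10 000 | m | pads the study area so `dst_` covariates escape edge effects |
| urban stratum | class 190 | — | which cells grow at the urban rate; `BLT` available |
| growth law | exponential | — | UN annual rates are conventionally exponential; geometric available |

## Numerical and design choices

* **Cell ownership.** A cell belongs to the polygon containing its centre;
  centres on a shared edge go to the smaller unit id (units claim cells in
  increasing id order). A unit capturing no centre is assigned the cell
  containing its interior representative point, so every count can be
  placed.
* **Nibble ties.** Equidistant donors resolve to the earliest cell in
  row-major scan order — deterministic and orientation-free.
* **Zonal mode ties.** A 50/50 split of a binary covariate reports 0
  (absence): the conservative claim.
* **Log base.** Natural log. The forest is invariant to the base; only the
  reported OOB MSE scale depends on it.
* **Back-transform.** Per-cell predictions are averaged on the log scale
  and then exponentiated (mean-then-exp). No smearing-type bias correction
  is applied; weights are used only through within-unit ratios, so a
  uniform multiplicative bias cancels exactly.
* **Importance.** OOB permutation importance (mean increase in OOB MSE when
  a covariate's out-of-bag values are shuffled), not impurity decrease. The
  elimination loop drops covariates with importance ≤ 0 and refits until
  all survivors are strictly positive.
* **Zero-population units** are excluded from the response (log 0 is
  undefined) but keep their cells and receive a zero share.
  **Zero-weight units** with people fall back to uniform shares with a
  warning rather than failing.
* **Distances** are planar, centre-to-centre, in the projected system; no
  geodesic correction. Inputs are assumed already projected.
* **Buffering** uses an exact Minkowski offset (edge offsets joined by
  vertex arcs) per ring; this is exact for convex rings, which covers the
  rectangular tessellations the package generates. The buffered region is
  kept as a collection of per-unit polygons whose union defines the
  processing extent.
* **Model borrowing** (predicting one country's weights with another's
  model) is never automatic: below 10 usable units the fit warns, and
  borrowing is an explicit `cross_predict()` call that records the donor.
* **Outputs** are floating-point person counts (no integerization), named
  `<ISO>_{ppp|pph}_v<ver>_<YEAR>[_UNadj]`. Raster interchange is the
  plain-text ESRI ASCII grid and vector interchange is GeoJSON, chosen so
  the package has no compiled geospatial I/O dependency.

## The synthetic world

`make_landscape()` generates the stated test world: a rectangular
two-level tessellation (default 120×120 cells at 100 m, 6 coarse units × 4
children), smooth continuous covariates (white noise passed through a
circular moving-average filter, emulating spatial autocorrelation), a
land-cover field cut from terciles of a smooth field, an urban core with a
built-up ring, and a ground-truth density

$$D = \exp\!\big(b_0 + \textstyle\sum_k \beta_k z_k + \varepsilon\big)
\quad[\text{people/km}^2],$$

with standardized stack layers $z_k$, defaults $b_0 = \ln 50$,
$\beta = (0.45\,\text{lights},\ -0.2\,\text{elev},\ 0.15\,\text{tmean},\
-0.5\,\text{dst\_BLT},\ 0.3\,\text{prp\_BLT})$ and smooth noise
$\varepsilon$ with s.d. 0.2 (0.05–0.1 in "low-noise" settings). Unit counts
are the integral of $D$ over unit cells, rounded by largest remainder
within each coarse unit so the hierarchy sums exactly.

The effect sizes were calibrated once so the world spans a realistic ~3
decades of density and satisfies the generator's own recoverability
contract: on a low-noise world with an adequate training sample (48 fine
units), the full pipeline's output correlates with the true per-cell
population at r > 0.9. A first draft with stronger effects (5+ decades)
failed that contract for an instructive reason: a forest trained on unit
*means* cannot extrapolate above the largest training response, so extreme
urban peaks are systematically flattened and a handful of core cells
dominate the linear-scale correlation even when the log-scale correlation
is 0.96. That flattening is a real property of the method, worth knowing
when interpreting the published surfaces.

What a green test on this world does **not** establish: performance under
covariate misregistration, census-geometry slivers, holes or invalid
polygons, non-convex units, geodesic effects, or covariates whose relation
to density is nothing like log-linear. The generator emulates the
statistical structure the model assumes — that is the point — so passing
tests demonstrate correctness of the machinery, not real-world accuracy.

## Validation design

`holdout_compare()` mirrors the publication's check: aggregate fine counts
to the parent level, fit the forest **only** on the coarse units,
disaggregate the coarse counts by forest weights and by SAW, sum both
surfaces over the fine units, and compare with the observed fine counts
via RMSE, MAE, and %RMSE (RMSE as a percentage of the *mean* fine-unit
population). The fine counts never enter fitting, which the tests assert.
On the synthetic worlds the forest beats SAW on both RMSE and MAE in at
least 9 of 10 seeds.

One acceptance clause is intentionally red: demanding that an injected
pure-noise covariate be *always* eliminated by the importance-at-zero loop
contradicts the behaviour of permutation importance under
terminal-node-size-1 trees — deep trees genuinely use the noise column, so
its permutation importance is often strictly positive (confirmed against
an independent reference implementation). Constant covariates, whose
importance is exactly zero, are always eliminated.

## Known limitations

* Convex-ring buffering; holes in polygons are unsupported.
* No reprojection: all inputs must share one projected system.
* OOB error is a unit-level statistic; it is not the cell-level prediction
  error of the final surface.
* The exponential-vs-geometric growth law and the 190-vs-BLT urban stratum
  are configuration choices the source leaves undocumented; both defaults
  are logged on every run.
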