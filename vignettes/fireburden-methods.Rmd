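---
title: "Methods: from deforestation to fire to smoke to health burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from deforestation to fire to smoke to health burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package models

Fire in the Brazilian Amazon is driven jointly by climate (drought, heat)
and by people, who clear forest and burn the felled vegetation. `fireburden`
implements, end to end and on synthetic data with known structure, the
analysis chain that quantifies this coupling:

1. a **synthetic world generator** producing gridded monthly climate, annual
   deforestation with a spatial frontier, land cover, daily fire detections,
   emissions, particulate matter and demographic inputs;
2. a **feature-panel builder** turning those grids into one row per grid
   cell and month;
3. an **ensemble fire-count regressor** (gradient boosted trees plus a
   feed-forward neural network) evaluated under a chronological
   leave-one-year-out protocol;
4. **attribution** of the fitted model's behaviour via permutation
   importance and incremental perturbation sensitivities (elasticities);
5. a **scenario engine** for counterfactual deforestation and climatological
   climate, with pattern-preserving rescaling and fire-count-ratio emission
   scaling;
6. a **health module** computing PM2.5-attributable deaths, YLL, YLD and
   DALYs with the GEMM hazard function and the subtraction method for the
   averted burden between two exposure fields.

Because every input is generated from a known model, each downstream stage
can be tested against ground truth without any satellite downloads.

## The generative fire-rate model

The expected number of fire detections per cell and month is

$$\mu = \beta_0\, s_m\, e^{\gamma_T (T - T_{ref})}\,
  (P/P_{ref})^{-\gamma_P}\, (D/D_{ref})^{\gamma_D}\, (1 + \gamma_L\,L)$$

with $T$ the monthly surface temperature (°C), $P$ the monthly
precipitation (mm), $D$ the deforested area of the current plus two
preceding years (km²), and $L$ the pasture fraction. The defaults encode
the sensitivities the analysis is meant to recover: $\gamma_D = 0.44$ (a
0.44% fire increase per 1% more deforestation), $\gamma_P = 0.8$ (0.8% more
fire per 1% less rainfall), and $\gamma_T = \ln(1.035)/0.1$ (3.5% more fire
per +0.1 K). Counts are drawn negative-binomially around $\mu$ with
dispersion $k$ (default 5, moderate overdispersion; the variance is
$\mu + \mu^2/k$). Below $D_{floor} = 0.01$ km² the deforestation term is
floored so the rate stays defined on undeforested cells; the elasticity is
exact away from the floor.

Two generator choices deserve comment:

* **The seasonal profile $s_m$ defaults to flat.** Calendar month is not a
  model feature (the panel carries only climate, land cover and
  deforestation), so any exogenous seasonal multiplier would be
  unlearnable and would contaminate the recovered climate sensitivities.
  All seasonality therefore enters through the precipitation and
  temperature cycles themselves — dry-season cells burn more because
  $(P/P_{ref})^{-\gamma_P}$ is large, which is also the mechanism the
  regression must learn.
* **The frontier jitters year to year.** The deforestation field combines a
  persistent south-east frontier gradient with lognormal year-specific
  jitter. Without jitter the spatial pattern of deforestation would be
  collinear with the static pasture map and the model could substitute one
  for the other, biasing the deforestation elasticity low.

## Default study conditions

The default world is a 20 × 30 cell grid at 0.25°, masked to an elliptical
biome of roughly 500–550 cells, over 18 years (2003–2020). Drought years
(indices mirroring 2005, 2007, 2010, 2015) lose 30% of dry-season rainfall
and gain +0.5 K. The annual deforestation trajectory is a stylised U-shape
anchored at the published record: ~25,400 km²/yr early, a 4,571 km²/yr
minimum in 2012, rising to 10,851 km²/yr in 2020. Gridded annual totals
match this trajectory exactly by construction. Detections carry confidence
values (20% drawn below the 66% screening threshold) and a handful of
persistent non-vegetation sources emit every month; both are removed by the
ingest filter, which thins counts uniformly and therefore leaves all
elasticities intact.

With two years consumed by the 3-year deforestation window (and the 6- and
12-month climate windows inside them), the usable panel is 16 years ×
12 months × ~530 cells ≈ 100,000 rows. These sizes were chosen as the
smallest panel on which ensemble training is well conditioned and the
sensitivity recovery is stable across seeds.

## Ensemble protocol

Each ensemble averages gradient boosted trees (`xgboost`, squared error on
raw counts, 150 rounds, depth 6, learning rate 0.1) and a feed-forward
neural network (`nnet`, one hidden layer of 16 units, weight decay 1e-4,
inputs standardised, target scaled by its standard deviation). The
single-hidden-layer network is this package's reconstruction of the
original architecture, which is not fully specified; width, decay and
iteration caps are configurable through `modelSpec()`. A random forest
member (`ranger`) is implemented but excluded from the default ensemble,
which mirrors the published finding that trees-plus-network averaging
performed best. Negative ensemble means are clipped to zero since counts
cannot be negative. Loss is on raw counts by default; `logTarget = TRUE`
switches to `log1p` counts.

Hyperparameters are selected by mean validation RMSE over 5 random row-wise
folds; the default grids contain a single point each, so the search
degenerates and the folds serve only to build the fold-wise members whose
mean is the ensemble prediction. Historical skill is evaluated
chronologically: each year is predicted by an ensemble trained with that
year excluded, and skill is summarised on annual biome totals by Pearson's
r (t-distribution p-value), $r^2 = 1 - SS_{res}/SS_{tot}$ (negative when
the prediction is worse than the observed mean) and RMSE.

## Perturbation sensitivities

Sensitivities are estimated exactly as a model-agnostic sweep: one driver
is perturbed in every cell-month (+0.1 to +1 K for temperature; −1% to
−10% for precipitation, scaling the antecedent 6-month window consistently;
+1% to +50% for deforestation), predictions are re-run, annual totals are
formed, and the mean log total-ratio across years is recorded per
increment. The per-unit slope is a through-origin least-squares fit of the
mean log-ratio against the increment coordinate — the additive increment in
K for temperature, $\log(1 + \delta/100)$ for the multiplicative drivers.
With the multiplicative coordinate the fitted slope *is* the elasticity:
substituting the generative oracle for the trained model returns
$\gamma_D$, $-\gamma_P$ and $\gamma_T$ to machine precision, which is the
package's internal consistency check. Reported units are the conventional
ones: % per +0.1 K ($100(e^{0.1\hat\gamma_T} - 1)$), % per percentage-point
precipitation reduction ($-\hat\gamma$), % per percentage-point
deforestation increase ($\hat\gamma$).

`runSensitivityStudy()` repeats world generation, training and the three
sweeps over several seeds and averages the slopes; with the default
conditions the recovered values settle within a few percent of the
generative 0.44 / 3.5 / 0.8.

## Scenarios, emissions and the toy dispersion stand-in

Counterfactual deforestation scenarios rescale the observed annual grids by
a single scalar per year (pattern-preserving: per-cell ratios are constant
to machine precision), either to a policy target or by copying the
minimum-total year's field; the climatological-climate scenario replaces
the climate fields by their per-cell monthly means. All windowed features
are rebuilt *after* the overrides, so the 3-year deforestation window is
consistent with the scenario. The biome-level policy target is derived by
reducing the Legal-Amazon target (3,925 km²/yr) by the 16.34% area
difference; the one-decimal report truncates toward zero, matching the
published figure of 3,283.6 km²/yr.

Scenario emissions scale control emissions by the ratio of predicted fire
counts, applied per cell and month (the finest shared resolution). Where
the control prediction is below 0.01 counts the ratio is undefined and
emissions pass through unchanged with a warning — reductions are never
invented where the model has no signal.

The particulate-matter fields used by the health module come from a
declared toy: annual emissions convolved with a truncated Gaussian kernel
(default sd 1.5 cells) on top of a 5 µg/m³ background, exactly linear in
emissions. It exists solely to give the health chain spatially coherent,
scenario-dependent exposure fields; it does not emulate atmospheric
chemistry, transport or meteorology, and no conclusion about real PM2.5
levels follows from it.

## Health burden

Relative risk follows the GEMM hazard shape
$RR = \exp\{\theta \log(1 + z/\alpha)\,\omega(z)\}$ with
$z = \max(0, \mathrm{PM} - 2.4)$ and logistic weight
$\omega(z) = 1/(1 + e^{-(z - \mu_w)/\nu_w})$: unit risk at and below the
2.4 µg/m³ counterfactual, continuous and increasing above it, saturating at
high exposure. Parameters live in a replaceable CSV; the packaged table is
a synthetic stand-in (a single published-magnitude NCD+LRI parameter set
replicated across adult age brackets) because the original supplement
values are not shipped. Attributable events are
$P \times \mathrm{rate} \times (1 - 1/RR)$ per cell, age group and outcome,
identically for deaths, YLL and YLD (YLD with a morbidity-shrunk RR,
$ratio \cdot RR - ratio + 1$, when cause-specific ratios such as 0.141/0.553
are configured), and DALY = YLL + YLD exactly. The averted burden between
two exposure fields is the cell-wise difference of burdens (the subtraction
method) — antisymmetric, zero at identity, and attributing only the change
due to the intervention rather than the burden of fire smoke in general.
Uncertainty is propagated by evaluating the whole chain at
$\theta \mp 1.96\,SE(\theta)$, giving lower ≤ mean ≤ upper stratum-wise; no
Monte-Carlo over $\theta$ is performed. Regional totals divide by regional
population for per-100,000 rates, with `NA` rather than an error for empty
regions.

## Numerical choices and degenerate inputs

* Cell assignment of detections is half-open, `[west, east) × [south,
  north)`; a point on a west/south edge belongs to that cell.
* The confidence filter keeps the 66% boundary (`>=`), reading "below 66
  removed" literally.
* Antecedent windows exclude the current month ("preceding"), preventing
  same-month rainfall from leaking into its own antecedent sum; an
  `includeCurrent` switch exposes the inclusive reading.
* Rows whose windows are undefined (the first two years) are dropped, not
  padded; the generator's own rate model pads the deforestation window at
  the series start by reusing the earliest year, which only affects years
  the panel later drops.
* Deforestation rescaling with an all-zero observed pattern and a non-zero
  target is an error (the pattern is undefined); a zero target returns the
  zero field.
* `expectedFireRate` rejects non-finite inputs and non-positive
  precipitation; world configurations with fewer than 3 years, non-positive
  dimensions, or a trajectory of the wrong length are rejected at
  construction.

## What passing tests do and do not show

The generator reproduces the *statistical skeleton* the analysis assumes —
seasonal and drought-modulated climate, a persistent deforestation
frontier with a U-shaped trajectory, overdispersed counts whose expectation
has known elasticities, linear emission-to-exposure coupling, and a
regionally structured population. It deliberately omits fire spread,
understorey fire types, satellite overpass artefacts, the Aug–Jul
deforestation reference year, atmospheric chemistry and real demography.
Passing tests therefore demonstrate that the pipeline's machinery is
correct and that the estimation procedure can recover known sensitivities
from data of this structure — not that the published real-data magnitudes
(42–43% fire increase, 32% reduction, 2,300 deaths, 88,140 DALYs) are
reproduced, which would require the satellite record and a
chemistry-transport model and is out of scope by design.

## Worked example

```{r example}
library(fireburden)

cfg <- worldConfig(seed = 1L)
world <- generateWorld(cfg)
dets <- generateFireDetections(world)
kept <- filterFireDetections(dets, 66, persistentSourceCells(world)$cell, cfg)
counts <- gridMonthlyFireCounts(kept, world)
panel <- buildFeatureTable(world, counts)

ens <- trainFoldModels(panel, spec = modelSpec(seed = 1L))
perturbationSensitivity(ens, panel, "deforestation")@slope

# counterfactual: policy-target deforestation from 2013 on
target <- scenarioSpec("target_deforestation",
                       defTotals = derivePolicyTarget())
panelT <- buildScenarioPanel(world, counts, target)
predictScenarios(ens, list(control = panel, target = panelT))
```
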