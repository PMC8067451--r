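---
title: "Canopy growth, incident light and light use efficiency: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy growth, incident light and light use efficiency: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canolux)
library(dplyr)
```

`canolux` quantifies why some leafy greens outgrow others under electric
light, by splitting growth into a morphological factor — how much light
the canopy intercepts — and a physiological one — how efficiently
intercepted light becomes biomass. This vignette documents the models,
the default parameter values and why they were chosen, the numerical
decisions, and what the synthetic-data generator does and does not
emulate.

## The growth and light model

**Canopy expansion.** The projected canopy size (PCS, cm² per plant, the
plan-view silhouette of a nine-plant group divided by nine) is modelled
over days after seeding `t` by the three-parameter logistic

$$\mathrm{PCS}(t) = \frac{a}{1 + e^{-(t - x_0)/b}},$$

with asymptote $a$ (cm²), inflection day $x_0$ (where PCS is exactly
$a/2$) and shape $b$ (days). The logistic captures the three phases of a
baby-leaf crop cycle — slow seedling establishment, near-exponential
expansion, and plateau as leaves saturate the footprint — and in practice
fits twice-weekly imaging with R² ≥ 0.99 at realistic measurement noise.
The symmetry identity $f(x_0+t) + f(x_0-t) = a$ is used as an analytic
invariant in the tests.

**Light budget.** A treatment delivering PPFD $P$ (µmol m⁻² s⁻¹) over a
photoperiod $h$ (hours per day) supplies a daily light integral
$\mathrm{DLI} = P \cdot h \cdot 3600 / 10^6$ (mol m⁻² d⁻¹). Incident
light per plant on day $d$ is $\mathrm{PCS}(d)\cdot 10^{-4}\cdot
\mathrm{DLI}$ (mol plant⁻¹ d⁻¹), and the cycle total is the *discrete
daily sum* over $d = 0,\dots,$ harvest day. The daily sum, not a
continuous integral, is the definition: it matches how periodic imaging
is actually converted to a light budget. Incident light is not absorbed
light — no absorptance or canopy-extinction model is applied.

**Traits.** At harvest, per nine-plant unit: light use efficiency
$\mathrm{LUE} = \mathrm{DW}/\text{total incident light}$ (g mol⁻¹),
specific leaf area $\mathrm{SLA} = \mathrm{LA}/\mathrm{DW}$ (cm² g⁻¹),
and canopy overlap ratio $\mathrm{LA}/\mathrm{PCS}_{\mathrm{harvest}}$
(dimensionless; ≥ 1 whenever leaves overlap within the footprint).
PCS at harvest is taken from the fitted curve at the harvest day, for
consistency with the daily series used in the light integral; an
`pcs_source = "image"` switch substitutes the last raw observation.
Values below 1 are flagged with a warning, not rejected — they indicate
segmentation or leaf-area measurement problems worth inspecting.

**Statistics.** Each response is regressed on PPFD (continuous) and
species (two-level class, lettuce as reference) by OLS. The full model
includes the species × PPFD interaction; when its p-value is ≥ α
(default 0.05) the interaction is removed and main effects are reported.
Per-species slopes are read from the interaction model whenever it is
retained. The original split-plot blocking is simplified to fixed-effects
OLS (block can be added as a fixed covariate via `include_block`); no
random-effects machinery is used, and no multiple-testing correction is
applied. Univariate PPFD-response forms (linear, quadratic, exponential
rise to maximum $y = A(1-e^{-kx})$, and the logistic) are available for
slope and asymptote summaries.

## Default parameters and where they come from

The generator's defaults emulate a published comparison of mizuna
(*Brassica rapa* var. *japonica*) and oakleaf lettuce (*Lactuca sativa*
'Green Salad Bowl') grown at six PPFDs for 16 h d⁻¹ in a three-block
split-plot design, harvested at 27 (mizuna) and 28 (lettuce) days after
seeding. Treatment PPFDs enter calculations as the *measured* tray-center
means (53, 128, 210, 281, 345, 410 µmol m⁻² s⁻¹); the nominal labels
(50–425) are display-only, because the published DLIs (3.1–23.6 mol m⁻²
d⁻¹) derive from the measured means.

| Quantity | Mizuna | Lettuce | Source |
|---|---|---|---|
| PCS asymptote, high PPFD (cm²) | 340–350 | 235–247 | published plateaus (~340, ~240) |
| sigmoid $x_0$, $b$ (d) | 18, 3 | 19, 3.5 | chosen to place the plateau just before harvest |
| CCI slope (per µmol m⁻² s⁻¹) | 0.08 | 0.01 | published |
| ACI slope | 0.015 | 0.004 | published |
| Φ_PSII slope (mol mol⁻¹ per µmol m⁻² s⁻¹) | −0.0003 | −0.0003 | published common slope |
| Φ_PSII intercept at PPFD 0 | 0.77 | 0.72 | assumption; preserves the published +0.05 mizuna offset within (0, 0.85) |
| assimilation slope (µmol m⁻² s⁻¹ per µmol m⁻² s⁻¹) | 0.044 | 0.035 | published |
| LUE peak (g mol⁻¹) | 1.26 | 0.74 | published maxima |
| overlap ratio range | 1.1–2.35 | 1.2–5.2 | published endpoints |

Unpublished values are filled with documented assumptions: the PCS
asymptote at the lowest PPFD is 25% of the species maximum ("much lower"
is all that is reported); the asymptote ladders rise gently and
monotonically within the reported "~" plateaus rather than being exactly
flat, because harvest PCS is reported to increase asymptotically with
PPFD; intermediate overlap and LUE values interpolate smoothly between
the published endpoints. Where a printed slope and approximate endpoint
means disagree (lettuce CCI: slope 0.01 vs endpoints suggesting ~0.02),
the printed regression slope wins and the endpoints are treated as
rounded.

**Noise defaults.** Replicate-level scatter is not published (only
nine-plant group means), so the noise model is a design choice: PCS and
dry weight get multiplicative lognormal noise with mean 1 (`pcs_cv` =
0.05, `dw_cv` = 0.07), physiology gets additive Gaussian noise (CCI 2,
ACI 0.5, Φ_PSII 0.02, assimilation 1.8, each in its own units). The
assimilation SD was set so that the species × PPFD interaction for
assimilation is borderline at α = 0.05 — matching the reported
significance regime, where that interaction was weak (p ≈ 0.08) while
the CCI and ACI interactions were overwhelming and the Φ_PSII interaction
absent. These were fixed once and are fully overridable via
`noise_model()`.

**Imaging cadence.** Twice-weekly imaging (days 4, 7, 11, 14, 18, 21, 25
plus the day before each species' harvest) is the only cadence that
leaves ≥ 5 points for a 3-parameter fit within a 27–28 day cycle;
"biweekly" in the fortnightly sense would not.

## The synthetic image renderer

`render_canopy_image()` stands in for a chlorophyll-fluorescence rig
(dark background, bright vegetation). Each plant is a rosette of ellipse
leaves placed at the golden phyllotaxis angle (137.508°) around a small
central crown, with per-leaf length jitter; nine rosettes are stamped on
a grid of non-touching cells under random dihedral transforms (area
preserved exactly). The geometry is calibrated numerically:

1. leaf count and anchor distance are initialised from the target overlap
   ratio (more, more-central leaves for high overlap);
2. the leaf scale is calibrated so the *union* (foreground) pixel count
   matches the requested projected area — multiplicative iteration
   followed by bisection on the exact pixel count, tolerance 0.4%;
3. the measured drawn/union ratio feeds back into the leaf count (up to 4
   outer iterations, accepted within 7%).

The exact rendered foreground count is returned as ground truth, so the
1% area contract is checked against the *request*, while segmentation
benchmarks compare against the *rendered truth* (exact on noise-free
images). Foreground/background separation is kept ≥ 50 grey levels;
optional Gaussian sensor noise defaults to 0.02, far below the
separation, so thresholding is unambiguous by construction.

Segmentation itself uses Otsu's histogram threshold (strictly-above
masking) with a fixed-threshold override for cross-batch reproducibility,
then removes 8-connected components smaller than 25 px. A blank image
raises a "no bimodality" error rather than silently reporting zero area.
Areas are raw pixel counts × pixel-scale² with no sub-pixel boundary
correction, matching the precision of interactive area measurement tools;
plants are never individually delineated (per-plant PCS is the group
mean).

## Numerical choices

* **Sigmoid fitting.** Levenberg–Marquardt least squares
  (`minpack.lm::nlsLM`) with analytic starts ($a_0 = 1.05\max$, $x_{0,0}$
  the day nearest half-max, $b_0 = \mathrm{range}/6$) and up to five
  *deterministic* jittered restarts — no RNG inside the fitter, so
  fitting never perturbs seeded pipelines. Bounds $a \in (0, 10\max]$,
  $b \in [0.1, 30]$ d, $x_0 \in [-10, \max(\mathrm{day})+10]$ exclude
  flat-line and step degeneracies. Flat trajectories raise a "no growth
  signal" error; non-convergence raises an error carrying the best
  attempt. $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$.
* **Day grid.** Day 0 is seeding; the daily series runs over integer
  days 0..harvest inclusive. The days-0–3 tail contributes negligibly
  (PCS < 1 cm²), so this convention is cosmetic but fixed.
* **Quadrature cross-check.** The daily sum treats each day as a
  unit-width bin, so the independent oracle used in tests integrates the
  continuous curve over $[-0.5, \text{harvest}+0.5]$ (midpoint-rule
  framing) with a 1000-point trapezoid; agreement is well within 2%.
  Integrating over $[0, \text{harvest}]$ instead would disagree by ~5%
  purely from end effects — a range-convention artifact, not an error.
* **Zero-noise regressions.** With zero residual variance, t-based
  p-values are undefined; they are reported as `NA`, and the pruning rule
  falls back to dropping the interaction exactly when its coefficient is
  numerically zero relative to the PPFD slope. A constant response
  returns a degenerate fit (zero slopes, $R^2 = 0$) instead of an error.
* **Saturated curve fits.** `fit_response_curve()` accepts $n =$
  number-of-parameters points (e.g. a two-point line), the standard way
  to quote a slope from published endpoints; `fit_sigmoid()` still
  requires ≥ 4 distinct days.
* **Determinism.** One seed drives the experiment; per-image seeds are
  derived from it, and the renderer restores the caller's RNG state.
  Identical seed + configuration reproduces every table byte-for-byte.

## What the generator does and does not emulate

It reproduces the *statistical and morphological structure* of the study:
design (6 × 2 × 3, nine-plant units), sigmoidal PCS with PPFD-dependent
asymptotes, linear physiology responses with the published slopes, LUE
and overlap ladders, and dry weights that are exactly
`LUE × true incident light` before noise — which is what makes end-to-end
parameter recovery a meaningful test.

It does **not** emulate: spectral physics of fluorescence excitation or
camera optics (lens distortion, perspective); within-group plant-to-plant
variation (only group-level noise is observable in the emulated study);
correlated unit-level vigor — PCS noise and dry-weight noise are drawn
independently, whereas in real crops a unit that grows large early also
tends to end heavy. That last simplification deliberately *understates*
the early-PCS → final-biomass correlation: the generator yields strong
positive correlations (median R ≈ 0.7–0.9 across seeds), somewhat below
the ~0.9 reported from real data, and the tests assert the qualitative
property rather than the real-data value. Passing tests therefore
demonstrate pipeline correctness (recovery of known truth), not that real
images will segment this cleanly: real fluorescence imaging contends with
algae, substrate autofluorescence and touching canopies between groups.

## Problem sizes

The test suite and examples run the full 36-unit experiment at its study
dimensions for all table-level stages. Image-based checks use single
units or single plants (areas 10–400 cm² at 0.05 cm px⁻¹, canvases up to
~1500² px), the fit-quality sweep uses 50 seeds, stochastic recovery
checks use 15-seed medians, and the interaction-pruning calibration uses
500 null simulations against a 99.9% binomial band around α.

## Interfaces

The package is function-first: `run_pipeline(run_config(...))` is the
single-call entry point (YAML configs via `run_config_from_yaml()`), and
each stage is an ordinary data-frame-in/tibble-out function, so shell
orchestration reduces to one-line `Rscript -e` calls;
`scripts/acceptance.R` in the repository is an example of exactly that.
On-disk interchange uses plain formats throughout: PNG/TIFF images with
JSON sidecars, CSV tables (`pcs_long.csv`, `sigmoid_fits.csv`,
`pcs_daily.csv`, `incident_light.csv`, `traits.csv`,
`regression_report.csv`) and a versioned `report.json`.

## Known limitations

* Incident ≠ absorbed light; LUE here folds absorptance into the
  efficiency term.
* Uncertainty from the sigmoid fit is reported (`residual_sd`) but not
  propagated into LUE.
* The regression layer is fixed-effects OLS; genuine split-plot error
  strata are out of scope.
* Alternative growth forms (Gompertz, Richards) are not implemented.
* The renderer's overlap-ratio control is approximate (±7% target band);
  only the projected-area contract is tight (1%).
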