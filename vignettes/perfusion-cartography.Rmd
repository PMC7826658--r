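---
title: "Methods: perfusion cartography, capillary density and lactate prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perfusion cartography, capillary density and lactate prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfmap)
```

This vignette documents the models implemented in `perfmap`, the choices
made where the underlying procedures admit more than one reasonable
definition, and what the synthetic experiment does and does not establish.

## The perfusion surrogates

Two per-pixel quantities stand in for tissue perfusion.

**Time-to-peak slope.** After an intravenous indocyanine-green bolus, the
fluorescence intensity of a well-perfused pixel rises quickly to a bright
plateau; an ischemic pixel rises late and dimly (dye reaches it only by
diffusion). The cartography summarizes each pixel's curve by

$$\mathrm{slope} = \frac{I_{\text{peak}} - I_{\text{baseline}}}{t_{\text{peak}}},$$

in units of normalized intensity per second. Definitional choices, all
configurable:

* *Normalization.* Fluorescence falls off with distance (inverse quadratic
  law) and varies with illumination. Every frame is divided by that frame's
  mean intensity over a constant-fluorescence reference card in the scene.
  This makes the stack dimensionless, sets reference pixels to mean 1, and
  cancels any multiplicative factor common to tissue and card — the scale
  invariance that the test suite asserts exactly.
* *Baseline* is the mean of the first 5 raw frames (frame 0 is taken as the
  injection time; there is no bolus-arrival detection).
* *Smoothing* is a centered moving average, default window 5 frames, with
  partial windows at the edges.
* *Peak and tie-break:* the **first** frame attaining the smoothed maximum,
  matching the "time required to reach the maximum" semantics and making the
  estimate deterministic. A pixel is invalid when the smoothed maximum does
  not exceed the baseline by `min_delta` (default 0.02 normalized units —
  suppresses background and reference pixels) or when the peak falls on the
  first frame, where the slope is undefined.

The vectorized map is, by construction and by test, bit-identical to
applying the scalar estimator per pixel.

**StO2.** Hyperspectral tissue-oxygen-saturation maps are consumed as
device output (percent per pixel); no spectral inversion is modeled. Zone
classification replaces an investigator's manual annotation with explicit
thresholds: ischemic below 33%, vital at or above 63%, transition between.
The defaults are the midpoints between the in-vivo per-zone means
(16.5 / 48.8 / 76.5%); connected components smaller than 25 px are removed,
and an empty class is a hard error naming the class, since every downstream
step assumes three nonempty ROIs.

## Enhanced-reality registration

The static StO2 map is deformed onto the fluorescence cartography with
affine moving least squares from manually picked landmark pairs. For an
evaluation point $v$, weights $w_i = 1/\lvert p_i - v\rvert^{2\alpha}$
(default $\alpha = 1$) define the affine map minimizing
$\sum_i w_i \lvert A(p_i) - q_i \rvert^2$, applied to $v$. Numerical
choices:

* distances are floored at $10^{-8}$ px, and points within 0.5 px of a
  source landmark snap to that landmark's displacement — the exact
  interpolation limit of the weight function;
* landmark sets whose centered source points are collinear make the 2×2
  normal matrix singular and raise a degenerate-configuration error;
* the dense field is the *inverse* map (target to source), evaluated every
  4 px and bilinearly upsampled before bilinear image resampling — the
  affine-in, affine-out property is preserved because bilinear upsampling is
  exact for fields that are affine in the grid coordinates. Target pixels
  falling outside the source image are flagged invalid.

Pairs consistent with one global affine map are reproduced exactly;
arbitrary configurations interpolate their landmarks within 0.5 px
(property-tested over random configurations). Overlays are plain alpha
blends on valid pixels.

## Capillary density: the FCD-A index

$$\mathrm{FCD\text{-}A} = \frac{\bar d \cdot L}{A_{\mathrm{FOV}}}$$

with $\bar d$ the skeleton-pixel-weighted mean vessel diameter, $L$ the
total centerline length and $A_{\mathrm{FOV}}$ the pixel count of the round
field of view. The reference vessel-detection software is proprietary; the
operator chain here is the minimal one satisfying "elongated bright
structures": Gaussian blur ($\sigma = 1$), Otsu threshold computed within
the FOV, component filters (elongation = major/minor axis ratio ≥ 3, area ≥
50 px²), Zhang–Suen thinning, and per-skeleton-pixel diameter as twice the
Euclidean distance transform of the vessel mask. Skeleton length counts
4-neighbor steps as 1 and diagonal steps as √2, skipping diagonals already
mediated by an orthogonal pixel.

Discretization caveats worth knowing: a band whose centerline sits exactly
on a pixel row rasterizes one pixel wider than its nominal diameter (the
test phantoms use sub-pixel centerlines, as the random generator does), and
lattice-aligned 45° vessels are the worst case for the distance-transform
diameter (inflation up to ~20% of the index, vs < 10% at generic angles).
Absolute FCD-A magnitudes from the reference software have unstated
normalization; the per-zone phantom densities are therefore calibrated so
the *measured* indices reproduce the in-vivo zone contrast
(≈ 0.26 / 0.247 / 0.122, vital ≈ 2.1× ischemic), and only orderings and
ratios are treated as meaningful.

## Lactate prediction

Local capillary lactate (LCL) accumulates in ischemic tissue; systemic
lactate sets the floor. With normalized LCL = LCL − systemic, each metric
$x$ (StO2 in percent, or slope) gets the model

$$\widehat{\mathrm{LCL}} = e^{-a x + b} + \text{systemic lactate}.$$

$(a, b)$ minimize the **raw-scale** squared error
$\sum_i (y_i - e^{-a x_i + b})^2$ (Levenberg–Marquardt), initialized from a
log-linear fit of $\log\max(y_i, 10^{-3})$. Non-positive normalized values —
possible when LCL < systemic — stay in the raw-scale fit and are floored
only for initialization; the objective is always positive so the raw-scale
problem remains well defined. Whether such published calibrations are fit on
the raw or the log scale is often unstated, so `loss = "log"` exposes the
alternative; raw is the default and the one used throughout. If the
initializer already fits to machine precision the optimizer is skipped (its
gradient check degenerates on zero residuals).

Model evaluation:

* **Leave-one-subject-out CV** holds out all three ROIs of one subject per
  fold; per-record absolute errors are reported.
* **Error summaries** give mean, SD, median and `q95_threshold` — the 95th
  percentile (linear interpolation) of observed LCL over the error-bearing
  records, i.e. the LCL level below which 95% of the errors occur. This is
  one reading of that statement; it is documented rather than asserted
  against any external value.
* **Paired Wilcoxon comparison** of two models' record-wise errors drops
  zero differences (p = 1 if none remain), uses the exact tie-aware null of
  the positive-rank sum for ≤ 25 nonzero pairs (convolution over doubled
  ranks, verified against exhaustive sign enumeration), and the normal
  approximation with tie and continuity corrections above.
* **Spearman correlation** is the Pearson correlation of average ranks with
  a two-sided t-approximation p-value.
* **Sample size** for detecting correlation $r$ uses the Fisher z method,
  $n = \lceil ((z_{1-\alpha/2}+z_{\text{power}})/C)^2 + 3 \rceil$,
  $C = \tfrac12\log\frac{1+r}{1-r}$ — the standard formula, which gives 13
  paired values at $r = 0.78$, $\alpha = 0.05$, power 0.9, and agrees with a
  brute-force simulated power search within ±1 over $r \in [0.5, 0.9]$.

## The synthetic experiment

The generators define the study conditions; every downstream stage is
tested against their analytic ground truth.

* **Scene**: three zone bands plus a reference card; 96×96 px by default.
* **Inflow curves**: the kinetics family is not published, so each zone
  follows a truncated-logistic rise — smooth, monotone, with an unambiguous
  first-attained plateau at `time_to_peak` (the slope metric depends only on
  peak timing and height, not on the curve family). Defaults: delay
  2/4/8 s, time-to-peak 8/15/30 s, plateau 100/80/30 intensity units on a
  reference of 50, chosen once to reproduce the in-vivo slope ordering.
  Distance attenuation is a single multiplicative scene factor, which the
  reference normalization cancels exactly.
* **StO2 maps**: zone pixels are Normal(76.5, 6.0), (48.8, 8.1),
  (16.5, 4.76) percent — the reported per-ROI means/SDs — clipped to
  [0, 100].
* **Capillary phantoms**: straight vessels of known diameter and total
  length in parallel lanes with positional/angular jitter (random global
  orientation per frame); ground truth length, diameter and index are
  analytic.
* **Cohort**: six subjects by default; systemic lactate Normal(1.87, 0.869)
  mmol/L; per-zone StO2 and slope draws from the reported marginals; LCL
  generated from the StO2 model (a = 0.0343, b = 2.72) with multiplicative
  log-normal noise (SD 0.3 on the log scale — set so that noisy coefficient
  recovery is realistic rather than trivial, and so lactates stay positive).

All generators draw through one explicitly passed seed and restore the
global RNG state; identical parameters and seed give bit-identical outputs,
and `run_experiment()` reports a config hash alongside the seed.

**What passing tests do and do not show.** The synthetic scene has no
motion, no breathing, no spatial StO2 gradients within a zone, no photon
transport, no fluorescein leakage or pooling, and its cohort ties lactate
to StO2 by construction — so end-to-end tests establish the correctness of
the *computations* (estimators recover known ground truth; orderings and
correlation signs mirror the in-vivo ones) but say nothing about how the
chain behaves on real surgical video. Published headline statistics from
the original 18-record animal dataset (correlation magnitudes, absolute
error levels, absolute FCD-A values) are treated as sign/ordering anchors
only, since that dataset is not available.

## Problem sizes and runtime

Default problem sizes are chosen to keep a full run interactive on a
laptop: 96×96 px scenes, 40 s × 25 fps stacks (1000 frames), 241×241 px
capillary frames with 3 frames per zone, 6-subject cohorts, 200-replicate
Monte-Carlo recovery checks, and 20 000-replicate power simulations.
`run_experiment()` completes in a few seconds; the full test suite in well
under a minute.

## Known limitations

* The slope's absolute scale depends on the (arbitrary) fluorescence units
  and plateau heights; only orderings, ratios and correlations are
  meaningful.
* The FCD-A diameter estimator inherits distance-transform lattice bias at
  exactly diagonal orientations (see above).
* MLS warping is the affine variant; similarity/rigid variants are not
  implemented.
* The classification thresholds assume StO2 plateaus per zone; strongly
  graded maps would need different thresholds or a spatial model.
* Lactate models assume a single exponential with multiplicative noise;
  heteroscedastic additive noise would call for weighted least squares.
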