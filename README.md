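# perfmap

Quantitative perfusion cartography from intraoperative optical imaging.

During visceral surgery, deciding where tissue is still viable is hard to do
by eye. Two imaging modalities address this quantitatively: fluorescence
angiography with indocyanine green (ICG), where the *speed* at which the dye
reaches each pixel's maximal intensity reflects local inflow, and
hyperspectral imaging, whose device output is a per-pixel tissue oxygen
saturation (StO2) map. `perfmap` implements the analysis chain that turns
these signals into perfusion maps and biomarker predictions, together with a
synthetic-data generator that emulates a three-zone (vital / transition /
ischemic) partial-ischemia experiment so the whole chain can be exercised
and tested without any external data.

## What it computes

* **Time-to-peak slope cartography.** Each video frame is divided by the
  mean intensity of a constant-fluorescence reference card in the scene
  (cancelling distance/illumination falloff), then for every pixel the slope

  `slope = (I_peak − I_baseline) / t_peak`

  is computed, where `t_peak` is the time of the first frame attaining the
  smoothed maximum. Fast, bright inflow (vital tissue) gives large slopes;
  slow, dim inflow (ischemic tissue) gives small ones.
* **StO2 zone analysis.** Threshold-based classification of the StO2 map
  into ischemic / transition / vital zones (defaults 33% / 63%) with
  small-object cleanup, and per-ROI means for both modalities.
* **Enhanced-reality registration.** Affine moving-least-squares (MLS)
  warping driven by landmark pairs: for each evaluation point `v` the affine
  map minimizing `Σ w_i |A(p_i) − q_i|²` with `w_i = 1/|p_i − v|^(2α)` is
  applied, deforming the static StO2 map onto the fluorescence cartography;
  alpha-blended overlays composite either map onto a video frame.
* **Capillary density (FCD-A).** Vessels in confocal endomicroscopy frames
  are segmented as elongated bright structures, thinned to a centerline, and
  the functional capillary density area index is
  `FCD-A = mean diameter × total length / field-of-view area`.
* **Lactate prediction.** Exponential models
  `LCL = exp(−a·x + b) + systemic lactate` (x = StO2 or slope) fit by
  raw-scale nonlinear least squares to systemic-normalized local capillary
  lactate, with leave-one-subject-out cross-validation, paired Wilcoxon
  comparison of two models' errors (exact tie-aware null for small n),
  Spearman correlation, and Fisher-z correlation sample sizes.

## Worked example

```r
library(perfmap)
report <- run_experiment(perf_config(seed = 1))
print(report)
```

```
Synthetic perfusion experiment (seed 1 , config 80cae83b )
Per-zone metrics (classified ROIs):
       zone sto2_mean sto2_sd slope_mean slope_sd n_pixels
      vital      76.6    5.98     0.1028  0.05042     2560
 transition      48.7    6.77     0.0647  0.01901     2404
   ischemic      16.5    4.78     0.0184  0.00298     2595
Registration: max landmark residual 0 px, 81% valid
FCD-A zone means: vital 0.297, transition 0.282, ischemic 0.129 
Models: StO2 (a=0.03339, b=2.744); slope (a=0.09497, b=1.703)
LOO-CV mean error: StO2 1.56, slope 3.08 mmol/L (Wilcoxon p = 0.00475)
Spearman: StO2~slope 0.095, StO2~LCL -0.742, slope~LCL -0.182
```

Reading this: the classified zones recover the generator's StO2 levels
(76.5 / 48.8 / 16.5%), both per-zone metrics are ordered
vital > transition > ischemic, landmark registration is exact at the control
points, capillary density collapses in the ischemic zone, and the StO2-based
lactate model (fit on the 18 ROI-level records of the six synthetic
subjects) recovers coefficients close to its generating model
(a = 0.0343, b = 2.72) and predicts held-out subjects' lactate with a mean
absolute error of ~1.6 mmol/L. Both metrics correlate negatively with local
capillary lactate. `render_report(report, "figs")` writes the
scatter-plus-curve and per-zone summary figures.

Individual stages are plain functions, e.g.

```r
video <- generate_fluorescence_video(default_scene_layout(), seed = 1)
slope <- compute_slope_map(normalize_by_reference(video))
m     <- fit_lcl_model(generate_cohort(cohort_params(seed = 1)), "sto2")
summary(m)
```

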