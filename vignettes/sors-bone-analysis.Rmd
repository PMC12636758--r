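---
title: "Depth-resolved Raman analysis of bone: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved Raman analysis of bone: model, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorsbone)
```

## The problem

Dual-energy X-ray absorptiometry (DXA) grades bone loss by mineral
density alone, summarized as a T-score and binned into the WHO classes
normal (T > -1), osteopenia (-2.5 < T <= -1) and osteoporosis
(T <= -2.5). Raman spectroscopy sees what DXA cannot: the chemical
make-up of the tissue, through the phosphate nu1 band of apatite at
960 cm^-1, carbonate substitution near 1070 cm^-1, and the
collagen-associated Amide III, CH2 and Amide I bands. Ratios of the
phosphate band to the matrix bands ("mineral-to-matrix" ratios) track
demineralization. Spatially offset Raman spectroscopy (SORS) collects
scattered light laterally displaced from the excitation spot; photons
arriving at larger offsets have travelled deeper, so an offset
measurement weights the subcortical bone more heavily than the surface
cortex.

`sorsbone` implements the full analysis chain for such measurements —
detector-frame calibration, spectral cleanup, band-ratio statistics,
and cross-validated T-score regression — together with a synthetic
cohort and instrument simulator that provides ground truth for every
stage, so the whole pipeline is testable without access to cadaver
data.

## The generative model

### Cohort

`cohort_spec()`/`generate_cohort()` simulate a cohort of female donors
in the three WHO classes (default 8/6/11). Class T-scores are drawn
from normal distributions (defaults 0.05 +/- 0.45, -1.63 +/- 0.38,
-4.19 +/- 0.90) truncated to each class's WHO interval, so a label
never contradicts its own score.

Bone is modelled as two layers — surface cortex and subcortical bone —
each carrying amplitudes for the five bands. Band `b` in layer `l` of
a donor with T-score `t` has amplitude

    A_bl = a_b * (1 + kappa_l * beta_b * (t_ref - t)) * (1 + eta) + eps_bl

* `a_b`: baseline amplitude (phosphate 1000 counts; carbonate, Amide
  III, CH2, Amide I at 250/180/350/300).
* `beta_b`: link slope per T-score unit (0 for phosphate — the fixed
  reference; 0.06 for carbonate; 0.10-0.12 for the matrix bands).
  Lower T-score therefore raises every matrix band relative to
  phosphate, the direction seen in diseased bone.
* `kappa_l`: layer link strength — 1 subcortically, 0.3 at the
  surface. Compositional change with disease is stronger at depth,
  which is what makes the offset geometry diagnostic.
* `eta ~ N(0, 0.06)`: a per-donor heterogeneity factor shared by all
  linked bands. This term is deliberate: matrix content is not a
  deterministic function of the T-score in real cohorts (age, collagen
  maturity and remodelling history all move it), and without a shared
  factor the per-band residuals average away across four bands and
  cross-validated prediction becomes unrealistically easy (r > 0.99).
  With `matrix_sd = 0.06` the irreducible T-score error at the 3-mm
  geometry is roughly `matrix_sd` divided by the effective link slope
  (~0.065 per T-unit), i.e. about 0.9 T-score units — the error regime
  a cohort-level Raman/DXA comparison actually operates in. Because
  `eta` multiplies all linked bands equally, contrasts between linked
  bands (e.g. carbonate versus Amide III) cancel it, which is why a
  multivariate model beats any single ratio.
* `eps_bl ~ N(0, 0.035 * a_b)`: independent per-band, per-layer noise.

Each donor also gets a smooth fluorescence background (an order-3
polynomial over the axis rescaled to [-1, 1], positive everywhere,
lognormal amplitude around 3000 counts — several times the phosphate
peak, as in real bone) and a small band-position jitter
(sd 0.2 cm^-1).

### Offset mixing

A spectrum collected at offset `d` is the weighted sum of the two
layer spectra with subcortical weight `w(0) = 0.2`, `w(3) = 0.5`,
`w(6) = 0.6` (weights sum to 1; `render_clean_spectrum()`). These
weights are phenomenological stand-ins for photon transport — no
Monte-Carlo light propagation is attempted — and are configurable.
Their ordering is the only thing the analysis relies on: deeper
sampling at larger offset. Bands are Gaussian with full widths of
12-25 cm^-1, standard for bone at this resolution; the source never
constrains the lineshape, so Gaussian is a modelling choice.

### Instrument

`detector_spec()` describes a 1024 x 256 px CCD spectrograph behind an
830-nm laser: a quadratic pixel-to-wavelength dispersion
(~0.18 nm/px), a quadratic "smile" column shift versus row (default
4e-5 px/row^2, about 2.6 px across the detector), a per-pixel
lognormal fixed-pattern gain (sd 5%, unit mean), a smooth broadband
response, a 500-count dark level, additive Gaussian read noise
(default sigma = 0.4 counts/px/frame, the high-ADU-gain regime of a
cooled deep-depletion detector), and Poisson-count single-pixel cosmic
rays (5 per frame expected, 200-2000 counts). The three fiber bundles
(4, 12, 26 fibers at 0/3/6 mm) map to disjoint detector row blocks;
each bundle row carries 1/n of the bundle signal so row summation
reconstructs the spectrum. `render_frame_stack()` records every
injected cosmic-ray position, which the tests use as an oracle.

## The processing chain

The stage order is fixed and enforced: calibrate, extract, reject
cosmic rays, average, remove baseline, clip, normalize.

1. **Dark subtraction** (`dark_subtract`), elementwise.
2. **Smile rectification** (`fit_rectification`/`apply_rectification`):
   per-row intensity-weighted centroids of the 15 neon + 13
   acetaminophen calibration peaks, one shared quadratic drift law
   (free intercept per peak), rows resampled by linear interpolation,
   then cropped to 499 spectral pixels. A shared-curvature model is the
   minimal one consistent with a single optical aberration; the
   centroid window (11 px) recenters on the running centroid so that
   shifted peaks are not truncated asymmetrically — without this the
   recovered curvature is biased low by ~10%.
3. **Axis calibration** (`calibrate_axis`): quadratic pixel-wavelength
   fit to the neon centroids (axis rescaled to [-1, 1] for
   conditioning), then the effective laser wavelength solved in closed
   form from the acetaminophen shifts, which are linear in
   `1/lambda0`. Detected peaks are matched to the known line lists by
   choosing the order-preserving subset that minimizes the fit
   residual, which tolerates spurious detections near the crop edges.
   The line lists supplied must be the lines visible inside the
   cropped window.
4. **Response correction** (`correct_response`): division by the
   high-frequency fixed pattern of the white-lamp frame (frame over
   its 31-px moving median) and by the broadband response (smoothed
   ratio of measured to certified glass-standard emission, unit mean).
   The absolute throughput is not identifiable — all spectra are
   recovered up to a single global scale, which the phosphate
   normalization later removes anyway.
5. **Cosmic-ray rejection** (`reject_cosmic_rays`): per pixel across
   the five replicate spectra, values exceeding the mean of the four
   lowest by more than 10 unscaled MADs of those four (floored at
   1 count) are replaced by that mean. Two reading choices are
   deliberate: the MAD carries no 1.4826 consistency factor, and
   flagged values are replaced rather than deleted so averaging stays
   balanced. The four-sample MAD is a very noisy scale estimate — on
   pure Gaussian noise the literal rule would flag ~10% of pixels if
   the floor were inactive — so the 1-count floor is doing real work:
   at the default read noise it sets a fixed ~10-count detection
   limit, far below any real cosmic ray (hundreds of counts) and far
   above the noise.
6. **Averaging** (`average_frames`), refused until rejection has run.
7. **Fluorescence removal** (`remove_fluorescence`): iterative
   modified polynomial fitting, order 7, at most 10 iterations,
   stopping when the relative L2 change of the fitted polynomial drops
   below 0.05%. The convergence functional is a choice (the source
   states only a percentage); successive changes are monotone
   non-increasing in practice and the loop converges in ~5 iterations
   on bone-like spectra.
8. **Noise-floor clipping** (`clip_to_noise_floor`): sigma_noise is
   the residual sd about a linear trend in a signal-free window
   (default 1750-1800 cm^-1); values below -sigma/2 saturate at that
   bound ("clipping" read as saturation, not deletion).
9. **Phosphate normalization and ratios**
   (`normalize_to_phosphate`/`compute_ratio_set`): bands are
   quantified as chord-corrected peak height by default (area is
   available). The chord between the +/- 20 cm^-1 window endpoints
   removes residual linear background; it underestimates wide
   Gaussians whose wings reach the window edge by a fixed factor,
   which cancels in every ratio comparison. Height was preferred over
   area as the default because at 499-px resolution neighbouring-band
   wings contaminate areas more than apexes.

## Statistics and regression

`pairwise_group_tests()` compares each ratio across N-OP, N-OPE and
OPE-OP with a two-sided Mann-Whitney U test by default (groups of 6-11
cannot support a normality assumption; Welch's t is available), with
Bonferroni correction across the three pairs, capped at 1. The source
tables this package mirrors contain p = 1.0000 entries, which is what
a capped correction produces; the test choice itself is a design
decision, not an inference about the original software.

`fit_pls()` is a from-scratch single-response NIPALS partial least
squares regression: mean centering only (no variance scaling — the
predictors share units), weight vectors proportional to `X'y`,
orthogonal scores, and coefficients `beta = W (P'W)^{-1} q`. At full
rank with fewer predictors than observations it reproduces ordinary
least squares; the test suite also checks it against an independent
reference implementation. `loocv_select_rank()` runs leave-one-out
cross-validation over ranks 1-9, recomputing the centering inside
every fold (a leakage test verifies no held-out statistic enters
training), picks the rank minimizing RMSE_CV with ties broken toward
parsimony, and reports the LOO predictions, Pearson r, RMSE_CV and
WHO classification accuracy. The phrase "rank chosen in each
iteration" in the source protocol is ambiguous between global and
per-fold selection; both are implemented (`per_fold = TRUE`), global
is the default because the protocol then selects "the" optimal rank
from the RMSE_CV curve.

Predictors default to phosphate-normalized processed spectra
(`normalize_predictors = TRUE`): normalization removes the arbitrary
per-measurement throughput scale, which is standard chemometric
practice when absolute intensities are not calibrated; raw processed
spectra are a flag away.

## What the simulation does and does not show

Problem sizes: the pipeline tests run the full 25-donor cohort at
1024 x 256 px with 5 frames per site; the recovery property uses 20
cohort replicates, and the null calibration of the group tests uses
1000 simulated two-group cohorts at the ratio level. On one CPU a full
cohort run takes under ten seconds.

Passing tests demonstrate that the implementation inverts its own
generative model: known smile, dispersion, gain, response and laser
wavelength are recovered (curvature within 1%, lambda0 within 0.01 nm,
bundle spectra within 2% RMS at zero noise); seeded cosmic rays are
flagged with a false-positive rate below 0.1%; and T-scores are
recovered at 3 mm (r >= 0.8, RMSE_CV <= 1.2 in at least 80% of
cohorts) with strictly worse 0-mm performance, reproducing the
qualitative offset ordering. They do not demonstrate performance on
real bone: the two-layer mixture, Gaussian lineshapes, additive
Gaussian noise and the phenomenological offset weights are all
idealizations, the offset weights in particular are free parameters
rather than estimates of any real probe, and the synthetic
heterogeneity (`matrix_sd`) sets the difficulty of the regression by
construction.

## Known limitations

* No keystone (row-direction) distortion, slit-function deconvolution
  or detector nonlinearity; the smile model is column-shift only.
* Cosmic rays are single-pixel; multi-pixel morphologies would need a
  spatial model and a different oracle.
* The crop position within the 1024 columns is a convention (centered);
  only the 499-px length is fixed.
* Ratio quantities and PLS inputs use the fitted axis; residual axis
  error (< 0.1 cm^-1 in simulation) is negligible against the 20 cm^-1
  band windows but is not propagated as uncertainty.
* Group-test and regression outputs are point estimates; no uncertainty
  intervals on predictions are provided.

## A minimal run

```{r example, eval = FALSE}
run <- run_pipeline(pipeline_config(seed = 1))
print(run)
run$comparisons[["3mm"]]
run$cv[["3mm"]]$rmse_cv
```
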