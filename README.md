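# sorsbone

Spatially offset Raman spectroscopy (SORS) analysis of cortical bone:
from raw CCD frames to mineral-to-matrix band ratios and
cross-validated DXA T-score prediction.

## What problem this solves

Osteoporosis screening relies on DXA bone mineral density, summarized
as a T-score and binned into the WHO classes Normal (T > −1),
Osteopenia (−2.5 < T ≤ −1) and Osteoporosis (T ≤ −2.5). Raman
spectroscopy adds chemistry: the phosphate ν₁ band at 960 cm⁻¹
against the carbonate (≈1070 cm⁻¹), Amide III (≈1250), CH₂ (≈1450)
and Amide I (≈1660 cm⁻¹) bands. Collecting the Raman signal at a
lateral offset from the laser spot weights deeper, subcortical bone,
where disease-related compositional change is strongest.

`sorsbone` is aimed at spectroscopists building such analyses. It
implements:

- **Frame calibration** — dark subtraction; smile rectification by a
  shared quadratic column-drift law fitted to the centroids of 15 neon
  and 13 acetaminophen calibration peaks, cropped to 499 spectral
  pixels; pixel–wavelength calibration from the neon lines and a
  closed-form solve of the effective laser wavelength λ₀ from the
  acetaminophen Raman shifts via ν = 10⁷(1/λ₀ − 1/λ); two-step
  response correction (white-lamp fixed pattern, certified green-glass
  broadband response); bundle-row summation into per-offset spectra.
- **Spectral cleanup** — per-pixel cosmic-ray rejection across the
  five replicate frames (flag if a value exceeds the mean of the four
  lowest by 10 unscaled MADs of those four, floored at 1 count);
  frame averaging; iterative modified-polynomial fluorescence removal
  (order 7, ≤10 iterations, 0.05% convergence); clipping below the
  noise floor at −σ/2.
- **Band metrics** — phosphate normalization and the five diagnostic
  ratios PO₄/CO₃, PO₄/Amide III, PO₄/CH₂, PO₄/Amide I, CO₃/Amide III,
  with pairwise Mann–Whitney group tests and star annotation.
- **Chemometrics** — from-scratch single-response NIPALS partial
  least squares regression (β = W(PᵀW)⁻¹q on centered data),
  leave-one-out cross-validation over ranks 1–9 with RMSE_CV rank
  selection, Pearson r, and WHO classification of predicted T-scores.
- **A synthetic cohort and instrument simulator** — 25 donors
  (8 normal / 6 osteopenic / 11 osteoporotic, class T-scores
  0.05 ± 0.45, −1.63 ± 0.38, −4.19 ± 0.90), a two-layer band-amplitude
  model linking composition to T-score, offset-dependent layer mixing,
  and a full CCD model (smile, gain, response, dark, read noise,
  cosmic rays) with recorded ground truth for every stage.

The methods vignette (`vignettes/sors-bone-analysis.Rmd`) documents
the generative model, every numerical choice and the limitations.

## Worked example

```r
library(sorsbone)
run <- run_pipeline(pipeline_config(seed = 1))
print(run)
#> SORS bone analysis run: 25 specimens, offsets 0/3/6
#>   0mm: LOOCV PLSR (global rank selection): optimal rank 5, r = 0.850, RMSE_CV = 1.061, accuracy = 76%
#>   3mm: LOOCV PLSR (global rank selection): optimal rank 6, r = 0.931, RMSE_CV = 0.724, accuracy = 80%
```

The two lines are the headline result: with 3-mm offset spectra the
leave-one-out PLSR predicts distal-radius T-scores with Pearson
r = 0.93 and RMSE_CV = 0.72 T-score units on this synthetic cohort,
while the surface-weighted 0-mm geometry is clearly worse
(r = 0.85, RMSE_CV = 1.06) — the depth-sensitivity advantage the
offset geometry exists for. Group contrasts at 3 mm:

```r
head(run$comparisons[["3mm"]], 3)
#>     ratio   pair      p_value stars
#> 1 PO4/CO3   N-OP 7.620862e-03    **
#> 2 PO4/CO3  N-OPE 1.778222e-01    ns
#> 3 PO4/CO3 OPE-OP 6.060116e-02    ns
```

p-values are Bonferroni-corrected across the three class pairs and
annotated with the usual stars (≤0.0001 `****` … ≤0.05 `*`). All five
N-vs-OP contrasts are significant at 3 mm for this seed.

Individual stages are exported and composable: `generate_cohort()`,
`render_frame_stack()`, `fit_rectification()`, `calibrate_axis()`,
`reject_cosmic_rays()`, `remove_fluorescence()`,
`compute_ratio_set()`, `fit_pls()`, `loocv_select_rank()`, …

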