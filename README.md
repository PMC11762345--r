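# endohsi

Snapshot RGB → visible-range hyperspectral conversion for endoscopic
imaging, with simulated narrow-band imaging and a detection-evaluation
metric layer.

## The problem

Early esophageal lesions (squamous cell carcinoma and its precursor,
dysplasia) are subtle under white-light endoscopy. Narrow-band imaging
(NBI) — illumination at ~415 nm (blue) and ~540 nm (green) — highlights the
mucosal vasculature, but needs dedicated optics. An alternative is
*spectral conversion*: calibrate the endoscope camera once against a
24-patch colour target measured with a spectrometer, then expand every RGB
frame into a per-pixel visible-range reflectance spectrum (380–780 nm, 401
bands), from which NBI-like renderings can be synthesised computationally.
`endohsi` implements that pipeline end to end for researchers working on
spectrally-enhanced endoscopic image analysis.

## The model

Three fitted stages, all estimated from the 24 calibration patches:

1. **Camera correction.** sRGB code values are decoded (IEC 61966-2-1) and
   mapped to CIE 1931 XYZ (white Y = 100). Camera defects are corrected by
   a polynomial model fitted by Moore–Penrose pseudoinverse:

   C = XYZ_Spectrum · pinv(V),  XYZ_Correct = C · V

   where V holds monomials of the camera XYZ per patch (default `poly3`,
   20 terms up to total degree 3).

2. **Spectral basis.** Mean-centred PCA of the measured reflectance
   spectra; six components explain ≥ 99.64 % of chart variance.

3. **Score regression.** Component scores regressed on the polynomial
   expansion of the corrected XYZ, giving the reconstruction
   S = mean + EV · (M_reg · V_Color).

Quality is scored by per-patch XYZ RMSE, per-patch spectral RMSE (percent
reflectance) and CIEDE2000 colour difference. A built-in simulator
(analytic CIE observer, illuminants, synthetic colour chart, distortable
virtual camera) makes everything testable without instrument data.

The detection layer evaluates object-detector output in YOLO text format:
IoU matching with a background class into a confusion matrix
(rows = predicted, columns = true), per-class sensitivity / precision /
specificity / F1, overall accuracy, Cohen's kappa, and 101-point
interpolated average precision.

## Worked example

```r
library(endohsi)

## calibrate on the synthetic 24-patch target (seed 42)
ps <- build_calibration_fixture(seed = 42)
model <- calibrate_patch_set(ps, term_spec = "poly3", n_pc = 6)
model
#> <conversion_model>
#>   patches:                 24
#>   XYZ RMSE (corrected):    0.0321  (uncorrected 9.2256)
#>   spectral RMSE:           0.2224 % reflectance
#>   explained variance (6 PC): 100.00 %
#>   mean dE00:               0.0952
```

The corrected camera XYZ lands within 0.03 units (Y = 100 scale) of the
spectrometer reference — the polynomial correction removes the simulated
gamma mismatch, crosstalk and dark current almost entirely (uncorrected
error: 9.2). Reconstructed spectra deviate from truth by 0.22 % reflectance
on average.

```r
## convert a scene and synthesise an NBI view
scene <- build_scene(ps, layout = matrix(1:4, 2, 2), size = 64)
cube <- convert_image(scene$rgb, model)
cube
#> <hypercube 64 x 64 x 401, 380-780 nm, convert_image>
nbi <- simulate_nbi(cube)          # 415 nm -> G,B; 540 nm -> R
write_cube(cube, "scene_cube", format = "envi")

## score a detector from its printed confusion matrix
cm <- read_confusion_csv(system.file("extdata", "confusion_rgb_wli.csv",
                                     package = "endohsi"))
met <- metrics_from_confusion(cm)
round(met$accuracy, 4)
#> [1] 0.7768
met$per_class
#>       class sensitivity precision specificity        f1
#> 1       SCC   0.7822823 0.9303571   0.9750480 0.8499184
#> 2 dysplasia   0.7513441 0.8817035   0.9494949 0.8113208
#> 3    normal   0.8006231 0.8908146   0.9603025 0.8433142
```

Accuracy 0.78, SCC sensitivity 0.78, SCC precision 0.93, mean F1 0.83 —
the worked-example table reproduces the published two-decimal values
(sensitivity, precision, F1, accuracy) exactly; specificity and kappa are
reported under their standard definitions (see the methods vignette).

A command-line layer wraps the same operations:

```sh
Rscript -e 'quit(status = endohsi::endohsi_cli())' calibrate \
    --csv calibration.csv --out model.json
Rscript -e 'quit(status = endohsi::endohsi_cli())' evaluate \
    --confusion table.csv --out metrics.csv
```

## Layout

- `R/` — colorimetry and correction, spectral reconstruction, hypercube +
  NBI, camera/spectrometer simulator, detection evaluation, CLI
- `inst/extdata/` — worked-example confusion matrices (CSV)
- `tests/testthat/` — unit, property and acceptance suites
- `vignettes/rgb-to-hyperspectral.Rmd` — model, assumptions, numerical
  choices, limitations
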