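---
title: "From RGB endoscopy frames to visible-range spectra: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From RGB endoscopy frames to visible-range spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endohsi)
```

## The problem

Clinical narrow-band imaging (NBI) improves the visibility of mucosal
vasculature by illuminating tissue with narrow blue (~415 nm) and green
(~540 nm) bands, but it requires dedicated optics. A snapshot spectral
conversion sidesteps the hardware: a consumer RGB camera is calibrated once
against a 24-patch colour target whose reflectance spectra are known from a
spectrometer, and from then on every RGB frame can be expanded into a
visible-range reflectance estimate per pixel (380-780 nm, 401 bands, the
standard grid in this package) from which NBI-like renderings are computed.
This package implements that conversion pipeline, a fully synthetic
camera/spectrometer simulator to exercise it, and the detection-evaluation
metric layer used to score lesion detectors (squamous cell carcinoma,
dysplasia, normal mucosa) on such imagery.

## The conversion model

The pipeline has three fitted stages.

**1. Camera correction in XYZ.** Stored 8-bit sRGB code values are decoded
with the IEC 61966-2-1 electro-optical transfer function and mapped to CIE
1931 XYZ through the standard sRGB/D65 matrix, on a scale where the
reference white has $Y = 100$. A real camera deviates from this ideal path
(nonlinear response, dark current, imperfect colour filters), so the
camera-side XYZ is corrected by a polynomial model fitted on the target
patches by Moore-Penrose pseudoinverse:

$$C = XYZ_{\mathrm{Spectrum}} \cdot \mathrm{pinv}(V), \qquad
  XYZ_{\mathrm{Correct}} = C \, V,$$

where each column of the variable matrix $V$ holds the monomial expansion
of one patch's camera XYZ and $XYZ_{\mathrm{Spectrum}}$ holds the
spectrometer-derived references. The default term set (`poly3`) is the 20
monomials of $X, Y, Z$ up to total degree 3 with all cross terms; 20 terms
against 24 patches keeps the least-squares problem over-determined.

**2. Spectral basis.** The 24 measured reflectance spectra are reduced by
mean-centred PCA. Six components suffice for chart-like reflectance sets
(the package's acceptance bound is a cumulative explained variance of at
least 99.64%), because printed-pigment reflectances are smooth and
effectively low-dimensional -- the empirical fact underlying all
tristimulus-to-spectrum recovery.

**3. Score regression.** The component scores are regressed on the same
polynomial expansion of the *corrected* XYZ, again via pseudoinverse.
Reconstruction is then

$$S = \bar{s} + E\,(M\,V_{\mathrm{Color}}),$$

with $\bar s$ the mean spectrum, $E$ the loadings and $M$ the regression
matrix; the product $E M$ is the combined colour-to-spectrum transform.
Outputs are clamped to the physical 0-100% reflectance range (with a
warning).

Quality is reported as (a) mean per-patch XYZ RMSE between corrected camera
values and spectrometer references, (b) mean per-patch spectral RMSE in
percent reflectance, and (c) mean CIEDE2000 between Lab coordinates derived
from the analog and the measured spectra.

```{r calibrate}
ps <- build_calibration_fixture(seed = 42)
model <- calibrate_patch_set(ps, term_spec = "poly3", n_pc = 6)
model
```

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `term_spec` | `"poly3"` (20 terms) | monomial set for both fits; `affine` (4) and `poly2` (10) available for small patch counts |
| `n_pc` | 6 | retained principal components |
| `feature_scale` | 100 | XYZ divisor before monomial expansion (see numerics) |
| NBI `centers` | 415, 540 nm | narrow-band filter centres |
| NBI `fwhm` | 30 nm | Gaussian filter width, characteristic of clinical narrow-band filters |
| `iou_threshold` | 0.5 | box-match threshold in the evaluation layer |

## The synthetic world, and what a green test establishes

No instrument data ships with the package; the simulator supplies a stated,
fixed world instead:

* **Observer.** The CIE 1931 2° colour-matching functions are realised by
  the Wyman-Sloan-Shirley piecewise-Gaussian approximation (maximum
  deviation from the tabulated observer below 0.02, clamped nonnegative),
  avoiding any bundled data table.
* **Illuminant.** Equal-energy by default -- the endoscope light source is
  unspecified in practice -- with an analytic daylight-like alternative
  (Planckian radiator at 6504 K).
* **Colour target.** `generate_reflectances()` emulates a Macbeth-style
  chart: six achromatic gray-ramp patches (graded levels 3.1-88% with a
  slight random spectral tilt) plus chromatic patches made of a baseline and
  2-4 broad Gaussian pigment lobes (one dominant, FWHM 250-450 nm, centres
  410-690 nm), rescaled smoothly if they would exceed 95% reflectance.
  The gray ramp and the broad dominant-lobe structure are the two features
  that give real charts their steep PCA spectrum; without them (narrow or
  independent lobes) the spectra family contains tristimulus-invisible
  ("metameric") variance that *no* three-channel method can recover, and
  the published error bounds are unreachable in principle.
* **Camera.** The defect model applies, in linear RGB: an exposure gain
  (defaulting to `auto`, which places the illuminant white at 95% of
  clipping, as exposure control would), 5% symmetric channel crosstalk, a
  0.02 dark offset, optional Gaussian noise (off for patch averages, which
  are measured regions, not single pixels), and a gamma-2.2 encode where
  the pipeline will assume sRGB -- a realistic encoding mismatch. All
  randomness flows through explicit seeds.

A green calibration test therefore establishes that the fitting machinery
recovers spectra under *systematic* camera defects on a *chart-like*
reflectance family. It does not establish performance on tissue (whose
reflectances are not in the chart family), on scenes with specular
highlights or saturated pixels, or under photon noise; and the simulator
is not a radiometric tissue model.

## Numerical choices

* **Conditioning of the polynomial fit.** Monomials of XYZ values up to 100
  reach $10^6$, which destroys the pseudoinverse's effective rank. Features
  are therefore expanded on white-normalised XYZ (divided by
  `feature_scale = 100`); the scale is stored in the model, so the fitted
  map is unchanged. Even so the 20-term basis on 24 points has condition
  number around $10^7$: individual coefficients are not identifiable, the
  least-squares *fit* is. Tests compare fitted values against an
  independent pivoted-QR solve; plain normal equations (which square the
  conditioning) are used as oracle only on well-conditioned random
  instances.
* **Pseudoinverse tolerance.** Singular values below
  $\max(\mathrm{dim}) \cdot \varepsilon \cdot \sigma_{\max}$ are dropped;
  rank deficiency from too few patches raises an error rather than being
  silently regularised.
* **Sign convention.** Each PCA loading is flipped so its largest-magnitude
  element is positive, making serialized models byte-reproducible.
* **Lab conversion.** The companding function uses the classic printed
  constants (threshold 0.008856, linear branch $7.787n + 0.137931$)
  verbatim; the two branches agree at the threshold within $10^{-3}$, which
  is the accepted discontinuity of that historical formulation.
* **Cube storage.** Cubes are held at 32-bit float precision from
  construction (the ENVI on-disk type), so write/read round trips are
  bit-exact in both supported formats.
* **Degenerate inputs.** Negative corrected XYZ and out-of-range
  reflectance are clamped with warnings; zero metric denominators yield
  `NA` ("undefined"), never 0.

## Design decisions where the method was open

* **Wavelength grid.** 380-780 nm at 1 nm (401 bands) everywhere. Published
  descriptions of such pipelines sometimes quote a 300-700 nm output range
  for the reconstruction; the operational 401-band statement wins, and one
  grid is used consistently.
* **Reflectance units.** Percent (0-100); the spectral-RMSE bound of 0.75
  is read on that scale (sub-percent mean error).
* **Gamma dialect.** The decode path uses the piecewise sRGB curve, not a
  pure power law, because the stored files are declared sRGB. What the
  *camera* does is part of the distortion model.
* **Regression target.** Component scores, not raw spectra: with the
  pseudoinverse this is equivalent in fitted values to regressing the
  spectra and projecting, but it matches the basis-times-regression
  factorisation and serializes compactly.
* **NBI display mapping.** 540 nm feeds the red display channel, 415 nm
  feeds green and blue -- the convention that renders superficial
  vasculature reddish-brown on NBI monitors; configurable.
* **Detector-input rendering.** How a 401-band cube is collapsed to three
  detector channels is not standardised; two explicit modes are provided
  (`bands-415-540-700` and `pc-composite`), neither claimed canonical.
* **Accuracy denominator.** Overall detection accuracy divides the sum of
  correctly matched real-class boxes by the number of real-class ground
  truths, *excluding* background ground-truth counts. This is the only
  convention under which the published worked-example tables are internally
  consistent, and the package's recomputation confirms every sensitivity,
  precision, F1 and accuracy entry at two decimals.
* **Specificity and kappa.** One-vs-rest specificity over the full
  background-augmented table and Cohen's kappa on the full table are
  reported. For the worked-example tables these standard definitions give
  values about 0.01-0.02 away from the printed specificity/kappa columns
  (e.g. kappa 0.61 vs printed 0.62 on the first table); no standard
  convention reproduces those two columns, so the package documents the
  mismatch rather than reverse-fitting a nonstandard definition.

## Worked evaluation example

The four published confusion matrices ship as CSV fixtures and reproduce
the published metric table:

```{r evaluate}
cm <- read_confusion_csv(system.file("extdata", "confusion_rgb_wli.csv",
                                     package = "endohsi"))
met <- metrics_from_confusion(cm)
round(met$accuracy, 4)
met$per_class
```

## Known limitations

* Tristimulus input fundamentally limits recovery to the ~3 effective
  degrees of freedom visible to the observer functions; spectra outside the
  calibration family (fluorescence, narrow spectral features, energy beyond
  ~700 nm where the observer is blind) are not recoverable.
* The correction model interpolates the training gamut; colours far outside
  it (saturated pixels especially) extrapolate poorly.
* The evaluation layer scores detector *outputs*; it neither trains nor
  runs a detector, and average precision requires confidences, which
  published tables usually omit.
* Chromatic adaptation between illuminants, ICC profiles and RAW decoding
  are out of scope: the camera is assumed sRGB-declared.
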