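# astaxmap

Quantification of the carotenoid pigment **astaxanthin** (µg per g fish) in
salmonid fillets from 19-band multispectral reflectance images.

Astaxanthin gives rainbow trout and salmon flesh its red colour; its
concentration is a commercially graded quality trait that is normally
measured destructively by chemical extraction. Because the pigment absorbs
strongly between roughly 400 and 600 nm while flesh reflects freely in the
red and near infrared, a narrow-band multispectral image carries enough
information to calibrate a regression from image spectra to chemical
concentration — and, once calibrated, to map the pigment pixel by pixel
across a fillet. This package implements that pipeline end to end, together
with a synthetic fillet **phantom generator** with known ground truth, so
every stage can be validated without access to an imaging instrument.

## The pipeline

For each fillet image (an H×W×19 reflectance cube on bands 395–970 nm):

1. **Segmentation** — a maximum noise fraction (MNF) transform orders linear
   band combinations by signal-to-noise, solving Σ_N v = λ Σ v where Σ_N is
   a noise covariance estimated from half-differences of adjacent pixels.
   Otsu's threshold on the leading component separates fillet from
   background; a canonical discriminant (Fisher) variate trained on seed
   regions removes fat/collagen, leaving the region of interest (ROI).
2. **Extraction** — each cube contributes one mean ROI spectrum **x** ∈ R¹⁹.
3. **Calibration** — spectra are autoscaled (per-band standardization),
   then a NIPALS partial least squares regression (PLSR) is fitted against
   chemically determined concentrations; the number of latent components A
   is chosen by leave-one-out cross-validation (minimum RMSECV). Candidate
   outliers are screened beforehand with Hotelling's T² on PCA scores.
4. **Colour baseline** — the same cubes are reduced to sRGB images
   (monotone-cubic spectral reconstruction at 5 nm → CIE 1931 2° observer →
   sRGB), and a 3-variable model on mean R, G, B provides the comparison
   that motivates multispectral imaging.
5. **Mapping** — the fitted regression vector is applied to every ROI pixel
   to produce a concentration map, rendered with a blue→red ramp.

The phantom generator renders elliptical fillets with Beer–Lambert
attenuation, `R(λ) = flesh(λ) · 10^(−c · ε(λ))`, fat stripes, smooth
concentration gradients, per-sample brightness and heme-like interference,
and reference concentrations drawn from a truncated normal calibrated so the
cohort reproduces the reference-data moments (mean 1.69, SD 0.95, range
0.20–4.34 µg/g over 59 samples).

## Worked example

```r
library(astaxmap)
report <- run_experiment(experiment_config(seed = 1))
print(report)
```

```
<experiment_report>
  cohort: n = 59, mean 1.70, sd 0.87, range [0.26, 4.07] ug/g
  outliers removed from training: 0
  multispectral: A = 4, RMSEP = 0.043, r2 = 0.997
  sRGB baseline: A = 2, RMSEP = 0.080, r2 = 0.991
```

This simulates a 59-fillet cohort (20 training / 39 validation), runs
segmentation, extraction and both calibrations, and validates on the held
out set. The 19-band model predicts the test concentrations with an RMSEP of
0.043 µg/g (r² = 0.997) using 4 latent components; collapsing the same cubes
to three sRGB means nearly doubles the error (0.080 µg/g) — the ordering
that justifies multispectral over conventional colour imaging. A pixel-wise
map for any cube follows with:

```r
sample1 <- report$cohort_data$samples[[1]]
map <- predict_map(sample1$cube, sample1$masks$roi,
                   report$models$multispectral)
write_map(map, "sample1_map.tif", png_path = "sample1_map.png")
```

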