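---
title: "Multispectral calibration of astaxanthin concentration: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multispectral calibration of astaxanthin concentration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astaxmap)
```

## The problem

Astaxanthin is the carotenoid responsible for the red colour of salmonid
flesh. Its concentration (µg per g fish) is a graded quality trait, normally
determined by destructive chemical extraction on duplicate subsamples.
Because the pigment absorbs strongly over roughly 400–600 nm and flesh
reflectance rises steadily toward the near infrared, a 19-band reflectance
image (395–970 nm) of a fillet carries a quantitative pigment signal.
`astaxmap` implements the full analysis: segment the fillet, reduce each
image to one mean spectrum, calibrate a latent-variable regression against
chemical reference values, compare against an sRGB colour baseline, and map
concentration pixel by pixel. Since no public image set accompanies this
problem, the package ships a first-class synthetic phantom generator with
known ground truth; every claim the package makes about itself is tested on
those phantoms.

## The forward model behind the phantoms

A phantom is an elliptical "fillet" on a darker background, crossed by
bright fat stripes (myocommata-like), imaged on the default 19-band layout.
Flesh pixels follow Beer–Lambert attenuation of a pigment-free flesh
spectrum:

$$R(\lambda) \;=\; s \cdot \mathrm{flesh}(\lambda)\cdot
  10^{-\,c\,\varepsilon(\lambda)\; -\; \nu\,\varepsilon_h(\lambda)}
  \;+\; \mathcal{N}(0, \sigma^2)$$

* $\mathrm{flesh}(\lambda)$ rises sigmoidally from ≈0.30 in the violet to
  ≈0.75 in the NIR, reproducing the monotone brightening of fillet images
  with wavelength.
* $\varepsilon(\lambda)$, the decadic absorptivity of astaxanthin per
  (µg/g), is a Gaussian band centred at 500 nm (σ = 55 nm, peak 0.12),
  giving strong absorption through the blue–green and essentially none in
  the red/NIR — the behaviour that makes the pigment look dark red/purple.
* $\varepsilon_h(\lambda)$ is a heme-like nuisance absorber (centre 545 nm,
  σ = 30 nm, peak 0.05) with a random per-sample level $\nu$, standing in
  for residual blood/myoglobin. Real cohorts contain such interfering
  chromophores; without one, three colour variables would suffice to invert
  a single-pigment model and the multispectral-vs-RGB comparison would be
  vacuous.
* $s$ is a per-sample brightness factor (log-normal, ≈4 % SD), the
  fillet-to-fillet lightness variation any reflectance instrument sees.
* Additive i.i.d. Gaussian noise (default σ = 0.01 reflectance) is applied
  per pixel and band, clipped to [0, 1.2].

Fat pixels take a bright flat spectrum (0.85), maximally separated from
flesh below 570 nm; the background is a mid-grey with a mild downward
slope. A smooth multiplicative concentration field (linear gradient,
normalized to mean 1 over the fillet) lets phantoms carry spatial pigment
structure for map validation.

What the phantoms do **not** emulate: optical scattering (Kubelka–Munk),
illumination non-uniformity, specular highlights, petri-dish rims, and
instrument-specific stray light. Tests passing on phantoms therefore
demonstrate correctness of the algorithms under the stated forward model,
not instrument-level performance on real fillets.

## The reference-concentration distribution

Reference data for this problem are characterized by four numbers: range
0.20–4.34 µg/g, mean 1.69, SD 0.95, over 59 samples. We model
concentrations as a **truncated normal** on [0.20, 4.34] — the simplest
two-parameter family consistent with a bounded, unimodal histogram.

One subtlety matters: reported sample moments are moments of the *observed*
(bounded) data, i.e. of the truncated distribution. Truncating
N(1.69, 0.95²) to [0.20, 4.34] would yield realized moments of about
1.80/0.83 — the wrong cohort. `cohort_spec()` therefore calibrates the
parent parameters numerically (`match_truncated_normal()`, giving
µ ≈ 1.176, σ ≈ 1.370) so that the truncated distribution itself has mean
1.69 and SD 0.95. The literal parameterization remains available via
`moment_match = FALSE`. Sampling is by inverse-CDF transform, so draws
respect the bounds exactly and are reproducible under a seed.

Chemical duplicates are emulated by adding N(0, 0.02²) measurement error to
each replicate; the working concentration is the replicate mean, as in
duplicate chemical determination.

## Segmentation

* **MNF.** The maximum noise fraction transform solves
  $\Sigma_N v = \lambda\, \Sigma v$ with $\Sigma_N = \mathrm{cov}(\Delta)/2$
  estimated from horizontally adjacent pixel differences and $\Sigma$ the
  total covariance; components are ordered by increasing noise fraction
  $\lambda$. Under shift-difference noise estimation this coincides with
  maximum autocorrelation factors, so a single implementation is provided
  (offset configurable, default 1 pixel horizontal). The leading component
  is the smoothest contrast in the image — on fillet images, fillet vs
  background.
* **Otsu.** Thresholds maximize between-class variance over a 256-bin
  histogram, exhaustively, ties toward the lower cut. The background side
  is chosen by border-pixel majority; the largest connected component is
  kept and holes filled (robustness post-processing). If the leading MNF
  noise fraction exceeds 0.5 the image has no coherent structure and
  segmentation errors out rather than thresholding noise.
* **CDA.** Fat removal trains a Fisher canonical variate
  ($S_B v = \lambda S_W v$) on meat/fat seed pixels — on phantoms the
  ground-truth masks, on real images user-supplied seed regions — and
  thresholds it within the fillet. Fat removal is optional
  (`fat_removal = FALSE`) since real pipelines may lack seed labels.

Numerical choices: generalized eigenproblems are solved by Cholesky
whitening; a ridge of $10^{-8}\,\mathrm{tr}(B)/p$ is added only when the
covariance is not positive definite (with a warning). Component vectors are
unit-norm with the largest-magnitude entry made positive.

## Calibration

Spectra are autoscaled (subtract per-band mean, divide by per-band sample
SD, n−1 denominator throughout). PLSR uses NIPALS with X-deflation and a
univariate response; the regression vector is
$b = W (P^\top W)^{-1} q$, and predictions are reproducible from $b$ alone.
The component count A is chosen by leave-one-out cross-validation with
**autoscaling refitted inside every fold** — the unbiased choice, avoiding
test-into-train leakage — at the minimum RMSECV (smallest A on ties);
A_max defaults to 10. Validation reports RMSEP, r² = 1 − SS_res/SS_tot, and
the standard error of the fit, defined here as sd(residuals)/√n.

Outlier screening automates what is usually a visual score-plot check:
Hotelling's T² on the first two PCA scores of the autoscaled training
spectra, flagged above the F-quantile at α = 0.975. Flagged samples are
removed from the training pool only; the validation set is left untouched so
reported errors are not survivorship-biased. All thresholds are
configurable.

## Colour baseline

The 12 visible bands (395–700 nm) are interpolated to the 5 nm colorimetric
grid 380–780 nm by monotone piecewise-cubic (Fritsch–Carlson) interpolation
— vectorized across pixels, and equal to `stats::splinefun(method =
"monoH.FC")` per spectrum — with constant extrapolation beyond the band
range and clipping at zero. Monotone interpolation was chosen as the
reconstruction operator because it cannot overshoot into negative
reflectance and adds no oscillation between bands.

XYZ integration uses the CIE 1931 2° observer with a D65 illuminant and the
normalization $k = 100/\sum S\,\bar y$, so a perfect diffuser has Y = 100
exactly. The colour-matching functions are generated from the published
multi-lobe Gaussian analytic fit (Wyman, Sloan & Shirley 2013, accurate to
about 1 %); D65 is tabulated at 20 nm and linearly interpolated, which is
immaterial for smooth reflectances. Rendering anchors the white point: XYZ
is rescaled per channel so the table's computed illuminant white maps to
the nominal D65 white before the standard sRGB matrix and gamma. This keeps
the diffuser → white and zero → black identities exact regardless of the
~1 % CMF approximation. The 3-variable baseline model uses mean 8-bit R, G,
B over the ROI.

## Pixel-wise mapping

Every ROI pixel spectrum is autoscaled with the *training* parameters and
projected through $b$. Because autoscaling, the mean-spectrum extraction
and the regression vector are all affine, the ROI mean of the map equals
the scalar prediction of the ROI mean spectrum — an identity the tests
verify to 1e−8 on every phantom. Maps are NA outside the ROI, rendered on a
blue→red ramp over [0, 4.5] µg/g (the reference concentration span), and
stored as a scaled 32-bit float TIFF with a JSON sidecar (float TIFF pages
carry values in [0, 1] only, hence the stored scale/offset).

## The experiment driver and problem sizes

`run_experiment()` chains the whole study from one validated config:
cohort → segmentation → extraction → outlier screening → LOOCV → both
calibrations → validation. Defaults mirror the study design (59 samples,
20/39 split, A_max 10). Phantoms default to 60×80 pixels — large enough
that ROI averaging reduces pixel noise well below the chemical replicate
error while keeping a full 59-sample experiment around a few seconds, which
is also the scale the test suite runs at. With the default seed the
experiment reaches a multispectral RMSEP of 0.043 µg/g (r² 0.997) against
0.080 µg/g for the sRGB baseline; the ordering — multispectral strictly
better than colour — is the study's qualitative conclusion and is asserted
in the acceptance tests. The absolute errors are smaller than those
attainable on real fillets, as phantoms lack the biological and
instrumental variation listed above.

## Known limitations

* The Beer–Lambert link is an idealization; real fillet reflectance mixes
  absorption with scattering, so absolute phantom errors understate
  real-data errors.
* The concentration histogram is matched only in range/mean/SD; any
  skewness of real cohorts is not reproduced.
* CDA seed regions must be supplied for real images; the package does not
  learn them.
* Pixel-level map accuracy is validated only against the synthetic ground
  truth — chemical micro-sampling validation is out of scope.
* The spectral reconstruction is an interpolation, not a learned basis; it
  is exact at band centres but unconstrained between bands beyond
  monotonicity.
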