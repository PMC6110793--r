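---
title: "Spectral taxonomy of benthic megafauna: methods and design"
author: "benthospec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral taxonomy of benthic megafauna: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benthospec)
```

## The problem and the data

A push-broom underwater hyperspectral imager (UHI) mounted on an ROV
records, line by line, a full spectrum for every ~1 mm seafloor pixel —
on the emulated instrument, 112 bands spanning roughly 378–805 nm. Benthic
megafauna (sponges, corals, holothurians, ophiuroids, crustaceans, ...)
and sediment anomalies reflect light in category-specific ways, so a pixel
spectrum acts as an *optical fingerprint* that can identify an organism
without physical sampling. The workflow this package implements has four
scientific stages: normalising raw intensities to pseudo-reflectance,
building a reference library of fingerprints from identified objects,
assigning unknown objects by spectral similarity, and classifying every
pixel with a supervised model to find objects the human annotator missed.

## Pseudo-reflectance, not reflectance

True reflectance requires knowing the illumination spectrum at each pixel
and the optical properties of the intervening water. Neither is available
in a deep-sea deployment, so the package follows the standard
approximation: divide each pixel spectrum by a *reference spectrum*
estimated from the image itself.

Two estimators are provided (`computeReference()`):

* `column_mean` (default): one reference per cross-track sample, the mean
  over all along-track lines of that column. Because the lamp array is
  rigidly mounted, its geometric falloff is static per column, and this
  estimator removes a purely multiplicative cross-track field exactly (a
  property the test suite checks). It is biased in columns where
  non-background objects occupy a noticeable share of the track — the
  residual our validation quantifies.
* `global_mean`: a single whole-cube mean spectrum; exact when the field
  is flat, and the right choice for the noiseless identifiability check
  below.

The quotient is deliberately labelled *pseudo*-reflectance throughout:
residual illumination and water-column effects remain, which is also why
chlorophyll-a concentration indices are out of scope.

The full chain (`preprocessCube()`) is **subset → divide → smooth**:

* **Spectral subsetting** to 400–710 nm, *inclusive* on both ends —
  "between 400 and 710 nm" names band limits, not an open interval. On
  the default grid this keeps exactly 83 of the 112 bands. The margins
  are dropped because the detector is noisy there (the simulator inflates
  marginal noise five-fold for the same reason).
* **Moving-average smoothing** over 11 bands (~44 nm at ~4 nm spacing),
  applied per pixel along the band axis. Edge handling is unspecified in
  the field literature; the default here is symmetric (`reflect`)
  padding, chosen so the band count is preserved — the 83-band grid stays
  83 bands — with a `shrink` mode (window shrinks at the spectrum ends)
  as the alternative. A centred symmetric window leaves affine spectra
  unchanged in the interior, which the suite uses as an analytic oracle.

## Spectral contrast angle

Similarity between two spectra $a$ and $b$ is the angle

$$\cos\theta = \frac{\sum_i a_i b_i}{\sqrt{\sum_i a_i^2 \sum_i b_i^2}}$$

reported in degrees. $\theta = 0°$ means identical shape; nonnegative
spectra are confined to $[0°, 90°]$; intensity scaling of either spectrum
changes nothing. Numerical choices: the cosine is clamped to $[-1, 1]$
before the arccosine (rounding can push it marginally outside), zero-norm
inputs are errors rather than NaNs, and angles are kept at full floating
precision internally — two-decimal rounding happens only in reports.
`matchToLibrary()` assigns a query to the category of the smallest-angle
entry; ties below $10^{-9}$ degrees go to the earliest library entry,
with a warning, so results are deterministic and auditable. Both sides
are max-normalised before matching for presentation consistency; by scale
invariance this cannot change an assignment. An optional `thetaMax`
threshold yields `"unassigned"` instead of a forced nearest match; the
default is no rejection, mirroring the workflow's always-assign
behaviour.

## Reference libraries

`extractROISpectrum()` averages the smoothed pseudo-reflectance over an
annotated region (mean first, then max-normalisation — the unnormalised
mean is retained because anomaly categories differ partly in absolute
intensity). Typical object surfaces span 20–600 pixels; sizes outside
that range warn rather than fail, since tiny masks average little noise
and huge ones mix surface variation. Whether averaging should precede or
follow per-pixel normalisation is genuinely open; mean-then-normalise was
chosen and is stated here rather than hidden.

## Supervised classification

The per-pixel classifier is a one-vs-one multi-class SVM with an RBF
kernel (`e1071`/libsvm), with $\gamma = 1/n_\text{bands}$ and $C = 100$ —
the documented defaults of the commercial package this workflow is
usually run in, exposed as arguments. Features are raw (unscaled)
pseudo-reflectance values, so brightness differences between categories
are informative, not normalised away.

Two training modes exist because the field procedure is ambiguous:

* `avg_spectra` — one sample per object (its mean spectrum), reproducing
  the one-spectrum-per-OOI protocol verbatim;
* `roi_pixels` (default) — one sample per ROI pixel, because a few dozen
  single spectra across ~19 categories is statistically thin. Pixels per
  ROI are capped (default 150) by deterministic even subsampling; this
  bounds the support-vector count, and hence whole-cube prediction cost,
  without measurably affecting the separable synthetic classes.

Background matters: sediment and manganese nodule are first-class
categories (objects of interest are *anomalies against* that background),
and training without them triggers an explicit degraded-mode warning.
Training is order-insensitive — samples are sorted into a canonical order
before fitting, so permuting ROIs cannot change predictions — and
identical spectra under different labels abort with the colliding object
ids listed.

## From pixels to objects

`detectOOIs()` masks out background pixels and groups the rest into
connected components *across categories jointly* (8-connectivity by
default): an organism whose rim pixels were misassigned to a similar
category should remain one object, labelled by majority vote (ties go
alphabetically, with a warning; purity records the majority fraction).
Components under `minSizePx` (default 20 px = 2 cm² at 1 mm pixels —
below the smallest organisms of interest, above single-pixel noise) are
discarded but accounted for: detected + background + filtered pixels must
equal the frame, an invariant the suite asserts on every run. Densities
are `count / area` with the survey area from
`computeSurveyedArea()` (Σ lines × samples × pixel area); full precision
is kept internally and the conventional two decimals appear only in
reports. No splitting heuristic for touching organisms is implemented;
low purity is the diagnostic flag.

## The synthetic scene generator

`generateScene()` inverts the correction chain the pipeline applies:

$$\text{pixel}(\lambda) = R_\text{material}(\lambda) \cdot
  I(\text{line}, \text{sample}) \cdot L(\lambda) + \varepsilon$$

with $R$ the category's true reflectance, $I$ a multiplicative
illumination field (cross-track cosine falloff to 0.6 at the swath edge,
static per column, times a ±5% along-track sinusoidal gain drift), $L$ a
smooth lamp spectrum, and $\varepsilon$ Gaussian noise with standard
deviation 1% of signal, inflated ×5 outside 400–710 nm (values are
clamped at zero, preserving the nonnegativity the container requires).
Because the cross-track profile is static per column, the default
column-mean reference correction is exact in expectation — a deliberate
simplification mirroring the approximation the correction itself makes.

Materials are smooth baselines plus one to three positive Gaussian
features: bright rising sediment, dark nodules, and category-specific
fauna fingerprints whose pairwise contrast angles are at least 5° on both
the full and subsetted grids (enforced at build time, over the fauna
categories). The green/white anomaly spots are sediment carved by a
chlorophyll-a-like absorption dip at 675 nm ($\sigma$ = 8 nm; depth 0.5
for green, 0.35 for white, white additionally brightened ×1.15 above
650 nm). These dip parameters are invented phenomenology describing the
qualitative shape of such anomalies — configuration values, not claims
about pigments — and they pin the spot spectra's mutual similarity
(~4.5°), so the spot pair and the backgrounds are exempt from the strict
5° check; they are deliberately the hard case for the classifier, and
green↔white confusion is the expected failure mode.

Scene defaults define the standard study conditions: 300 × 400 px at
1 mm, the 112-band grid, six planted categories × 5 objects, 40
background nodules. The instrument's stated band configuration (112 bands,
378–805 nm, 4 nm resolution) is not arithmetically self-consistent, so
the default grid uses 3.75 nm spacing from 378 nm — chosen so inclusive
[400, 710] subsetting keeps exactly 83 bands, matching the processed band
counts; the true grid is configurable when known. Fauna discs default to
1.5–6 cm diameter (field surveys report roughly 2–15 cm bodies plus
sub-cm detections; many 15 cm bodies cannot fit a 30 × 40 cm scene) and
spots to 0.8–2 cm, respecting their reported 2 cm maximum. Objects are
placed largest-first by rejection sampling with a 1 cm clear-sediment
margin around fauna/anomalies (2 px around nodules): distinct organisms
are rendered as separate bodies, so components correspond one-to-one to
planted objects. All placement and noise flows from the single scene
seed; the same seed reproduces the cube bit for bit.

**What the simulator does not emulate** — and therefore what passing
tests do not show about real data: mixed (sub-pixel) boundary spectra,
within-category spectral variability beyond noise, organism morphology
beyond discs, water-column inherent optical properties, vehicle motion
artefacts, and radiometric calibration (replaced by the smooth lamp
model). Synthetic accuracy is an upper bound on field accuracy.

## Validation protocol and problem sizes

`syntheticBenchmark()` is the standard end-to-end check: five seeded
300 × 400 × 112 scenes with default noise and illumination; training ROIs
from half the planted objects per category plus background patches (24
sediment squares of 10 × 10 px spread across the swath, and the five
largest nodules — spreading matters, because it samples the range of
column-mean reference conditions); SVM training and whole-cube
classification; detection; then two scores against ground truth: the
fraction of pixels with the correct category, and the fraction of planted
objects overlapped by a detected component of the correct majority label.
The acceptance thresholds are 90% for both, the pixel bar matching the
overall SVM accuracy reported for field data of this kind. A separate
noiseless, flat-illumination scene (where the global-mean reference is
exact and same-category spectra are identical by construction) checks
*identifiability*: angle matching must recover every held-out object's
category with $\theta_{\min} < 1°$.

These sizes — 120 000 pixels × 83 bands per scene, five scenes — were
chosen as the smallest configuration that exercises every pipeline stage
at realistic density; the unit suite uses far smaller fixtures with
analytically forced expectations (impulse and ramp smoothing, elementwise
mean oracles, brute-force flood fill, exhaustive pairwise angle
enumeration).

## Known limitations

* Pseudo-reflectance is reference-dependent: columns dominated by bright
  or dark objects bias the column-mean estimator, and the resulting
  halo misclassifications around large objects are visible in the
  synthetic confusions too.
* The SVM gives no calibrated probabilities and no reject option; an
  out-of-library organism will be forced into the nearest category
  (angle matching at least exposes `thetaMax` for rejection).
* Touching organisms merge into one detected object by design; purity is
  the only flag.
* The ENVI-style reader targets the common header dialect; it is not a
  validated parser for any specific archive's deposit.
* Green vs white spot discrimination rests on small intensity and dip
  differences; with realistic noise, occasional confusion between the two
  spot classes is expected and observed.
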