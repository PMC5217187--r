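---
title: "Automated rCBV quantification from DSC-MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated rCBV quantification from DSC-MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dscquant)
```

## The problem

Dynamic susceptibility contrast (DSC) MRI images the first pass of a
gadolinium bolus through the brain with a rapid T2*-weighted sequence.
The transient susceptibility-induced signal drop in each voxel encodes
the local contrast concentration, and the time integral of the
concentration curve over the first pass is proportional to cerebral
blood volume (CBV). In neuro-oncology the clinically used quantity is
*relative* CBV (rCBV): the CBV map divided by the mean CBV of
normal-appearing white matter (WM). Normalizing to contralateral WM and
skipping arterial-input-function deconvolution is favored for
repeatability, but it moves the methodological burden onto steps that
are often manual and operator-dependent: locating the bolus, correcting
for contrast leakage through a disrupted blood–brain barrier, and
choosing the WM reference region. `dscquant` automates all three and
adds the agreement statistics used to compare rCBV estimates between
tools.

`dsc_quantify()` is the single entry point; it returns a classed result
with `print`, `summary` and `plot` methods. Every stage is also exposed
as its own function so each step can be tested, replaced, or run in
isolation.

## Signal model

With baseline signal $S_{base}$ (the per-voxel mean over the pre-bolus
window) and echo time $TE$, the concentration-time curve is

$$\Delta R_2^*(t) = -\frac{1}{TE}\,\ln\!\frac{S(t)}{S_{base}},$$

computed per voxel. $TE$ is carried in milliseconds, so $\Delta R_2^*$
is in 1/ms; since rCBV is a ratio, the unit cancels and only relative
values matter. The transform is exactly invertible, which the tests
exploit: on noiseless phantoms the reconstruction
$S_{base}e^{-TE\,\Delta R_2^*}$ must reproduce the signal to machine
precision. Negative $\Delta R_2^*$ (signal above baseline, the
T1-driven leakage overshoot) is deliberately retained — the leakage
model needs that lobe — and the baseline estimator is the plain mean
over the window, not a robust variant. Voxels whose signal touches zero
cannot be log-transformed and are excluded from the mask rather than
imputed.

## Bolus detection

The first 3 frames of the series are discarded (steady-state saturation;
`saturation_frames` parameter). Detection then runs on the brain-average
signal curve:

1. a continuous wavelet transform with the Ricker (Mexican-hat) wavelet
   over integer scales 1–12 frames;
2. per-scale maxima/minima of the coefficients, linked across adjacent
   scales into ridges when positions agree within ±2 samples;
3. ridges persisting over at least 3 scales are retained; the trough is
   the smallest-scale position of the strongest minimum ridge (largest
   summed |coefficient|, ties to the earlier position).

The wavelet is not dictated by the problem; the Ricker wavelet is the
standard choice for dip/peak localization and its two vanishing moments
make constant and linear trends (and hence any affine rescaling of the
curve) invisible to the transform, which is the basis of the
scale/offset-invariance property tests. The scale range 1–12 frames
covers first-pass widths of roughly 5–15 frames at ~2 s frame spacing.
Coefficients are computed with reflection padding, extrema within one
scale of the curve ends are ignored (padding artifacts), and ridges
whose peak coefficient is below $10^{-8}$ of the curve range are
treated as numerical noise — this is what makes a pure ramp yield *no*
minima ridges rather than boundary artifacts.

Entrance and exit are the local maxima of the 3-frame moving-average
smoothed curve nearest the trough on either side. A flat pre-bolus
plateau or a monotone post-bolus recovery offers no strict local
maximum; in that case the *plateau end* is used: the last (first) frame
whose smoothed value is within 5% of the pre- (post-) trough extreme,
measured relative to the trough depth. When both a strict maximum and a
plateau point exist, the one closer to the trough wins. The baseline
window is frame 1 through entrance − 1 and must be at least 3 frames.

Because a tumor bolus can be delayed or dispersed relative to the brain
average, integration bounds are recalculated per voxel: the integer lag
in ±3 frames that maximizes the correlation between the voxel's
concentration curve and the brain-mean concentration curve over the
bolus window shifts both bounds. A voxel falls back to the global
bounds when it has no usable local structure — bolus-window peak below
3 baseline SDs above its baseline mean, or best correlation under 0.5.
A lag-based search was chosen over re-detecting extrema per voxel
because it degrades gracefully with noise and is exactly the identity
on a voxel that matches the global curve.

When no brain mask is supplied, one is derived by Otsu thresholding of
the temporal-mean volume and keeping the largest 6-connected component.

## Leakage correction and CBV integration

Blood–brain-barrier disruption adds T1- and T2*-weighted extravasation
effects to tumor curves. The correction is the reference-curve linear
model: with $\bar c(t)$ the mean $\Delta R_2^*$ curve over
*non-enhancing* voxels,

$$\Delta R_2^{*,vox}(t) \approx K_1\,\bar c(t) -
  K_2 \int_0^t \bar c(t')\,dt',$$

fitted per voxel by ordinary least squares over the frames from the
bolus entrance to the end of the series (pre-bolus frames carry no
information about either coefficient). The corrected curve is
$measured(t) + K_2\int_0^t\bar c$. CBV is the trapezoidal integral of
the corrected curve between entrance and exit at the acquired frame
spacing — no resampling and no gamma-variate fitting of the measured
curve. Negative integrals are retained; clipping would bias downstream
agreement statistics.

Non-enhancing voxels are the brain mask minus the tumor ROI minus
voxels whose post-bolus tail fails to return to baseline: tail mean
$|\Delta R_2^*|$ above twice the voxel's baseline-window SD. The noise
threshold is floored at 5% of the voxel's bolus peak so that on
noiseless data the residual first-pass tail (the gamma-variate never
quite reaches zero) does not disqualify every voxel.

The cumulative integral of the reference uses the same cumulative
trapezoid as the phantom generator's leakage term, so on generatively
leaky phantoms the noiseless $K_1/K_2$ recovery is exact to machine
precision — an intentional sharp oracle rather than a coincidence.
Coefficient standard errors from the OLS fit are stored so recovery can
be assessed in SE units under noise.

## White-matter reference selection

The automatic path clusters in-brain concentration curves and picks the
cluster that a WM probability atlas (supplied pre-aligned to the DSC
grid; registration is established external tooling and out of scope)
identifies as white matter:

* **Features.** Curves truncated at the bolus entrance (pre-bolus
  frames are baseline noise), then projected onto the leading principal
  components capturing 95% of variance. Per-frame standardization
  before PCA was evaluated and rejected: it inflates noise-only tail
  frames to unit variance, the 95% rule then keeps ~20 noise-dominated
  components, and mean shift fragments into hundreds of clusters. On
  raw centered curves the same rule keeps a handful of components that
  carry the tissue contrast.
* **Clustering.** Flat-kernel mean shift: seeds on an axis-aligned grid
  of cell size equal to the bandwidth (one seed per occupied cell),
  iterated to the mean of in-bandwidth points, modes merged within half
  a bandwidth (better-supported mode wins), points assigned to the
  nearest mode. There is no random initialization, so clustering is
  deterministic and invariant to voxel enumeration order. The default
  bandwidth is half the median pairwise distance of an (at most)
  500-point evenly spaced subsample — evenly spaced rather than random
  so the "automatic" path stays parameter- and RNG-free.
* **Gating.** Among voxels with WM probability ≥ 0.95 (inclusive), the
  cluster with the largest *count* of such voxels is selected (ties:
  higher mean probability); the ROI is that cluster intersected with
  the probability gate and minus the tumor ROI. Count was preferred
  over fraction because tiny spurious clusters can have perfect
  fractions.

The manual path takes a drawn label volume, intersects with the brain
mask and removes the tumor ROI. The automatic path does not exclude the
tumor *hemisphere* — only the tumor ROI itself; a hemisphere rule would
need lateralization input the tool does not require.

## Tumor ROI

Given a generous user boundary on the (pre-aligned) post-contrast T1w
image, the Otsu threshold of the intensities inside the boundary
separates enhancing tissue; the largest 6-connected bright component is
the final ROI. Otsu is implemented over 256 equal-width bins spanning
the in-boundary intensity range, maximizing between-class variance with
ties resolved toward the lowest cut; because bins are placed relative
to the range, the partition is invariant under affine intensity
rescaling. A constant in-boundary image is a degenerate histogram and
raises an error.

## rCBV and agreement statistics

rCBV divides the corrected CBV by the mean corrected CBV over the WM
ROI; by construction the WM-ROI mean of rCBV is exactly 1, which is
asserted on every pipeline run. Per-ROI summaries are the mean and the
95th percentile over finite voxels, with linear interpolation between
closest ranks (R quantile type 7); the interpolation rule is recorded
in the output since the 95th percentile reflects few voxels and is
sensitive to it. Negative rCBV voxels are included — any exclusion
would be an undocumented filter.

Agreement between two measurement sets uses Bland–Altman analysis with
limits of agreement at bias ± 2·SD of the paired differences (the 2·SD
convention, not 1.96·SD) and the one-way random-effects intraclass
correlation. The single-measure form ICC(1,1)
$= (MS_B - MS_W)/(MS_B + (k-1)MS_W)$ is the default; the
average-measure form ICC(1,k) is available via `type = "average"`
since reports often leave the form ambiguous. A table with zero total
variance raises an error rather than returning an arbitrary 0 or 1.

## The synthetic phantom

`generate_phantom()` emulates the acquisition the pipeline targets:
40 frames at 2.2 s spacing, TE 60 ms, bolus appearing 25 s after
acquisition start (so the entrance falls at post-discard frame 9 with
an 8-frame baseline window). Geometry is a concentric-block head on a
32×32×8 grid: a GM rim (2 voxels in-plane), WM interior, and a tumor
sphere (~200 voxels), with class CBV ratios WM : GM : tumor = 1 : 2 : 3
and per-class baselines of 300/340/320 signal units over a background
of 5. All classes share one gamma-variate first pass
$c(t) \propto (t-t_0)^{3} e^{-(t-t_0)/3}$ (peak 9 s after arrival),
scaled so its analytic integral equals the class CBV; the default CBV
scale puts peak $\Delta R_2^*$ at ~0.010–0.029 /ms, i.e. 45–80% peak
signal drops at TE 60 ms, which is the clinically typical range. The
default noise SD of 10 gives baseline SNR 30 for WM; SNR 20 (noise SD
15) is used in the detection-robustness tests. Tumor leakage, when
enabled, is generated in concentration space with the same linear
reference-curve model the correction fits, by construction of the
truth maps.

What the phantom does *not* emulate — and what passing tests therefore
do not demonstrate about patient data: anatomy and partial-volume
mixing, motion, recirculation and dispersion differences between
tissues, vendor-specific signal nonlinearity, and leakage kinetics
outside the linear model (a model-mismatch mode is not claimed by the
correction tests). The phantom validates the machinery, not clinical
accuracy.

## Numerical choices and degenerate inputs

* Frame and voxel indices are 1-based throughout (R convention);
  volumes are stored `(t, z, y, x)` internally and reordered exactly
  once at the NIfTI boundary, with a marked-voxel test guarding
  against silent permutation.
* Maps are written as float32 NIfTI-1 with the grid affine; grids must
  match exactly in shape and within $10^{-4}$ mm entrywise in the
  affine — no resampling is attempted.
* Monotone curves, series with the trough at a boundary frame, empty
  masks/ROIs, non-positive baselines, degenerate histograms and
  zero-variance ICC tables all raise stage-named errors rather than
  producing silent values.
* Determinism: no pipeline stage consumes the global RNG (the phantom
  and rater-table generators use an isolated seeded stream), so
  identical inputs give bit-identical outputs.

## Problem sizes in the test suite

The suite runs entirely on generated data: the 32×32×8, 40-frame
phantom (~3500 brain voxels) for end-to-end checks, 100 seeded
replicates at SNR 20 for detection robustness, 500 generatively leaky
voxels for coefficient recovery and correction benefit, and rating
tables of 200–4000 subjects for the ICC estimators. One caveat on the
"within 3 SE" recovery check: 3 SE is a 99.7% event per estimate, so
over 1000 coefficient checks a few exceedances are expected under the
model itself; the assertion is therefore that at least 98.5% of checks
fall within 3 SE, with the noiseless case required to be exact to
$10^{-10}$.

## Limitations

Registration (atlas-to-DSC, T1w-to-DSC) is delegated to external tools;
inputs must share a grid. DICOM input is not supported — NIfTI-1 is the
interchange format. No AIF detection or deconvolution, no percent
signal recovery or mean transit time maps, no preload or dual-echo
leakage modeling, and no confidence intervals on ICC.
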