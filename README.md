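# dscquant

Automated quantification of relative cerebral blood volume (rCBV) from
dynamic susceptibility contrast (DSC) MRI, for neuroimaging researchers
who need reproducible, operator-independent perfusion maps — typically
in brain-tumor studies where rCBV normalized to normal-appearing white
matter is the biomarker of interest.

## What it computes

DSC-MRI tracks the first pass of a gadolinium bolus with rapid
T2\*-weighted imaging. Per voxel, the signal drop is converted to the
change in transverse relaxation rate

$$\Delta R_2^*(t) = -\frac{1}{TE}\,\ln\frac{S(t)}{S_{base}},$$

which is proportional to contrast concentration. CBV is the trapezoidal
integral of the leakage-corrected concentration curve between the bolus
entrance and exit, and rCBV is that map divided by the mean CBV of a
white-matter reference region. The package automates the three steps
that are usually manual:

- **Bolus delineation** — a continuous wavelet transform (Ricker
  wavelet, scales 1–12 frames) of the brain-average signal curve;
  cross-scale ridge linking finds the trough, and the nearest local
  maxima (with a plateau fallback) give entrance and exit. Integration
  bounds are then recalculated per voxel by a bounded lag search on
  each voxel's own concentration curve.
- **Leakage correction** — the reference-curve linear model
  $\Delta R_2^{*,vox}(t) \approx K_1\bar c(t) - K_2\int_0^t \bar c$,
  fitted per voxel by OLS against the mean curve of automatically
  detected non-enhancing tissue; the corrected curve
  $measured + K_2\int\bar c$ is what gets integrated.
- **WM reference selection** — flat-kernel mean-shift clustering of the
  concentration curves (PCA-reduced), gated by a white-matter
  probability map: among voxels with ≥ 95% WM probability, the cluster
  holding the most of them becomes the reference ROI. A manual ROI path
  is also provided.

Supporting modules: Otsu-based tumor-ROI finalization inside a drawn
boundary, NIfTI-1 I/O on a shared voxel grid, ROI summaries (mean, 95th
percentile), Bland–Altman agreement (bias ± 2·SD limits) and the
one-way random-effects ICC, plus a fully seeded synthetic DSC phantom
with known ground truth (tissue classes, CBV ratios, bolus timing,
leakage coefficients, WM probabilities).

## Worked example

Everything runs on the built-in phantom — no data download. The phantom
emulates a 40-frame acquisition at 2.2 s spacing, TE 60 ms, bolus
arriving 25 s after acquisition start, with CBV ratios
WM : GM : tumor = 1 : 2 : 3 and mild tumor leakage:

```r
library(dscquant)

ph  <- generate_phantom(phantom_spec(noise_sd = 10, tumor_k2 = 0.01,
                                     seed = 42))
fit <- dsc_quantify(ph$series,
                    tumor_roi = ph$truth$labels == 3,
                    wm_prob   = ph$truth$wm_prob)
fit
#> DSC rCBV quantification
#> Bolus timing (post-discard frames, 3 discarded):
#>   baseline window [1, 8], entrance 9, trough 13, exit 24 of 37 frames
#>   leakage correction: on (3250 reference voxels)
#>   WM reference: automatic, 2200 voxels; mean WM CBV 0.1295
#>   ROI statistics (rCBV):
#>    roi n_voxels     mean      p95
#>     wm     2200 1.000000 1.087180
#>  tumor      200 3.012309 3.194717
```

Reading the output: after discarding the first 3 saturation frames, the
bolus entrance/trough/exit were detected at frames 9/13/24 (truth:
9/13/23 — exit within the one-frame detection tolerance); leakage was
fitted against 3250 automatically selected non-enhancing voxels; the
automatic WM reference recovered all 2200 true WM voxels; mean rCBV is
exactly 1 in WM by construction and ≈ 3.01 in tumor, matching the
phantom's 3:1 CBV ratio despite the injected leakage. `summary(fit)`,
`plot(fit)` (detection curve + rCBV slice) and
`write_quant_outputs(fit, "out/")` (NIfTI maps, timing JSON, stats CSV)
complete the workflow.

A thin CLI wraps the same functions
(`inst/scripts/dscquant quantify|simulate|agree`), e.g.:

```sh
Rscript inst/scripts/dscquant simulate --noise-sd 10 --seed 5 --out phantom/
Rscript inst/scripts/dscquant quantify --dsc phantom/dsc.nii.gz --te 60 \
    --wm-prob-map phantom/wm_prob.nii.gz --out quant/
```

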