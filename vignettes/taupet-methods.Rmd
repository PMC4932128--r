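---
title: "Quantifying dynamic tau-PET: models, corrections and statistics in taupet"
author: "taupet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dynamic tau-PET: models, corrections and statistics in taupet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taupet)
```

## What this package computes

`taupet` implements the quantitative core of a multi-tracer dynamic brain
PET study: kinetic quantification of a tau tracer by the reference Logan
graphical method, static SUV/SUVR quantification, Müller–Gärtner
partial-volume correction, region-of-interest analysis over a
grey-matter-masked atlas with Braak-stage composite regions, test–retest
reproducibility summaries, and ROI- and voxel-level group statistics.
Because patient images cannot be redistributed, the package ships a
synthetic dynamic-PET phantom generator with known ground-truth kinetics;
every stage of the pipeline is validated by parameter recovery against
that ground truth.

## The kinetic model

### Forward model (simulation)

The phantom's reference region follows a gamma-variate curve
$C_R(t) = A\,t\,e^{-t/\tau}$ with amplitude $A$ (activity per minute) and
time-to-peak $\tau$ (minutes). This is the simplest input form whose
convolution with a single-exponential kernel has a closed form, which
gives the simulator a cheap, high-accuracy oracle. Target-tissue curves
follow the simplified reference tissue model (SRTM),

$$C_T(t) = R_1 C_R(t) + \left(k_2 - R_1 k_{2a}\right)
  \int_0^t C_R(s)\, e^{-k_{2a}(t-s)}\, ds, \qquad
  k_{2a} = \frac{k_2}{1 + BP_{ND}},$$

with delivery ratio $R_1$, reference efflux $k_2$ (1/min) and binding
potential $BP_{ND}$. The distribution volume ratio is
$DVR = 1 + BP_{ND}$. Frame values are *within-frame time averages* of the
continuous curves (not midpoint samples), matching how scanners report
frames and how the Logan integrals are later built.

Defaults: $A = 20$, $\tau = 10$ min (peak near 10 min with roughly 3–5 %
of peak activity remaining in the last frames — a slow washout typical of
this tracer class, and necessary for the 30–60 min fit window to contain
usable signal); $R_1 = 1$, $k_2 = 0.15$/min. All are arguments.

### Inverse model (estimation)

`logan_dvr()` implements the simplified reference Logan plot: for frames
whose mid-time lies in the fit window (default 30–60 min),

$$\frac{\int_0^t C_T}{C_T(t)} = DVR \cdot
  \frac{\int_0^t C_R}{C_T(t)} + b,$$

fitted by ordinary least squares; the slope is the DVR. Integrals are
trapezoidal on frame mid-times with a leading triangle from $(0,0)$ —
standard for frame-averaged data. The population-$k_2'$ correction term
is deliberately omitted: at late fit windows its contribution is small
and typical practice for tau and amyloid tracers drops it; whether the
original analysis used one is not stated at this level, so the simpler
form is the default. Frames with non-positive target activity inside the
window are dropped (and counted in the fit object), not clipped.

`logan_dvr_image()` applies the same estimator voxel-wise in vectorised
form, with the reference curve taken as the mask-mean TAC. Voxels with
any non-positive in-window value fail the preconditions and become `NA`;
their count is attached to the map. On noiseless phantoms the estimator
recovers DVR within 2 % over DVR 1.0–2.0; residual error is the usual
mild negative bias of graphical methods at finite $k_{2a}t^*$, which
grows as efflux slows (at $k_2 = 0.1$/min and DVR 2 it reaches ~4 %).

## SUV, SUVR and amyloid positivity

SUV is activity concentration divided by injected dose over body weight;
SUVR divides a late-window average image (default 40–60 min) by the
unweighted mean over the reference mask (cerebellar grey matter for the
tau and amyloid tracers, pons for FDG). The amyloid-positivity cut-off on
isocortical SUVR is 1.41. The window average weights frames by their
overlap with the window, so partially covered frames contribute
proportionally.

## Partial-volume correction

`muller_gartner()` implements the two-compartment Müller–Gärtner
correction:

$$C_{GM}^{corr} = \frac{C - C_{WM}\,(WM \otimes PSF)}{GM \otimes PSF},$$

where $\otimes$ is Gaussian convolution with the scanner point-spread
function and $C_{WM}$ is a pure white-matter estimate, by default the
image mean over voxels with WM probability ≥ 0.99 eroded to at least
`wm_erosion_mm` (5–6 mm is a reasonable depth; erosion uses an exact
Euclidean distance transform, not a box kernel, because box erosion at
these structure scales removes far more than the nominal depth). CSF is
assumed activity-free. Corrected values are reported only where the GM
probability is at least `gm_threshold` (default 0.3 — a balance between
coverage and division noise), and the blurred-GM denominator is floored
at 0.1 with floored voxels counted, preventing edge explosions.

The assumed PSF defaults to 8 mm FWHM, matching the smoothing kernel used
elsewhere in the pipeline; the true scanner value is a free parameter. If
the assumed PSF exceeds the true one the correction overshoots — visible
in the workflow scripts, where maps rendered at 5 mm and corrected at
8 mm widen the regional range beyond the truth. This mirrors the
qualitative behaviour expected of the correction (a wider DVR range in
all regions) and is why the PSF is surfaced in `pvc_config()` rather
than hard-coded.

## Atlas, composites and ROI values

Atlases are masked to grey matter by binarising the GM probability map at
0.5 — the single most consequential unstated constant in this kind of
pipeline, which is why it is an explicit argument and recorded in
provenance. ROI means are unweighted over in-region voxels with finite
values (consistent with binarised masking semantics); non-finite voxels
are excluded and counted. Two composites follow the neuropathological
staging of tau spread: a limbic composite (Braak III–IV: hippocampus,
amygdala, parahippocampal and fusiform gyri in the phantom's vocabulary)
and an isocortical composite (Braak V–VI: all isocortical regions except
the precentral and postcentral gyri). A composite's mean equals the
voxel-count-weighted mean of its members — an exact identity that the
tests assert.

## Test–retest reproducibility

For subjects scanned twice, the per-region relative difference is
$100\,(R - T)/T$ — deliberately asymmetric in the roles. Region summaries
report the mean of the absolute percent differences and their *sample*
standard deviation (the signed-SD interpretation does not reproduce the
published table). The intraclass correlation coefficient is

$$ICC = \frac{BIMSS - WIMSS}{BIMSS + WIMSS}, \quad
  BIMSS = \frac{2\sum_i (\bar m_i - \bar g)^2}{n-1}, \quad
  WIMSS = \frac{\sum_i d_i^2 / 2}{n},$$

with $\bar m_i$ each subject's test/retest mean, $\bar g$ the grand mean
and $d_i$ the retest-minus-test difference. The exact degrees-of-freedom
convention is not printed alongside the published table; this choice
reproduces its well-conditioned cells (frontal cortex 0.975 vs the
printed 0.98).

Two reproduction limits are worth stating plainly. First, the published
per-subject percent rows are printed at two decimals; recomputing the SD
row from them recovers every cell only to within one unit of the last
printed digit (six of eleven cells differ by 0.01 from values evidently
computed on unrounded data). The mean-absolute row, by contrast,
reproduces exactly in all eleven regions. Second, regions with very low
between-subject variance (posterior cingulate, published ICC 0.52) are
numerically unrecoverable from two-decimal inputs, because the ICC there
is dominated by digits lost in rounding; such cells are documented, not
asserted.

## Group statistics

* **ROC/AUC** uses the Mann–Whitney rank identity with midranks (ties
  count one half); it is checked against exhaustive pair counting.
* **Rank tests**: Kruskal–Wallis omnibus per region with two-sided
  Mann–Whitney pairwise post-hocs, flagged at a Bonferroni-corrected
  alpha — for three groups compared pairwise in two composite regions,
  $0.05/6 \approx 0.008$.
* **Abnormality z-maps** compare a patient to the control mean and SD
  voxel-wise; flagging is one-sided ($z > 1.96$), since only abnormally
  *high* retention is of interest, and binarised maps are summed across a
  group to form count maps.
* **Permutation contrasts**: voxel-wise pooled-variance two-sample T with
  p-values from group-label permutations (two-sided; default 10,000). The
  observed labelling is included in the null count, so
  $p \ge 1/(n_{perm}+1)$ — the standard validity guarantee. When more
  permutations are requested than distinct assignments exist, all
  assignments are enumerated instead (so a 3-vs-3 contrast is exact with
  20 arrangements). Voxel p-values are Benjamini–Hochberg adjusted at
  $q = 0.05$; the FDR mask is by construction a subset of the
  uncorrected $p < 0.05$ mask. Group contrasts are two-sided while
  abnormality maps are one-sided; both choices are recorded here because
  the source analysis does not state its sidedness.
* **Cross-modality correlation**: per-voxel Pearson r across subjects
  with parametric p-values, thresholded at $p < 0.001$ (plus the more
  lenient 0.01 and 0.05), split by sign, and reduced to 26-connected
  clusters of at least 20 voxels (the SPM-family connectivity
  convention).

Smoothing uses a separable Gaussian with $\sigma = FWHM/(2\sqrt{2\ln 2})$
per axis in mm, kernel truncated at $4\sigma$ and renormalised,
zero-padded at the volume edges; total activity is conserved as long as
the signal does not touch the boundary, which holds for all phantom
scenes (the brain sits inside a background margin).

## The phantom: what it emulates, and what it does not

`default_phantom_scene()` builds a brain-like geometry on a cubic grid
(default 48³ voxels of 2 mm): an ellipsoidal brain, a basal cerebellar GM
slab (the reference region), a central WM compartment with nonspecific
retention (DVR 1.25 — tau tracers of this family show substantial WM
binding, which is the entire motivation for partial-volume correction),
four deep limbic structures, four isocortical sectors, a precentral
gyrus (present precisely so the isocortical composite can exclude it)
and a putamen. Tissue maps are binary; soft maps for partial-volume
experiments are made by blurring.

`make_cohort()` draws per-subject regional DVRs from group-specific
normal distributions truncated at 1. The default three-group
configuration (9 controls at DVR ≈ 1.02, 11 prodromal at limbic 1.20 /
isocortical 1.12, 9 dementia at 1.25/1.25, SDs 0.03–0.06) qualitatively
matches the published boxplot ranges (controls ≈ 1.0–1.1, isocortical
disease ≈ 1.1–1.4 before correction); no quantitative distributions are
published, so these are package choices, overridable in
`cohort_config()`. Injected dose is drawn at 212 ± 42 MBq. Rendering
applies a 5 mm PSF by default (clinical PET resolution) and Gaussian
noise with SD $= \text{noise\_scale}\sqrt{C}/\sqrt{\Delta t}$ per frame —
the standard variance approximation for reconstructed PET, giving
late-frame voxel coefficients of variation around 10–20 % at the default
scale of 1. All randomness flows from one integer seed through derived
per-subject seeds; no global RNG state leaks.

What the phantom does **not** emulate: arterial input and plasma
metabolites, Poisson counting statistics and reconstruction artefacts,
attenuation/scatter, head motion, inter-subject anatomical variability,
and registration error. Passing recovery tests therefore demonstrates
the correctness of the estimators under the declared noise and blur
model — not robustness to registration or reconstruction effects in real
data.

## Numerical choices and problem sizes

Degenerate inputs are rejected early with informative errors (empty
masks, non-positive reference activity in the fit window, erosion that
empties the WM core, windows outside the scan span). Ties in the AUC
contribute one half via midranks; zero-variance relabelings in the
permutation test count as extreme (conservative). The test suite and the
acceptance script run the phantom at 16³–32³ with 9–30 subjects — sizes
at which every recovery property already holds and a full run completes
in well under a minute per stage; the 48³ default is the recommended
scale for interactive use.

## Known limitations

* The reference Logan form omits the $k_2'$ term; with very fast-washout
  reference regions or early fit windows this biases DVR slightly
  downward.
* Müller–Gärtner corrects only GM/WM spill; region-based methods (GTM,
  RBV, iterative Yang) are out of scope.
* The ICC convention reproduces well-conditioned published cells;
  low-variance regions are inherently unstable under input rounding.
* The voxel-wise correlation uses parametric p-values (as in the
  original toolbox chain), not permutation p-values.
* Atlas and image are assumed on the same grid; registration and
  resampling are upstream concerns.
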