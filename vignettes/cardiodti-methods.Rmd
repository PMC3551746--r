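---
title: "Methods: cardiac diffusion tensor post-processing and reproducibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiac diffusion tensor post-processing and reproducibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiodti)
library(dplyr)
```

## The measurement model

Magnitude diffusion-weighted MR follows the Stejskal–Tanner attenuation
$S_i = S_0 \exp(-b\, g_i^\top D\, g_i)$, where $D$ is the symmetric
positive-definite $3\times3$ diffusion tensor of the voxel, $g_i$ a unit
encoding direction and $b$ the diffusion sensitization (here 350 s/mm²,
typical of breath-hold stimulated-echo cardiac protocols, which trade
sensitivity for motion robustness). With one $b=0$ reference and six
directions the log-linearized system

$$-\ln(S_i/S_0) \;=\; b\,(g_{ix}^2, g_{iy}^2, g_{iz}^2, 2g_{ix}g_{iy},
2g_{ix}g_{iz}, 2g_{iy}g_{iz})\cdot d$$

is exactly determined for the six unique components $d$ of $D$;
`fit_tensor_loglinear()` solves it per voxel (least squares when more
directions are supplied). We deliberately use the unweighted log-linear fit:
with the minimal 6-direction scheme there is no redundancy for robust or
weighted schemes to exploit, and the exactly-determined fit makes the
noiseless phantom roundtrip bit-exact, which anchors the test suite.

From the sorted eigensystem $\lambda_1\ge\lambda_2\ge\lambda_3$,
FA $= \sqrt{3/2}\,\sqrt{\sum_k(\lambda_k-\bar\lambda)^2}/\sqrt{\sum_k\lambda_k^2}$
measures deviation from isotropy and MD $=\bar\lambda=\mathrm{tr}(D)/3$ the
average diffusivity. Noise, misregistration and high local anisotropy can
push measured $\lambda_3$ (rarely $\lambda_2$) negative;
`repair_negative_eigenvalues()` replaces each negative eigenvalue by the mean
of the *same-rank* non-negative eigenvalues of its in-plane 8-connected
neighbours, in a single pass, falling back to 0 for isolated voxels.
Cross-slice neighbours are excluded because the slice spacing (8 mm thickness
+ 4 mm gap) makes them poor surrogates for an in-plane neighbourhood.

## Helix angle and the cardiac frame

At each myocardial voxel we erect a right-handed orthonormal frame: radial
$\hat r$ (in-plane, centroid to voxel), longitudinal $\hat\ell$ (long axis,
apex → base) and circumferential $\hat c = \hat\ell \times \hat r$. The helix
angle is the angle between the short-axis plane and the projection of the
principal eigenvector onto the $\hat c$–$\hat\ell$ plane (the plane
tangential to the local endocardium under a circular-contour approximation):

$$\mathrm{HA} = \operatorname{atan2}(v\cdot\hat\ell,\; v\cdot\hat c),
\qquad v = e_1 - (e_1\cdot\hat r)\hat r .$$

Eigenvectors are sign-ambiguous, so $v$ is flipped to make
$v\cdot\hat c \ge 0$; HA then lies in $[-90°, +90°]$, positive for
right-handed endocardial helices and negative for left-handed epicardial
ones (Streeter's convention), zero circumferential. Ties
($v\cdot\hat c = 0$) map to $+90°$. Voxels with $\|v\| < 10^{-9}$ or
$\lambda_1-\lambda_2 < 10^{-12}$ mm²/s are masked as unreliable: with
degenerate leading eigenvalues the direction of $e_1$ is numerically
meaningless. The centroid-radial tangent plane is an approximation; a
contour-normal refinement would matter for strongly non-circular
endocardial contours and is left as an extension.

Handedness deserves a note: the long axis points *out of* the short-axis
image toward the base, so "counterclockwise viewed from the base" runs
clockwise in image coordinates. `assign_walls()` therefore places the
anterior sector at `rv_azimuth − 90°` in image coordinates; the phantom
roundtrip (right-handed endocardial helices must come out positive) pins the
convention.

## Segmentation

Transmural depth is computed per slice from two Euclidean distance
transforms, $d = d_e/(d_e + d_p)$ with $d_e$ the distance to the cavity and
$d_p$ the distance to the background. Pixel-centre distance maps never reach
zero on the boundary (the nearest cavity *pixel centre* is at least one pixel
away), which at a 5-pixel wall would compress $d$ into roughly
$[0.17, 0.83]$ and distort the equal-thickness layers. We therefore measure
both distances to the mask *boundary* by subtracting half a pixel,
$d = (d_e - \tfrac12)/(d_e + d_p - 1)$, clipped to $[0,1]$; on the analytic
annulus this tracks continuous depth to well under half a pixel of wall
fraction. Layers are half-open thirds ($d<\frac13$ endocardial,
$[\frac13,\frac23)$ mesocardial, $\ge\frac23$ epicardial); walls are four 90°
sectors anchored at the user-supplied RV azimuth (automatic contouring and
papillary-muscle exclusion are the mask provider's responsibility).

## Preprocessing

The processing order is reject → co-register → average. Rejection scores
each repetition against the pixelwise median image of its (slice, channel)
group by normalized cross-correlation. Because rejection runs *before*
registration, frames still carry breath-hold translations; a plain NCC
against the median penalizes a 1–2 pixel shift as heavily as a genuine
artefact and, at the 0.90 default threshold, would discard most intact
frames. The score is therefore the maximum NCC over integer translations
within `align_radius` (default 3 pixels): a translation can explain a
breath-hold shift but not a signal-loss band, so intact frames score ≈ 1 and
corrupted ones stay low. Registration proper is an exhaustive integer-shift
NCC search (default radius 10 pixels) against the median of the accepted b0
repetitions; sub-pixel refinement is deliberately omitted — integer shifts
keep the operation exactly invertible, which the tests exploit. Averaging is
the plain mean over accepted repetitions.

## The phantom

`phantom_config()` defaults encode the acquisition this pipeline targets:
3 short-axis slices on a 48×48 grid at 2.7 mm, annular myocardium
(endocardial radius 12 mm, epicardial 25 mm — an HCM-thick 13 mm wall),
b = 350 s/mm² with the six dual-gradient directions (protocols rarely print
their direction tables; any set can be supplied via bval/bvec sidecars),
10 repetitions, S₀ = 1000 with Rician σ = 50 (SNR 20), integer breath-hold
translations with SD 1 pixel, and a 5% per-frame probability of a
signal-dropout band (a zeroed run of rows, the b0 signal-loss artefact mode).
Myocardial voxels carry FA 0.613 and MD 0.750×10⁻³ mm²/s — the global
in-vivo HCM values — via the axially symmetric inversion
$\lambda_1 = \mathrm{MD}(1+2a)$, $\lambda_{2,3} = \mathrm{MD}(1-a)$,
$a = \mathrm{FA}/\sqrt{3-2\,\mathrm{FA}^2}$. The helix angle ramps linearly
with transmural depth from +38.9° to −34.3°; the truth tensor is
$R\,\mathrm{diag}(\lambda)\,R^\top$ with $e_1$ in the tangent plane at the
prescribed angle, $e_3$ radial and $e_2 = e_3\times e_1$ (sheet-normal
convention). The cavity is filled with isotropic 2.5×10⁻³ mm²/s "blood" so
b0 images have realistic bright-pool contrast for registration.

Note a subtlety: +38.9/−34.3° are the *ramp endpoints*, so the phantom's
layer *means* (≈ +26/+2.8/−21° on the default annulus) are smaller in
magnitude than the in-vivo layer means of the same numbers — a linear ramp
averaged over a third of the wall cannot reproduce its own endpoint. The
acceptance analysis therefore recovers the endpoints by regressing the
fitted HA map on depth rather than comparing layer means.

What the phantom does **not** emulate: EPI/k-space artefacts, cardiac strain
or through-plane motion, coil-profile SNR gradients, partial-volume at the
blood pool beyond pixelation, and physiological between-scan change. Passing
phantom tests therefore demonstrates the correctness of the *post-processing
arithmetic* under a controlled forward model, not clinical robustness.
`synthetic_paired_study()` adds an explicit per-scan global perturbation
(SD in native units) to FA/MD targets so the reproducibility machinery can
be tested for parameter recovery.

## Reproducibility statistics

For paired initial/repeat studies, per region: mean difference, SD of the
difference (n−1 denominator), Bland–Altman 95% limits of agreement
(bias ± 1.96·SD) and CoV = 100·SD_diff / pooled mean. The pooled mean (mean
of both scans' values) is used as the CoV denominator — in the reference
tables the "mean value" column lies between the two scans' single-study
means, which is consistent with pooling. The CoV is flagged NA when the
pooled mean is within tolerance of zero: mesocardial helix angles average
near zero as the orientation rotates through the wall, making the ratio
meaningless. The variance-ratio comparison of two metrics' reproducibility
is implemented as $F = (\mathrm{SD}_1/\mu_1)^2/(\mathrm{SD}_2/\mu_2)^2$ on
$(n_1-1, n_2-1)$ degrees of freedom with a two-sided p; whether the original
analysis normalized by the mean before forming the ratio is not stated, so
this is one documented choice among defensible ones. Hierarchical
mixed-effects modelling of regional contrasts is out of scope; the
initial-study tables ship with raw between-region differences instead.

The reference tables in `inst/extdata/` are printed values (3 decimals for
FA/MD, 1 for HA and CoV). Recomputing CoV and limits of agreement *from the
printed inputs* cannot reproduce every printed output exactly — the source
computed from unrounded data — so `recompute_reproducibility_arithmetic()`
flags the rows that are self-consistent under rounding and the tests assert
(a) exact agreement at printed precision on those rows and (b) that every
row stays within the bound implied by input rounding
($(1+1.96+1)/2$ units of the last digit).

## Numerical choices and degenerate inputs

* Signal floor: DW intensities are clipped at $10^{-6} S_0$ before the log;
  voxels with $S_0$ below 5% of the robust (99th percentile) maximum are
  masked. At SNR 20 the Rayleigh background mean exceeds that floor, so
  background voxels are fitted and repaired too; this is harmless (all
  regional statistics intersect the myocardial mask) but visible in repair
  counts.
* Eigenvector signs: the largest-magnitude component is made positive —
  a deterministic choice that stabilizes outputs; HA is invariant to it.
* Equal eigenvalues: the eigenbasis is implementation-defined; downstream HA
  masks such voxels via the $\lambda_1-\lambda_2$ threshold.
* Constant images score NCC 0 (rejected) unless compared to an equal
  constant image (score 1).
* `run_reproducibility()` on a single study pair returns NA SD/LoA/CoV with
  a warning — the SD of one difference is undefined with the n−1
  denominator.
* All randomness (noise, shifts, corruption, cohort perturbations) flows
  through explicit integer seeds; identical seeds give bit-identical
  series and byte-identical CSV exports.

## Problem sizes

The test suite and the acceptance analysis use a 48×48, 3-slice phantom
(≈ 620 myocardial voxels) for acquisition-matched runs, 24–32 pixel grids
for unit tests, a 10-subject paired cohort at SNR 20 with registration
radius 5 for the CoV ordering, and a 50-subject noise-free cohort for
between-scan SD recovery; these sizes give stable statistics while keeping
a full run of tests plus acceptance under a few minutes on one CPU.

## Known limitations

Translation-only registration cannot correct rotation or deformation; the
median reference blurs when shifts are balanced across few repetitions
(with ≤ 3 repetitions the median itself is a mixture). The NCC rejection
proxy cannot be validated against human visual review. The centroid-radial
tangent plane approximates the true endocardial tangent. HA layer statistics
are voxel means within layers, not per-layer orientation fits. FA estimates
carry the well-known positive Rician bias at low SNR (visible as a ~1%
upward shift of global FA at SNR 20), and MD in noisy runs is biased upward
by a few percent by residual misregistration mixing bright cavity signal
into wall-edge voxels — both emerge in the noisy cohort and neither is
corrected for, matching common practice for this acquisition class.
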