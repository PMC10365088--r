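---
title: "Respiratory motion compensation in free-breathing whole-heart CMR: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory motion compensation in free-breathing whole-heart CMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Free-breathing whole-heart cardiac MR acquires an isotropic 3D volume over
several minutes of quiet respiration, ECG-gated to mid-diastole. Respiratory
motion of the heart (roughly one centimetre superior-inferior per breath)
must be dealt with at reconstruction time. Two strategies dominate:

* **Mcorr (motion-corrected)** — every interleaf of the radial acquisition
  starts with a readout along the superior-inferior (SI) axis. Its 1D
  Fourier transform is a projection of the whole volume onto SI: a
  self-navigator. Cross-correlating each interleaf's projection against a
  reference yields a per-interleaf SI displacement, which is removed by a
  linear phase in k-space before a single gridded reconstruction uses all
  the data.
* **Mres (motion-resolved)** — the same navigator projections feed a
  principal component analysis whose respiratory-band component orders the
  interleaves by breathing amplitude. The data are split into four
  equal-count amplitude bins (bin 1 = end-expiration) and reconstructed
  jointly by compressed sensing with a total-variation penalty along the
  respiratory-bin dimension (the XD-GRASP formulation), yielding four
  motion-frozen volumes from heavily undersampled bins.

This package implements both arms end to end on a synthetic, fully
controlled subject: a parametric thorax phantom with a closed-form Fourier
transform, an interleaved 3D radial spiral-phyllotaxis trajectory, the two
reconstructions, CLAHE post-filtering, a classical blood-pool segmenter
standing in for learning-based segmentation, and the evaluation chain the
comparison needs (absolute volume difference, 3D Dice, endocardial border
sharpness, best-bin selection, paired t-tests).

```{r}
library(phyllorecon)
cfg <- experiment_config("desk", seed = 1)
subject <- run_subject(cfg)
report <- run_cohort(cfg, n_subjects = 6, out_dir = "study_out")
print(report)
```

## The phantom and what it does (and does not) emulate

Anatomy is a sum of uniform ellipsoids with additive intensities: an LV
blood pool (total 1.0 in arbitrary signal units) inside a myocardial shell
(0.45, 8 mm thick), a dim body (0.2), and two bright **static** structures,
an anterior chest-wall slab (0.9 total) and a spine rod (0.8 total). Only
bright-blood *contrast* is emulated; there is no Bloch simulation, no
banding, no T2-preparation physics, and no cardiac contraction (the
acquisition is treated as perfectly mid-diastole gated).

Because each component's Fourier transform is known in closed form
(`analytic_kspace()`), simulated k-space samples come from the continuous
object, not from a discretised image — reconstruction is never tested
against its own discretisation (no inverse crime). The rasteriser
(`rasterize()`) produces the ground-truth volumes and LV masks that play
the "manual segmentation" role downstream.

**Breathing.** Displacement follows
`d(t) = A sin(pi t / T)^(2p) + drift t + jitter(t)`, with defaults
A = 10 mm, T = 4 s, p = 2, jitter 0.2 mm. The even power makes the subject
dwell near end-expiration, which is why the expiratory bins of the
motion-resolved arm carry the least intra-bin motion — a known property of
free breathing that the evaluation reproduces. Jitter is a seeded Gaussian
lattice (spacing T/8, linear interpolation), so `d(t)` is a deterministic
function of time.

**Motion direction.** Cardiac components are displaced along a tilted
axis: the full excursion along SI plus 35% of it along
anterior-posterior (`ap_fraction = 0.35` in `default_anatomy()`). Measured
respiratory heart motion is SI-dominant but has a consistent AP component
of a few millimetres; it is precisely the part of the motion that a 1D
SI-only correction cannot remove, and with a purely SI phantom the
motion-corrected arm would be artificially flattered — its model would be
exactly right, which it is not in vivo. Pure-SI phantoms
(`ap_fraction = 0`) remain available and are used to calibrate the shift
estimator and to verify the phase-correction oracle to machine precision.

**Noise.** Complex Gaussian noise is added per k-space sample with
`sd = peak * 10^(-snr_db/20) / sqrt(samples_per_line)`: the DC-referenced
noise budget is spent over one readout, so the SI navigator projection has
an SNR of `snr_db` and the reconstructed image SNR lands near 20 at the
default 30 dB — typical of clinical bSSFP. (Putting the whole budget on a
single sample instead yields image SNR ~2 and no stage downstream can
function; that reading was rejected.)

**What passing tests do not show.** The phantom has rigid motion, piecewise
constant tissue, ideal gating, ideal coils, and additive Gaussian noise.
Results here demonstrate that the *pipeline* behaves as designed, not that
either reconstruction attains any particular accuracy on patient data.

## Acquisition

`make_phyllotaxis()` distributes readout directions over the half-sphere
along a spiral (polar angle proportional to the square root of the line
index, azimuth stepped by the golden angle 137.5078 degrees), regrouped
into interleaves whose segment 0 always points along SI. All lines are full
diameters through k = 0 at Nyquist spacing `1/fov`. The published
whole-heart protocol corresponds to
`make_phyllotaxis(382, 32)` — 12,224 lines — at matrix 192 over a 220 mm
field of view; the desk preset keeps the 32-line interleaf structure at
matrix 64 with 200 interleaves, which is approximately fully sampled for
the full data and four-fold undersampled per respiratory bin, the same
regime as the protocol.

Motion is frozen within an interleaf (200 ms against a 4 s breath) and the
desk preset uses a 0.9 s cardiac interval: a realistic heart rate that also
avoids phase-locking the sampling to the 4 s breathing period (an exactly
1 Hz clock samples only three distinct phases of the breath).

## Reconstruction machinery

The non-uniform Fourier operator is Kaiser-Bessel gridding: apodisation
correction, zero-padded FFT, kernel interpolation. The adjoint is the exact
matrix transpose of the forward (same tabulated kernel, conjugated phases),
so the randomized adjoint dot-test holds to machine precision at any
accuracy setting; the `accuracy` knob only sets how closely the forward
matches the exact discrete Fourier sum (`"high"`: 2x oversampling, width-8
kernel, ~1e-7 relative; `"fast"`: 1.25x, width 5, ~1e-3 — ample for
iterative reconstruction and about three times cheaper).

Density compensation is the standard rho-squared radial weighting with two
refinements. First, every radial line re-acquires k = 0, so the central
weight is shared across lines — without this the centre is over-counted by
a factor of the line count and the image rides on a constant offset.
Second, `iterative_dcf()` (Pipe-Menon fixed point, `w / P'Pw`) refines the
weights for the actual phyllotaxis geometry; the weights depend only on the
trajectory and are computed once and reused. The gridded Mcorr arm uses
them, and the CS arm uses per-bin refined weights as its data-term
preconditioner, which is what lets a 20-iteration budget converge close to
the per-bin least-squares solution.

## The two arms

**Mcorr.** Projections are column-normalised; the heart band is isolated
as the hull of rows whose temporal variance exceeds 25% of the peak
(variance computed on L2-normalised, temporally low-passed profiles —
breathing at ~0.25 Hz is far below the interleaf rate, so the low-pass
suppresses noise without touching motion). Shifts come from normalized
cross-correlation against the first interleaf with 3-point parabolic
sub-sample refinement, and are applied as `exp(+2 pi i k_z delta)`.
On the clean heart-only phantom the estimator is accurate to well under
half a millimetre at 30 dB; on the full anatomy the static chest wall,
spine and body pedestal bias the correlation towards zero shift
(RMSE ~3-4 mm) — deliberately so, as this is the failure mechanism
described for cross-correlation self-navigation in the presence of bright
static structures.

**Mres.** The per-coil projection magnitudes are concatenated and the
leading principal components of the interleaf time series are scored by
spectral-power fraction inside the respiratory band (default 0.1-0.5 Hz;
below 20% raises an error). The winning component is sign-oriented by the
projection centroid. PCA pools variance across all rows and coils, which is
why it stays accurate (|r| > 0.99) on the same confounded anatomy that
breaks the cross-correlation — the robustness asymmetry at the heart of the
two-arm comparison. Equal-count amplitude binning guarantees comparable
per-bin undersampling; ties break by interleaf order.

The CS solver minimises
`sum_b 0.5 ||sqrt(W_b)(F_b x_b - y_b)||^2 + lambda TV_resp(x)` by proximal
gradient iteration: step size from power iteration, TV proximal operator by
a warm-started dual projection (Chambolle-style; the respiratory dimension
has only four points, so a handful of inner iterations suffices), and a
monotonicity safeguard that rejects any step that would raise the recorded
objective and halves the step instead — the reported objective is
nonincreasing by construction. Data are scaled so the density-compensated
adjoint has unit maximum, making `lambda = 0.1` (the reference protocol
value) scale-free. `tv_mode = "spatial"` and `"both"` are available;
respiratory TV is the default because it is the defining XD-GRASP
regulariser.

## Post-processing and segmentation

A 3D CLAHE filter (clip limit 0.01, 8 tiles per dimension, trilinear
blending of tile mappings) is applied identically to both arms before
segmentation, mirroring the equal-treatment normalisation step of the
clinical pipeline. The automatic segmenter is deliberately classical — the
deep network it stands in for requires training data and weights outside
this package's scope. It uses a three-class Otsu threshold inside a 60 mm
ROI around the seed (the ROI genuinely contains blood, myocardium, and
surroundings; the upper threshold is the blood/myocardium boundary — a
two-class threshold lands below the myocardium after CLAHE and floods the
shell), region growing by 6-connected flood fill from the seed (snapped to
the local maximum within 6 mm, since local equalisation can leave the
geometric centroid slightly darker than the pool), morphological closing,
and retention of the seed component. On noiseless rasterised phantoms it
reproduces the truth mask exactly; on desk-scale reconstructions it scores
Dice ~0.86-0.90 against truth, conveniently in the range the clinical
comparison operates in.

## Evaluation

AVD (`|countA - countB| * voxel volume`), 3D Dice, and mid-short-axis
endocardial sharpness are computed per reconstruction; each subject's best
bin is chosen per criterion (minimum AVD, maximum Dice, maximum sharpness)
and the cohort is compared by two-tailed paired t-tests (alpha 0.05;
degenerate zero-variance comparisons are reported as not applicable).
"Manual" masks are displacement-matched ground truth: end-expiration for
Mcorr (the reference position of the correction), the bin-mean position
for each Mres bin.

**Sharpness** is the one measure whose published definition was not
available, so its reconstruction here is the largest interpretive decision
and is isolated behind a single function. On the axial slice through the
LV mask centroid, 24 radial intensity profiles are cast from the blood-pool
centroid (bilinear interpolation, 0.1-voxel steps); per ray the transition
is the distance between the 80% and 20% levels of the local intensity drop
past the mask boundary, and the slice sharpness is the **median** of the
inverse widths over valid rays (at least half of the 24 must show a clean
drop within 15 mm). The median matters: a mean of inverse widths is convex
in the width, and two or three artifact rays with spuriously narrow
crossings can rate a ghosted image "sharper" than its own static reference;
with the median, a motion-corrupted reconstruction scores at or below the
matched static one, as it must. An ideal one-voxel step edge yields
`1/(0.6 * spacing)` exactly under the linear-interpolation convention.

## Numerical choices and degenerate inputs

* Grids are cubic with even matrix sizes; voxel (0,0,0) is centred at
  `-fov/2 + spacing/2`. Oversampled FFT sizes are rounded up to products of
  2, 3, 5.
* Empty anatomy rasterises to a zero volume with a warning; static data
  raise classed errors from band detection (`band_detection_error`) and
  respiratory PCA (`band_power_too_low`); flat projection columns estimate
  zero shift with a warning; empty bins and negative `lambda` are
  configuration errors; identical paired differences raise
  `degenerate_variance`; fewer than half valid sharpness rays raise
  `sharpness_undefined`.
* All NRMSE comparisons fit one optimal real scale first, because
  reconstruction amplitude depends on density-weight normalisation.
* Randomness flows from one master seed through named per-stage sub-seeds
  (`derive_seed`), so stages can be re-run independently and cohort
  subjects are reproducible individually.

## Problem sizes

The desk preset (matrix 64, 220 mm FOV, 200 interleaves of 32 lines,
single coil, 20 CS iterations with per-bin preconditioning) runs one
two-arm subject in about a minute on a single core; the test suite and the
acceptance script size their simulations accordingly (navigator studies
use 2-line interleaves, since only segment 0 feeds the estimators; solver
property checks run at matrix 16-32). The protocol preset reproduces the
published geometry (matrix 192, 382 x 32 lines, 4 coils) for scale checks
of the trajectory and bookkeeping; running full CS at that scale is
possible but not part of the routine tests.

## Known limitations

* Rigid ellipsoid anatomy: no deformation, no hysteresis (inspiration and
  expiration follow the same path), no cardiac residual motion.
* Coil sensitivities are broad Gaussians, and the simulator weights each
  component by the sensitivity at its (displaced) centre — exact for
  compact components, approximate for the body ellipsoid.
* The classical segmenter is a stand-in: results say nothing about deep
  networks beyond providing the evaluation scaffolding.
* The sharpness protocol is this package's own reconstruction of an
  unavailable published method; magnitudes are not comparable to published
  values, only within-study contrasts are meaningful.
* Equal-count binning and the 0.1-0.5 Hz respiratory band are defensible
  defaults, not validated against patient data.
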