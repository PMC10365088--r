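# phyllorecon

Simulation and motion-compensated reconstruction of free-breathing
whole-heart cardiac MR, with the downstream segmentation-based evaluation
that compares the two standard respiratory strategies:

* **Mcorr** — 1D superior-inferior (SI) motion *correction*: every
  interleaf of the 3D radial spiral-phyllotaxis trajectory starts with an
  SI readout whose 1D Fourier transform is a self-navigator projection;
  cross-correlation against a reference projection gives a per-interleaf
  displacement `δ_k`, removed by the k-space phase `exp(+2πi k_z δ_k)`
  before a density-compensated gridded reconstruction of all the data.
* **Mres** — respiratory motion-*resolved* binning (the XD-GRASP
  formulation): principal component analysis of the concatenated
  multi-coil SI projections extracts the respiratory signal, interleaves
  are split into four equal-count amplitude bins (bin 1 = end-expiration),
  and the four undersampled bins are reconstructed jointly by compressed
  sensing,

  minimize over x:  Σ_b ½‖√W_b (F_b x_b − y_b)‖² + λ · Σ_b ‖x_{b+1} − x_b‖₁

  with `F_b` the per-bin non-uniform Fourier operator, `W_b` per-bin radial
  density weights, and λ = 0.1 (scale-free after normalising the data to a
  unit-maximum adjoint).

Everything runs on a synthetic, fully controlled subject: a breathing
digital thorax phantom (uniform ellipsoids with a closed-form Fourier
transform — no inverse crime), an ECG-gated interleaved phyllotaxis
acquisition (the published whole-heart protocol is 12,224 radial lines in
382 interleaves of 32 segments over a 220 mm³ field of view), Gaussian
coil sensitivities, and realistic noise. Evaluation mirrors the clinical
comparison: CLAHE post-filtering, automatic LV blood-pool segmentation (a
classical seeded segmenter standing in for learning-based methods),
absolute volume difference (AVD), 3D Dice, mid-short-axis endocardial
border sharpness, per-criterion best-bin selection, and two-tailed paired
t-tests.

The intended audience is researchers prototyping or teaching self-navigated
whole-heart reconstruction who need a controlled testbed where ground-truth
motion and anatomy are known exactly.

## Worked example

One synthetic subject, both arms, desk scale (matrix 64, 200 interleaves,
about a minute on one core):

```r
library(phyllorecon)

cfg <- experiment_config("desk", seed = 2)
sub <- run_subject(cfg)

sp <- sub$grid$spacing
dice_mcorr <- dice3d(sub$mcorr$auto, sub$manual$mcorr)
dice_bins  <- sapply(1:4, function(b) dice3d(sub$mres[[b]]$auto, sub$manual$mres[[b]]))
round(c(mcorr = dice_mcorr, best_mres = max(dice_bins)), 3)
#>     mcorr best_mres
#>     0.874     0.904

sharp_mcorr <- sharpness(sub$mcorr$volume, sub$manual$mcorr, sp)
sharp_bins  <- sapply(1:4, function(b)
  sharpness(sub$mres[[b]]$volume, sub$manual$mres[[b]], sp))
round(c(mcorr = sharp_mcorr, best_mres = max(sharp_bins)), 4)
#>     mcorr best_mres
#>    0.1012    0.1054
```

The motion-resolved best bin segments closer to ground truth (higher Dice)
and shows the crisper endocardial border (higher sharpness, in 1/mm of
20–80% edge-transition width) than the motion-corrected arm — the expected
direction: on the full default anatomy, bright static structures (chest
wall, spine, body pedestal) bias the cross-correlation shifts, and the AP
component of heart motion is invisible to a 1D SI correction, whereas the
PCA-driven binning is insensitive to static structures and freezes each bin
near one respiratory position.

A cohort with paired statistics and report files (CSV, YAML summary,
boxplot figure):

```r
report <- run_cohort(cfg, n_subjects = 6, out_dir = "study_out")
print(report)
```

File-based stage-by-stage drivers (`run_simulate`, `run_recon`,
`run_evaluate`) persist every intermediate (k-space container, NIfTI
volumes and masks, shift/bin/objective CSVs, resolved YAML config), and
each stage can be re-run from the previous one's outputs.

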