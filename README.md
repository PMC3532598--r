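# painscale

Multivariate decoding of near-threshold pain perception from fMRI, across
spatial scales.

## What this package is for

When laser stimuli are calibrated to a person's individual pain threshold,
physically identical stimulation is perceived as painful on some trials and
not on others. The scientific question is whether — and at which spatial
scale — the *subjective* perception can be decoded from distributed brain
activity: single voxels, single anatomical regions, combinations of
regions, or the whole brain. The quantity of interest is the significance
with which decoding beats chance in a group of subjects, since that
accounts for between-subject variability; accuracy magnitude alone is not
the point.

`painscale` is a tested implementation of the complete analysis chain for
this design, aimed at neuroimaging methodologists who want a reproducible,
calibrated MVPA pipeline:

- **Trial-wise GLM (beta series).** For every trial, an anticipation
  boxcar of trial-specific duration (4–8 s) and a 1 s stimulation boxcar,
  HRF-convolved and fit jointly (2T regressors, e.g. 240 for 4 sessions ×
  30 trials), with 128 s discrete-cosine high-pass filtering and pooled
  AR(1) prewhitening applied consistently to data and design.
- **Decoding.** Per-voxel standardization and per-trial l2 scaling
  (fit on training folds only), then a linear soft-margin SVM
  (in-package SMO dual solver on precomputed Gram matrices, cross-checked
  against libsvm) under leave-one-session-out cross-validation with nested
  leave-one-trial-out selection of C; run separately per threat condition
  and averaged, so condition differences cannot confound perception
  decoding.
- **Permutation inference.** Within-session label shuffles; p = rank of
  the observed accuracy in the null / N, floored at 1/N, ties counted
  against the observed value. Classifier weight maps are tested per voxel
  via t_v = (w_v − μ̂_v)/σ̂_v against the permutation null's mean and SD,
  referred to t(N−1), with Bonferroni (default) or random-field FWE
  correction, plus a Lilliefors audit of the Gaussian null summary.
- **Spatial scales.** Region ranking by significance of group accuracy,
  cumulative unions of the most predictive regions, a pain-matrix preset,
  and the voxel-count curve from the single most discriminative voxel
  (re-ranked inside every training fold) tripling up to the whole brain.
- **Synthetic data.** A generator for multi-subject datasets with the
  session/trial structure, threat factor, near-threshold labels, weak
  distributed signal, AR(1) noise and drift the analysis assumes — plus
  ground truth, so calibration (type-I error, chance centering) and
  recovery (planted regions, planted voxels) are testable.

## Worked example

Simulate a small group with signal planted in three regions, estimate beta
series, and decode:

```r
library(painscale)

atlas  <- generate_atlas(grid_shape = c(16, 16, 12), n_regions = 26,
                         n_control = 2, seed = 7)
signal <- signal_spec(atlas, regions = c("SI.L", "SI.R", "AI.R"),
                      effect_size_mean = 25, effect_size_sd = 5,
                      phase = "stimulation", noise_sd = 1, ar1_rho = 0.3)
events  <- generate_events(n_sessions = 3, trials_per_session = 10, seed = 8)
subject <- simulate_subject(events, atlas, signal, TR = 3, seed = 9)
betas   <- estimate_beta_series(subject)
decode_subject(betas, phase = "stimulation")
#> <subject_decoding> sub01 stimulation whole_brain
#>   mean accuracy: 0.8667
#>   per stratum: high=1.000  low=0.733
```

The subject value is the mean of the two threat-stratum accuracies, each
the pooled proportion of correct test-trial predictions across
leave-one-session-out folds. At the group level, with a permutation
p-value (99 within-session shuffles of every subject's labels):

```r
cfg <- study_config(n_subjects = 8, n_sessions = 3, trials_per_session = 10,
                    grid_shape = c(16, 16, 12),
                    informative_regions = c("SI.L", "SI.R", "AI.R"),
                    effect_size_mean = 25, effect_size_sd = 5, seed = 7)
sim <- simulate_group_betas(cfg)
decode_group(sim$betas, "stimulation", feature_spec("whole_brain"),
             decoding_config(), N_perm = 99, seed = 10)
#> <group_decoding> n=8  mean accuracy 0.904 +/- 0.032 (SEM)  p=0.0101
```

The group decodes at 90% with the smallest p the 99-permutation null can
resolve beyond (1/99 ≈ 0.0101 is its floor). Ranking regions by the
significance of their accuracies recovers the planted ones:

```r
reg <- decode_regions(sim$betas, "stimulation", config = decoding_config(),
                      N_perm = 99, seed = 11)
head(roi_rank_order(reg)[, c("region", "accuracy", "sem", "p")], 4)
#>    region  accuracy        sem          p
#> 1    AI.R 1.0000000 0.00000000 0.01010101
#> 2    SI.L 1.0000000 0.00000000 0.01010101
#> 3    SI.R 1.0000000 0.00000000 0.01010101
#> 4 DLPFC.L 0.5166667 0.03450328 0.25252525
```

The three planted regions decode perfectly and occupy the top ranks; all
other regions sit at chance. (`significant` flags use the Bonferroni level
α/28, which N = 99 permutations cannot reach — use
`N_perm = required_N(0.05, 28)` for corrected region-level inference.)

`scale_curve()` produces the voxel-count accuracy curve,
`weight_map_analysis()` the FWE-thresholded classifier weight t-maps, and
`run_full_study()` composes the whole pipeline (simulate → GLM → decode →
inference → weight maps) into a resumable, manifest-tracked results
directory. A thin command-line wrapper is installed as `exec/painscale`
(subcommands `simulate`, `run-all`).

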