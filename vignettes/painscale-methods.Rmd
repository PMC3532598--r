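---
title: "Decoding near-threshold pain perception: models and methods"
author: "painscale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding near-threshold pain perception: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

When a stimulus sits exactly at a person's pain threshold, physically
identical stimulation is sometimes perceived as painful and sometimes not.
Whether the *subjective* perception can be read out from distributed brain
activity — and at which spatial scale that readout works best — is a
question about structure–function mappings, not about engineering accuracy:
what matters is the *significance* with which decoding beats chance in a
group, because that significance accounts for between-subject variability.

`painscale` implements the full analysis chain for this question as a
tested, reusable pipeline:

1. **Trial-wise GLM** — single-trial activity patterns (a *beta series*)
   for the anticipation and stimulation phase of every trial.
2. **Feature preparation** — per-voxel standardization, per-trial l2
   scaling, region-of-interest masking, and fold-wise voxel ranking.
3. **Decoding** — a linear soft-margin SVM under leave-one-session-out
   (LOSO) cross-validation with nested leave-one-trial-out selection of the
   regularization hyperparameter C, run separately within each level of a
   two-level threat factor.
4. **Permutation inference** — within-session label shuffles for accuracy
   p-values at subject and group level; permutation nulls of classifier
   weights, summarized per voxel as a Gaussian and converted to t-scores
   with family-wise error correction.
5. **Spatial scales** — accuracy as a function of the feature space: the
   single most discriminative voxel, tripling voxel counts up to the whole
   brain, single anatomical regions, cumulative unions of the most
   predictive regions, and the full "pain matrix".

Because no suitable public dataset exists for this exact design, a
synthetic-data module generates groups of subjects with the statistical
structure the analysis assumes, plus the ground truth needed for recovery
tests.

## The generative model of the synthetic data

A subject is `S` sessions of `n` trials (defaults 4 × 30, TR 3 s). Each
trial has an anticipation period of trial-specific duration, uniform on
4–8 s, followed by a 1 s stimulus; inter-trial intervals are uniform on
6–10 s (the interval is not constrained by the emulated design, so this is
a stand-in choice). The perception label is Bernoulli(0.5) per trial,
independent of the threat factor, which is balanced within sessions: the
near-threshold regime is modelled as a *weak amplitude difference*, not as
a psychometric process.

Voxel time series are

\[ y_v(t) = \sum_{\text{trials, phases}} a_{j,v}\,(h * u_j)(t)
  + d_v(t) + \varepsilon_v(t), \]

where \(u_j\) is the phase's boxcar, \(h\) the canonical double-gamma HRF,
\(d_v\) a slow cosine drift (period 192–384 s, so the 128 s high-pass
filter has work to do), and \(\varepsilon_v\) stationary AR(1) noise with
lag-1 correlation \(\rho\) (default 0.3) and unit marginal SD. All atlas
voxels respond with a common baseline amplitude; in the *informative*
regions the amplitude additionally differs by ±δ/2 between painful and
non-painful trials, in the phase(s) carrying the effect. The per-subject
effect size δ is drawn once per subject from Normal(mean, sd) truncated at
zero — this induces exactly the random-effects structure the group
permutation test assumes.

Geometry is deliberately schematic: a small grid (default 24³) with 26
pain-related regions plus two control regions as disjoint cubic blocks.
The statistics under test (calibration, recovery, non-circularity) do not
depend on realistic anatomy, and everything downstream is scale-invariant
after standardization and l2 scaling, so amplitude units are arbitrary.

**What the generator does not emulate:** physiological noise and motion,
spatial noise correlations, vasculature, susceptibility artifacts, or a
psychometric threshold model. Passing tests therefore demonstrate that the
*statistical machinery* is correct and calibrated — not that real fMRI data
would yield any particular accuracy.

An important emergent property: because each trial's anticipation and
stimulation regressors overlap heavily after HRF convolution, single-trial
beta estimates carry noise several times the volume-level noise SD (a
factor of roughly 7–8 under the default timing). Effect sizes must be read
against that inflated scale. The default group effect (δ = 2 ± 0.8 between
subjects, against unit volume noise) was calibrated once so that the
default study sits in the near-threshold regime of scientific interest —
group decoding modestly above chance (roughly 55%) rather than at chance
or at ceiling; per voxel it amounts to about a quarter of the single-trial
beta noise SD.

## Trial-wise GLM

One joint GLM per subject contains, for every trial, an anticipation boxcar
of the trial-specific duration and a 1 s stimulation boxcar (2 regressors
per trial — 240 for the standard design), each convolved with the canonical
HRF on a 0.1 s microtime grid and sampled at volume onsets, plus one
constant per session. The joint ("least-squares-all") formulation was
chosen over per-trial GLMs because the 2-per-trial design describes a
single filter producing all beta images at once.

Filtering follows the standard first-level conventions: a discrete-cosine
basis up to the 128 s cutoff (including the session mean) is projected out
of both data and design, which leaves noiseless recovery exact and absorbs
the session constants; serial correlation is handled by a single AR(1)
coefficient pooled over voxels, estimated from first-pass residuals, with
both data and design prewhitened before the final fit. This one-pass
estimate-then-refit scheme is a documented simplification of iterative
restricted-likelihood schemes; the pooled estimator is bounded inside
(−1, 1), and values at the boundary are clipped to ±0.95 defensively.
Gaussian smoothing (FWHM in mm; `sigma = FWHM / (2\sqrt{2\ln 2})`) is
available as a separable convolution with edge renormalization; the
simulation default is unsmoothed because synthetic noise carries no spatial
correlation for smoothing to exploit.

## Feature preparation and non-circularity

Within every analysis the feature matrix is standardized per voxel
(population SD; zero-variance voxels are flagged and zeroed, as they carry
no information) and then each trial pattern is scaled to unit l2 norm, in
that order. Standardization parameters are fit **on the training rows of
the current fold only** and applied to all rows; likewise the voxel
ranking used by `top_voxels` feature spaces (two-sample pooled-variance
|t|, ties stable by voxel index, infinite t from zero pooled variance
sorting first) is recomputed inside every training fold.

A `scaling = "global"` switch instead fits the standardization once on all
trials before cross-validation. This replicates the common practice of
standardizing before CV, which is mildly circular; the default is the
non-circular fold-wise variant, consistent with the principle that test
data must touch neither training nor hyperparameter optimization. The test
suite enforces this with a mutation test: perturbing any test fold's
features changes no trained weight, chosen C, or scaling parameter of that
fold.

Masking and selection are applied *before* scaling, so every analysis is
self-contained: within a ROI analysis each trial's pattern has unit norm
over that ROI's voxels. (The alternative — l2-normalizing whole-brain
images once and then masking — would make each analysis depend on voxels
outside its feature space.)

## Decoding

The classifier is a linear C-SVC (hinge loss, l2 penalty) solved in the
dual by sequential minimal optimization on precomputed Gram matrices, with
maximal-violating-pair working-set selection, tolerance 10⁻⁶, and
deterministic lowest-index tie-breaking. The solver is validated in two
independent ways: its solutions satisfy the Karush–Kuhn–Tucker conditions
of the dual, and they agree with libsvm (via `e1071`) to 10⁻⁴ on random
instances. Operating on Gram matrices lets the permutation machinery cache
everything label-independent (scaling, folds, kernels) and re-run only the
label-dependent part, which is what makes calibration studies with many
thousands of full pipeline re-runs tractable on one CPU.

Outer folds are leave-one-session-out — sessions are the natural
exchangeability blocks under serial correlation. Within each outer fold, C
is chosen from the grid {10⁻³, …, 10³} (a conventional logarithmic grid;
the emulated design does not state one) by leave-one-trial-out accuracy on
the training set, ties resolving to the smallest C (the strongest
regularization among equals). Decoding runs separately per threat stratum
so that threat differences cannot masquerade as perception differences;
the subject's value is the arithmetic mean of the two stratum accuracies.

Stratum accuracy is the *pooled* proportion of correct test-trial
predictions across folds, so unequal fold sizes weight naturally; the mean
of per-fold accuracies is reported alongside. Training folds containing a
single class are skipped with a warning and the accuracy pooled over the
remaining folds; a stratum whose every fold is degenerate is an error by
default, or NA in group runs (`undecodable = "na"`), where that subject
simply drops out of the group mean for that permutation. Class imbalance
in training folds is reported, not reweighted.

## Permutation inference

Labels are always permuted **within sessions**, preserving per-session
label multisets — the exchangeability structure LOSO requires. The p-value
is the tie-inclusive rank of the observed statistic in the null, divided by
N, floored at 1/N. Ties counting against the observed value makes the test
never anticonservative at its stated level, and the floor makes 1/N the
best attainable p — hence `required_N(alpha, n_tests)`, the smallest N with
1/N ≤ alpha/n_tests, determines the permutation budget for corrected
inference (e.g. 520 for 26 regions at α = 0.05, 1000 at α = 0.001).
Group-level nulls permute every subject's labels independently and record
the group mean per permutation.

For weight maps the classifier is trained once on all trials (no CV; C
selected by leave-one-trial-out on all data unless supplied), then refit
under N within-session shuffles. Each voxel's null is summarized by its
sample mean and SD, and the observed weight is converted to
\(t_v = (w_v - \hat\mu_v)/\hat\sigma_v\), referred two-sided to
\(t_{N-1}\). Voxels with zero null SD are flagged and excluded. The
default family-wise correction is Bonferroni at α/V — deliberately
conservative; a random-field-theory threshold (expected Euler
characteristic of a t field over the search box, with per-axis smoothness
estimated from the map unless supplied) is available as `method = "rft"`,
since the exact smoothness estimator of standard neuroimaging software is
internal to that software and not reproducible from published constants.
Significant voxels are split by sign; positive weights mean higher
activity on subjectively painful trials.

**Normality audit.** The Gaussian summary is audited per voxel. The naive
KS test against a Gaussian with the *same sample's* estimated mean and SD
is far below its nominal size (the Lilliefors phenomenon) and will
essentially never reject on Gaussian data; it is provided as
`method = "ks_plugin"` because it mirrors common practice. The default is
the Lilliefors-corrected test (`nortest::lillie.test`), whose rejection
rate on Gaussian nulls equals the test size — the property the audit's own
calibration test checks.

## The spatial-scale study

Regions are ranked by the *significance* of their group accuracies (p
ascending, ties by higher accuracy, then name), not by accuracy magnitude,
with Bonferroni flags at α divided by the number of regions tested
(controls included). Cumulative feature spaces take the union of the top-k
ranked regions, plus `pain_matrix` (all non-control regions) and
`whole_brain` presets. The voxel-count curve starts at the single most
discriminative voxel and triples the count until the whole brain, which is
always appended as an explicit final point; ROI results can be overlaid on
the voxel-count axis at their mask sizes. Two curve points are compared
with a sign-flip permutation test on per-subject differences (exhaustive
when 2ⁿ is small, tie-inclusive two-sided counting otherwise).

The ROI ranking used for cumulative combinations is computed on the same
data as the combination runs, which is mildly circular at the group level;
phase-matched rankings are used for each phase. A split-half alternative
(rank on half the subjects, evaluate on the rest) can be composed from the
exported pieces, at the cost of half the evaluation subjects.

## Numerical and design choices

- SMO tolerance 10⁻⁶, iteration cap 2 × 10⁵; everything downstream of a
  fixed seed is bit-for-bit reproducible, and every run records its
  configuration and seed in a JSON manifest.
- Decision values exactly 0 predict the negative class deterministically.
- Standardization uses the divide-by-n SD so fit-set SDs are exactly 1.
- Inner CV folds whose remaining training trials are single-class are
  skipped for all candidates; if no candidate is evaluable the smallest C
  is used.
- `perm_pvalue` drops NA null entries (degenerate permutations of a group
  run) before counting.
- The `l2` step inside the decoder tolerates an all-zero trial row
  (leaves it zero) so a pathological permutation cannot abort a long null
  run; the exported `l2_normalize_trials` errors on zero rows, naming the
  trial.

## Problem sizes in tests and the acceptance script

Calibration and recovery studies run at sizes chosen as the package's own
desk-scale conditions: null calibration uses 100 independent groups of 8
subjects (2 sessions × 10 trials, no signal) with N = 99 group
permutations; signal recovery uses 10 groups on a 26 + 2 region atlas with
a large planted effect (δ = 40 against unit noise — large deliberately,
because single-trial beta noise is several times the volume noise);
weight-map checks use enumeration on a 6-trial instance, 10 planted-signal
subjects, and 200 null maps. The acceptance script runs the whole study at
16 subjects, 4 sessions × 10 trials on a 16 × 16 × 12 grid with the default
weak effect (δ = 2 ± 0.8 between subjects), i.e. the near-threshold
regime where accuracies are expected modestly above chance rather than at
ceiling.

## Known limitations

- The noise model is temporally AR(1) and spatially white; no motion,
  physiology, or spatial autocorrelation. RFT thresholds on such data are
  close to Bonferroni because the estimated smoothness is near one voxel.
- AR(1) estimates from residuals of heavily parameterized trial-wise
  designs are biased toward zero in short sessions; the whitening is
  consistent between data and design either way.
- The across-subject mean t-map is a visualization aid, not a calibrated
  group statistic (nulls are subject-specific).
- Weight maps inherit the usual caveat that large weights need not mark
  the most pain-related voxels; regional accuracy analyses are the basis
  for conclusions, weight maps are illustrative.
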