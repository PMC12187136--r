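---
title: "Measuring the temporal dynamics of working-memory codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the temporal dynamics of working-memory codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

When a person holds a grating orientation in visual working memory over a
delay of many seconds, the multivoxel fMRI pattern that encodes the
remembered orientation may stay the same ("stable coding") or transform
over time ("dynamic coding"). Distinguishing the two requires more than
decoding accuracy at each timepoint: a decoder can succeed at every
moment while the underlying code rotates completely. `vwmdyn` implements
the analysis chain used to make that distinction — a circular-label
decoder, temporal cross-decoding with nonparametric cluster statistics,
subspace geometry, voxel-reliability selection, and the control
simulations that rule out a signal-to-noise confound — together with a
synthetic-data generator whose ground truth is known exactly, so every
stage can be validated without access to empirical data.

## Periodic decoding and the FCA metric

Orientation is 180°-periodic. Labels $\theta^\circ \in [0°, 180°)$ are
wrapped onto the full circle, $\theta = 2\pi\theta^\circ/180$, and two
independent epsilon-insensitive support vector regressions with an RBF
kernel (LIBSVM via **e1071**) predict $\sin\theta$ and $\cos\theta$ from
the voxel pattern. The reconstruction is the four-quadrant inverse
tangent $\theta_p = \mathrm{atan2}(x_p, y_p)$ of the two outputs. Accuracy
per trial is the feature continuous accuracy

$$\mathrm{FCA} = \frac{\pi - \Delta x}{\pi}\cdot 100, \qquad
\Delta x = \left|(\theta - \theta_p)_{\mathrm{circ}}\right|,$$

where $\Delta x$ is the shorter arc between prediction and label. FCA is
100 for a perfect prediction, 0 for the antipodal error, and 50 in
expectation under random guessing (the expected deviation of two
independent uniform angles is $\pi/2$).

Choices worth knowing:

* **Hyperparameters.** $C = 1$, $\varepsilon = 0.1$,
  $\gamma = 1/\upsilon$ ($\upsilon$ = voxels). These are standard
  library defaults with a scale-free kernel width; they are exposed in
  `psvr_hyperparams()` rather than tuned, because hyperparameter search
  inside cross-validation folds would change what the accuracy measures.
* **Rescaling.** Each voxel is mapped to $[0,1]$ by its *training* range;
  the same affine map is applied to test data without clipping (clipping
  would distort kernel distances). A constant training voxel maps to 0.5
  with a warning.
* **Cross-validation.** Folds are sessions: train on two of three
  sessions, test on the left-out one. Because folds are defined by
  session, training and test trials are disjoint for *every* pair of
  train/test timepoints, which is the precondition for interpreting the
  cross-decoding matrix.
* **Degenerate targets.** If all training labels coincide, LIBSVM returns
  a model without support vectors; the decoder then regresses to the
  constant, which is the correct limiting behaviour.

## Temporal cross-decoding and dynamic-coding elements

`cross_decode_matrix()` trains at timepoint $i$ and tests at every $j$,
giving a $T \times T$ FCA matrix per subject. Three cluster-based
sign-permutation tests (`cluster_sign_permutation_test()`) are combined
by `dynamic_elements()`:

1. accuracies above chance ($a_{ij} - 50$, positive tail),
2. off-diagonal deficit against the train-time diagonal
   ($a_{ij} - a_{ii}$, negative tail),
3. off-diagonal deficit against the test-time diagonal
   ($a_{ij} - a_{jj}$, negative tail).

An off-diagonal element is *dynamic* when tests 2 and 3 are both
significant and both of its diagonal elements lie in an above-chance
cluster. The per-timepoint *dynamicism index* is the fraction of the
$2(T-1)$ off-diagonal elements in the corresponding row and column that
are dynamic; row and column membership is counted jointly because the
quantity of interest is "how much of this timepoint's generalization
profile fails", not its direction.

The cluster test forms clusters from elements whose one-sided,
uncorrected one-sample $t$-test across subjects has $p < 0.05$
(a configurable, field-standard cluster-forming rule), links them by
4-neighbour adjacency, and compares each cluster's summed $t$ to the
distribution of the *maximal* null cluster sum under random sign flips
of whole subject maps (1000 permutations by default). Whole-map flipping
preserves the spatial correlation of each subject's matrix, which
element-wise flipping would destroy. The observed statistic is included
in the null, so the smallest attainable $p$ is $1/(n_{\mathrm{perm}}+1)$
and $p = 0$ cannot occur. Each cluster is compared to that null
independently, without further correction across clusters.

## Neural subspaces and the above-baseline principal angle

For geometry, trials are averaged within four 45° orientation bins over
a time window, voxels are mean-centered (`bin_and_center()`), and the
top two principal components of the $\rho \times \upsilon$ matrix define
a 2-D coding plane (`compute_subspace()`; computed through the SVD of
the small matrix, the $O(\rho^3)$ dual of the voxel-covariance
eigenproblem). The alignment of two planes is their *largest* principal
angle — the arc cosine of the smallest singular value of
$V_1^\top V_2$ — between 0° and 90°. A principal-angle pair exists for
2-D subspaces; the larger one is reported because it is the conservative
measure of misalignment and matches the conventional single-angle
subspace routine.

Raw between-time angles are biased upward by estimation noise, so
`above_baseline_pa()` uses a split-half baseline: per iteration trials
are randomly halved (stratified by orientation bin; the same split
serves both time windows, and odd bins give the extra trial to the first
half), subspaces are computed per half and window, and

$$\mathrm{aPA} = \underbrace{\tfrac12\left[\angle(V_{i,A},V_{j,B}) +
\angle(V_{i,B},V_{j,A})\right]}_{\text{between}} -
\underbrace{\tfrac12\left[\angle(V_{i,A},V_{i,B}) +
\angle(V_{j,A},V_{j,B})\right]}_{\text{within}}.$$

The two split-crossings are averaged (the combiner is not dictated by
the definition; the mean is the symmetric choice), the iteration default
is 1000 splits, and identical windows give exactly zero by symmetry.
Group inference uses a one-tailed sign-flip permutation test of the
subject means (exhaustive when $2^n$ flip patterns fit the permutation
budget), and families of pairwise window comparisons are controlled with
Benjamini–Hochberg FDR (`apa_time_matrix()`). The same machinery
compares target- versus distractor-binned subspaces on delay-averaged
patterns (`target_distractor_apa()`).

## Voxel selection

`reliability_select()` keeps voxels whose six-bin (30°) tuning function,
estimated by a least-squares fit on bin indicator regressors (plus
mean-centered sum-to-zero session intercepts, which leave bin estimates
equal to bin means in balanced designs), replicates across a stratified
half-split of the trials in *both* a memory task and a perception task.
The two per-voxel split-half correlations are Fisher z-transformed
($r = \pm 1$ clamped at $\mathrm{atanh}(1 - 10^{-12})$) and must both
exceed the 75th percentile of a null distribution built from 1000
label-permuted repetitions of the identical analysis. The null is pooled
across voxels within a region — one distribution per correlation type —
matching the reading that nulls are built per participant and region; a
zero-variance tuning function yields $r := -1$ (never selected) with a
warning. Under pure noise the two criteria are approximately independent
quarter-exceedances, so the expected selection rate is
$(1 - 0.75)^2 = 6.25\%$; the suite verifies this.

## The synthetic generator

`generate_tuned_voxels()` builds a population whose voxels respond to
orientation with unit-amplitude sine or cosine functions of the doubled
angle, circularly shifted per voxel (shifts uniform on $[0°, 180°)$ —
the amplitude and shift distribution are modelling choices, not
empirical claims). `generate_experiment()` then simulates a
three-session delayed-estimation experiment: per session and condition,
orientations are drawn stratified over six 30° bins (36 trials per
condition per session, 108 in total, matching the task design the
package targets), with TR 0.8 s and a 13 s delay.

Ground-truth knobs (`dynamics_spec()`):

* **rotation_schedule** — per-timepoint mixing weight between coding
  basis A and an orthogonal basis B. The population sine/cosine loading
  vectors are orthonormalized to a common norm before signals are built;
  without this, pattern norms vary weakly with orientation, and a
  nonlinear decoder converts that norm into systematic (if
  zero-mean-across-populations) transfer between supposedly orthogonal
  codes. Basis B lives in a seeded random orthonormal complement of the
  basis-A plane.
* **distractor_subspace_overlap** $\omega \in [0,1]$ — distractor
  loadings are $\sqrt{\omega}$ on the target plane and
  $\sqrt{1-\omega}$ on a further orthogonal plane, so $\omega = 1$
  collapses the two codes and $\omega = 0$ separates them fully.
* **snr_schedule** — per-timepoint signal-to-noise ratio, *defined as
  the ratio of per-voxel signal variance to noise variance* (the term
  has no canonical definition in this context; this one is used
  consistently everywhere, including `add_noise()` and the SNR
  simulations). Noise is i.i.d. Gaussian — the standard reading of
  "white noise".

Patterns are z-scored per voxel across all trials and timepoints as the
final step, emulating the normalization of empirical pattern data.
Deliberate *non*-features: no hemodynamic response model (timepoints are
abstract TR bins, which is sufficient because every in-scope analysis
operates on z-scored pattern snapshots), no scanner noise spectra, no
behavioural responses, and the distractor loads throughout the trial
rather than only during its 11 s presentation window. Passing tests on
this generator therefore demonstrate the *statistical* correctness of
the pipeline — calibration, error control, parameter recovery — not that
empirical fMRI data meet the generator's assumptions.

## SNR simulations

Could dynamic-coding elements be an artifact of time-varying
signal-to-noise rather than a changing code? `snr_cross_decode()`
rebuilds the tuned-population simulation: per iteration, 108 of the 180
integer-degree responses are sampled without replacement for training
and independently for testing (shared orientations allowed), white noise
scales each side to its SNR level, and the decoder is trained and tested
at every level pair; seven iterations are averaged. The default level
grid $\{0.01, 0.02, 0.05, 0.1, 0.25, 0.5\}$ spans the regime where
decoding of a 200-voxel population rises from near chance to near
ceiling; on saturated grids every cell decodes near 100% and the
simulation shows nothing. In the informative regime two signatures hold:
accuracy varies more along the *training*-level axis than the test-level
axis (`axis_dependence()`), and the conjunction test finds no dynamic
elements, because an off-diagonal cell is never significantly below
*both* of its diagonal cells when only noise levels differ.
`schedule_cross_decode()` applies the same logic to any base dataset by
re-noising it along a pseudo-time noise schedule (entries in units of
the per-voxel signal SD, i.e. pseudo-time SNR $= 1/\mathrm{scale}^2$).

## Numerical and design notes

* Orientations are degrees in $[0, 180)$ everywhere, half-open bins;
  180 normalizes to 0 on input (with a warning in file I/O). Angle
  doubling happens only inside the decoder.
* Cross-decoding with a distinct training condition reuses the identical
  session folds, so within- and cross-condition matrices are paired.
* `compute_subspace()` refuses rank-deficient geometry
  (singular-value ratio below $10^{-12}$) rather than returning an
  arbitrary plane.
* Principal-angle cosines are clamped to $[0, 1]$ before `acos` to
  absorb rounding.
* All randomness flows from explicit integer seeds; regenerating a
  dataset with the same design, dynamics and seed is bit-identical, and
  the pipeline manifest records seeds and artifact hashes.
* Serialization is plain text (TSV + JSON sidecar) at full double
  precision; `write_dataset()`/`read_dataset()` round-trip exactly.

## Problem sizes used by the test-suite

The suite validates statistical claims on compact synthetic designs
chosen so that Monte-Carlo checks remain affordable while keeping every
structural property of the full design: typically 3 sessions × 24 trials
(72 per condition), 40 voxels, 6 timepoints, 6-subject groups, 20
replicate groups for calibration rates, and reduced split/permutation
counts where only determinism (not resolution) is at stake. Single
datasets show sizeable dispersion in cross-basis transfer accuracy
(per-voxel normalization interacting with the nonlinear kernel), so
chance-level claims are asserted on seed or group means at
Monte-Carlo-appropriate tolerances.

## Known limitations

* The RBF decoder is the only decoder; linear or inverted-encoding
  alternatives are out of scope.
* Subspaces are fixed at two dimensions; higher-dimensional geometry is
  not measured.
* The generator's distractor and rotation constructions are linear;
  nonlinear code transformations would require a different ground truth.
* Cluster inference assumes exchangeability of subject maps under sign
  flipping (symmetric null); heavily skewed group effects would violate
  it.
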