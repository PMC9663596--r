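---
title: "Voxel-wise encoding and decoding of diverse cognitive tasks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise encoding and decoding of diverse cognitive tasks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxcog)
```

## The modeling framework

`voxcog` implements a voxel-wise modeling pipeline for fMRI experiments in
which subjects perform a large battery of short cognitive tasks (the
emulated sessions use 103 tasks of 6–12 s across 12 training and 6 test
runs, TR = 2 s). Two linear models anchor everything:

**Encoding.** Each voxel's time course is modeled from task indicators with
a finite-impulse-response (FIR) delay basis. The one-hot task matrix
$F\ [T \times N]$ is shifted by 2, 4 and 6 s and concatenated into
$F_E\ [T \times 3N]$, and the response $R\ [T \times V]$ is fit as
$\hat R = F_E W_E$ by L2-regularized (ridge) regression. The FIR basis
absorbs the slow hemodynamic response without committing to a fixed
response shape. Prediction accuracy is the per-voxel Pearson correlation
between prediction and measurement on the held-out test runs, whose four
repetitions are averaged beforehand to raise SNR. Significance comes from
the exact null of a sample correlation between independent Gaussian
vectors (evaluated through the t-transform with $n-2$ df), with
Benjamini–Hochberg FDR across voxels at $q < 0.05$.

**Decoding.** The transpose direction: delayed voxel responses
$R_D\ [T \times 3V]$ predict a continuous feature vector,
$\hat F_D = R_D W_D$, with the same ridge machinery.

Between the two sits the **cognitive transform function (CTF)**: each
task's delay-averaged weight map is correlated with the term maps of a
meta-analytic atlas (715 reverse-inference-style maps), giving a
tasks × terms matrix. Per subject, the CTF is the average of the *other*
subjects' matrices, so a subject's cognitive-factor features
(`apply_ctf`) never depend on their own data. Because the CTF places
every task in a shared continuous space, a decoder trained on 80% of the
tasks can score tasks it has never seen — the novel-task analysis.

## Regularization

A single ridge penalty is shared by all voxels of a fit. The grid is the
18 powers of two $2^0 \dots 2^{17}$; the source procedure states 18
values "ranging from 1 to $2^{17}$" without the spacing, and log-spaced
powers of two are the only 18-point grid with those endpoints that
matches standard practice. Two selectors are provided:

* `select_alpha_cv()` — 10-fold cross-validation maximizing the mean
  held-out correlation. Folds are *contiguous temporal blocks*, not
  shuffled bins: BOLD noise is autocorrelated, and shuffled folds leak
  information across the train/validation boundary. (The fold type was a
  genuinely open choice; blocks are the conservative one.)
* `select_alpha_resampling()` — 50 random 80/20 splits per subject, with
  scores averaged across subjects before the argmax. This yields one
  shared penalty for group analyses, keeping weight scales comparable
  across subjects. The same split sequence is reused for every subject so
  that identical subjects reproduce a single-subject selection exactly.

The solver eigendecomposes whichever Gram matrix is smaller ($X'X$ or
$XX'$), so a whole grid costs one decomposition; solving all voxels
jointly is algebraically identical to per-voxel fits.

## Representational similarity and cognitive spaces

Group analyses concatenate each subject's significant voxels
(delay-averaged weights, $q < 0.05$) into one tasks × voxels matrix. The
RSM is the task-pair Pearson correlation of the rows; tasks are ordered
by single-linkage clustering of $1 - r$ ("minimum distance" linkage), and
a rank-percentile transform (midranks for ties, mapped to [0, 100]) is
available for display. Regions are compared by the Spearman correlation
over the $T(T-1)/2$ unique off-diagonal pairs (5,253 for 103 tasks) plus
the SD of each region's similarities. Leaf order within single linkage is
not unique; the package fixes it by `stats::hclust`'s deterministic
tie-breaking, and no result depends on the particular leaf order.

PCA treats tasks as observations and voxels as variables, removing the
mean task map first (centering is required for explained-variance ratios
to mean anything; the source text does not state it). Task-side
coordinates are loadings, voxel-side coordinates scores; each PC's sign
is fixed so its largest-magnitude task loading is positive. The 2-D
cognitive space plots PC1/PC2 loadings with RGB colors from
min-max-normalized PC1–3 loadings ("normalized loadings" left the formula
open; per-channel min-max is the choice). PC score maps are z-scored per
subject — z-scores rather than min-max, because correlation with term
maps, the downstream use, is invariant to the affine choice and z-scores
keep degenerate channels well-defined.

## Novel-task decoding

Tasks are split into 5 groups (20–21 tasks each at full scale). For each
group, training timepoints inside a target-task trial **or within 6 s
after its offset** are dropped; at test only those timepoints are used.
Decoded vectors from the five group models are averaged where timepoints
are claimed by more than one group. Each decoded timepoint is correlated
with every CTF row (the *task score*); scores are averaged over each
task's timepoints; and the one-vs-one accuracy is the fraction of the
remaining $N-1$ tasks the target out-scores within its own timepoints
(ties count 0.5 — the source is silent; half-credit is the symmetric
convention). Whether comparisons use time-averaged or per-timepoint
scores was ambiguous; the time-averaged form is the default and the
`cross_scores` matrix exposes everything needed for the alternative.

Per task, significance is a one-sided exact sign test over the binary
comparisons (FDR-corrected across tasks). The mean accuracy and mean
task score are tested by permuting task labels over whole test trials
(preserving within-trial temporal structure) — 5,000 permutations at
full scale, fewer in the test suite — with the add-one estimator
$(1 + \#\{null \ge obs\})/(1 + n)$ so permutation p-values are never 0.

## Sensorimotor control and reconstruction

`flag_sensorimotor_voxels()` fits encoding models from sensorimotor
features (button-response counts are built in; visual/auditory feature
matrices can be supplied as plain time × feature matrices) on 50 random
80/20 splits of the training data and flags voxels with mean validation
accuracy ≥ 0.3 (0.2/0.1 as alternatives). Flagged voxels can be excluded
from any downstream analysis through the same voxel-selection path.

Voxel-to-voxel reconstruction compresses a source region's responses by
PCA (2,000 components at full scale) and uses the projections — delayed
like any feature matrix, since the source procedure says the models are
built "similarly" to encoding models; a no-delay flag exists — to predict
cortical voxels. The PCA basis is estimated on training timepoints only,
a leakage guard the source does not spell out. Subtracting the
per-timepoint global mean over all voxels is the control for common
additive signals.

## The synthetic generator

Every analysis is exercised on synthetic data with the statistical
structure the models assume:

* **Design**: multi-run sessions with 6–12 s trials, 2-s feedbacks
  (about 11 per run), 6-s rests opening and closing each run; training
  runs use pseudorandomized task order; test runs repeat one fixed task
  order four times, with end rests and a couple of extra feedback bins
  marked as discarded so the retained test timeline divides into
  identical repetitions. At full scale this reproduces 3,336 training and
  4 × 412 test samples. The 6-s opening rest can be counted or discarded
  via `discard_initial_rest`; counting it is the default because that is
  the convention consistent with 3,336 = 12 × 278 samples.
* **Ground truth**: per-region task × voxel weights whose representational
  geometries correlate across regions at a requested level. Latent task
  profiles mix shared and region-specific Gaussians (shared weight
  $s^{1/4}$ makes the RSM-element correlation equal the dial $s$) and are
  projected through per-region orthonormal, zero-column-mean bases so the
  true-weight RSM equals the latent cosine matrix exactly. The dial is
  verified at generation time with the package's own RSA comparison
  (tolerance ±0.05, bounded retries).
* **Responses**: delayed task design × true weights with FIR amplitudes
  (0.5, 1, 0.5) — by default the simulator uses exactly the model's delay
  basis, which makes parameter recovery well-posed; slow cosine drift
  (180–360 s periods) removable by the 120-s median-filter detrend;
  i.i.d. Gaussian noise scaled per voxel to the requested SNR; optional
  button-press-driven voxels for the sensorimotor control.
* **Term atlas**: term maps as Gaussian mixtures of the true task maps
  blended with noise; `alignment = 1` spans the task space (novel-task
  decoding is possible), `alignment = 0` severs it (decoding falls to
  chance).

What the generator does **not** emulate: physiological noise spectra,
motion artifacts, spatial noise correlations, hemodynamic variability
across voxels, and dependencies between related tasks (trials are packed
greedily with jitter; the "dependent tasks presented close in time"
property of the real sessions is not modeled). Passing tests therefore
demonstrate correctness of the estimators under their own assumptions,
not robustness to real-data pathologies. An optional mismatch between
simulated hemodynamics and the FIR basis is deliberately out of the
default path for the same reason.

## Problem sizes and numerical choices

The desk-scale study conditions used throughout the test suite and the
acceptance script are 24 tasks over 4 training + 2 test runs of 480 s
(960 training samples; four 118-sample test repetitions; about 8 training
instances per task, the same per-task exposure as the full-scale
sessions) with 2,000 cortex / 600 cerebellum / 300 subcortex voxels at
SNR 1 — region sizes scaled from the full-scale voxel counts at roughly
1:30. Group-level recovery checks simulate six subjects, the emulated
sessions' subject count, with the resampling-shared penalty. PCA compression uses 100 components in the reconstruction
analyses. Full scale is a configuration choice, not a code path.

Degenerate inputs are guarded explicitly: constant voxels z-score to 0;
zero-variance rows correlate to 0 (with a warning); a degenerate PC color
channel pins at 0.5; ties in alpha selection resolve to the first
maximum; runs shorter than the median-filter window fall back to a
run-length window with a warning.

## Known limitations

* **The per-task sign test is anticonservative under exchangeable nulls.**
  Its $N-1$ one-vs-one comparisons all share the target task's
  time-averaged score, so under label shuffling the win count is the rank
  of one exchangeable value within its score row — uniform on
  $\{0, \dots, N-2\}$ — rather than $\mathrm{Binomial}(N-1, 1/2)$. The
  binomial tail decays much faster than the uniform, so small p-values are
  over-produced: at 24 tasks roughly a third of shuffled tasks reach
  nominal $p < 0.05$, and an elevated fraction survives FDR. The test is
  retained because it is the field's convention for this metric and is
  informative when observed accuracies are near 1, but calibrated
  inference about decoding should rest on the label-permutation test of
  the mean accuracy / mean task score, which is exact by construction.


* The generator's trial packing cannot honor arbitrary run durations with
  repetition structure; infeasible combinations fall back to a
  single-pass test split or raise a capacity error.
* Group RSMs at low SNR attenuate cross-region correlations below the
  generator's dial (weight-estimation noise is region-independent);
  at the desk-scale conditions this bias is within ±0.1.
* **The median-filter detrend removes some task signal.** With nearly
  continuous task presentation, the 120-s running median tracks genuine
  inter-task signal fluctuations and subtracts them. On noiseless
  synthetic data the fitted-weight RSM recovers the true RSM at
  $\rho \approx 1$ without the filter but only $\approx 0.91$ with it, and
  because the distortion is driven by the (shared) design and signal, it
  is identical across subjects and does not average out in group
  concatenation. Its size depends on the particular drawn design and
  geometry: at SNR 1, desk-scale RSM recovery ranges from
  $\rho \approx 0.90$ (unfavorable draws) to $\approx 0.96$ across seeds.
* A single ridge penalty is shared across all feature spaces; banded or
  grouped regularization is out of scope.
* Sensorimotor flagging with only button features leaves visual/auditory
  components uncontrolled; richer feature matrices must be supplied
  externally.
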