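# voxcog

Voxel-wise encoding and decoding models for multitask fMRI experiments.

Large task batteries (on the order of a hundred short cognitive tasks)
make it possible to ask *quantitative* questions about how cognitive
functions are organized across brain structures: does the cerebellum
carry the same task geometry as the cortex? Can a task a decoder never
saw be identified from cerebellar activity alone? How much cortical
activity can be reconstructed from subcortical signals? `voxcog`
implements the full analysis stack behind such questions, for
methods-oriented researchers who want a tested, reusable pipeline they
can run on their own region-labelled response matrices — or on synthetic
data with known ground truth.

## What it implements

* **Encoding models** — each voxel's response is modeled as
  `R_hat = F_E W_E`, where `F_E [T x 3N]` concatenates one-hot task
  features at hemodynamic delays of 2, 4, 6 s, and `W_E` is estimated by
  ridge regression. The penalty is chosen from the 18-value grid
  `2^0 ... 2^17` by 10-fold block cross-validation, or by 50x 80/20
  resampling pooled across subjects for group analyses. Accuracy is the
  per-voxel Pearson `r` on repetition-averaged test data, with p-values
  from the exact Gaussian-vector null and BH-FDR across voxels.
* **Representational similarity analysis** — task x task correlations of
  group-concatenated, delay-averaged weights; single-linkage task
  ordering on `1 - r`; rank-percentile display transform; cross-region
  comparison by Spearman `rho` over the `T(T-1)/2` unique pairs.
* **PCA cognitive spaces** — tasks-as-observations PCA of the weight
  matrix; 2-D task maps colored by normalized PC1-3 loadings; per-subject
  z-scored PC score maps; interpretation by correlating score maps with a
  term atlas (top/bottom-10 terms per component); subregion selectivity
  profiles.
* **Cognitive transform function (CTF) decoding** — tasks x terms
  correlation matrices built leave-one-subject-out; ridge decoders
  `F_hat = R_D W_D` from delayed responses to cognitive-factor features;
  novel-task cross-validation over 5 task groups with exact exclusion of
  target-task timepoints (+6 s); task scores, one-vs-one accuracy
  (chance 0.5), one-sided sign tests with FDR, and label-permutation
  tests of the means.
* **Sensorimotor control** — voxels reliably predicted (mean `r >= 0.3`
  over 50 resampled fits) from sensorimotor features (button responses
  built in, visual/auditory supplied as matrices) can be excluded
  end-to-end.
* **Voxel-to-voxel reconstruction** — PCA-compressed responses of one
  region (fit on training timepoints only) predict another region's
  voxels, with a global-mean-subtraction control.
* **Synthetic data** — designs, multi-region ground-truth weights with a
  controllable cross-region geometry dial, delayed noisy responses, and
  term atlases, so the whole pipeline is testable with no imaging data.

## Worked example

```r
library(voxcog)

design <- generate_design(n_tasks = 12, n_train_runs = 3, n_test_runs = 2,
                          run_duration_s = 360, seed = 1)
design
#> <cog_design> 12 tasks, 3 train + 2 test runs of 360 s (TR 2 s)
#>   trials: 156; test repetitions: 4
#>   samples: 540 train, 88 test per repetition

truth <- generate_ground_truth(design,
  regions_spec = c(cortex = 300, cerebellum = 120, subcortex = 60),
  cross_region_similarity = 0.8, snr = 1, seed = 2)
resp <- preprocess_responses(simulate_responses(design, truth, noise_seed = 3))

bins  <- design_bins(design)
train <- bins$split == "train" & bins$keep
test  <- bins$split == "test"  & bins$keep
feats <- build_task_features(design)
fd    <- delay_expand(feats, run_index = bins$run_id)

alpha <- select_alpha_cv(fd$data[train, ], resp$data[train, ])
fit   <- ridge_fit(fd$data[train, ], resp$data[train, ], as.numeric(alpha),
                   feature_names = feats$feature_names)
ev    <- evaluate_encoding(fit, fd$data[test, ], resp$data[test, ],
                           pos = bins$pos[test])
mean(ev$r); sum(ev$significant)
#> mean prediction accuracy r = 0.832; 480/480 voxels significant (q < 0.05)

w       <- delay_average_weights(fit)
rsm_ctx <- compute_rsm(w[, truth$voxel_meta$region == "cortex"])
rsm_cb  <- compute_rsm(w[, truth$voxel_meta$region == "cerebellum"])
compare_rsms(rsm_ctx, rsm_cb)$rho
#> cortex vs cerebellum RSM: Spearman rho = 0.772 over 66 task pairs
```

The one-subject, 12-task example recovers the planted cross-region
geometry (dial 0.8) up to the attenuation expected from weight-estimation
noise at SNR 1; the group-level path (`group_task_weights` over several
subjects) tightens this considerably. `run_pipeline(default_config())`
chains every stage — encoding, RSA, cognitive spaces, CTF decoding,
reconstruction — and writes TSV tables plus a JSON manifest.

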