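# Shared fixtures, built in code. Small objects are constructed eagerly;
# the desk-scale "study" fixture (24 tasks, 2000/600/300 voxels, SNR 1) is
# memoized because several test files exercise it.

tiny_design <- function(seed = 0L) {
  generate_design(n_tasks = 6, n_train_runs = 2, n_test_runs = 1,
                  run_duration_s = 120, seed = seed)
}

small_design <- function(seed = 1L) {
  generate_design(n_tasks = 12, n_train_runs = 3, n_test_runs = 2,
                  run_duration_s = 360, seed = seed)
}

small_regions <- c(cortex = 300, cerebellum = 120, subcortex = 60)

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) assign(key, builder(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# Desk-scale study conditions used by the recovery and decoding checks:
# 24 tasks over 4 train + 2 test runs of 480 s (960 training samples, four
# 118-sample test repetitions, ~8 training instances per task), 2,000 /
# 600 / 300 voxels, SNR 1, geometry dial 0.8, aligned 715-term atlas, six
# subjects (the emulated sessions' subject count) with the shared
# regularization chosen by cross-subject resampling.
study_fixture <- function() {
  memo("study", function() {
    design <- generate_design(24, 4, 2, 480, seed = 1)
    truth <- generate_ground_truth(
      design, regions_spec = c(cortex = 2000, cerebellum = 600, subcortex = 300),
      cross_region_similarity = 0.8, snr = 1, seed = 2)
    atlas <- generate_term_atlas(truth, n_terms = 715, alignment = 1, seed = 3)
    subjects <- lapply(simulate_subjects(design, truth, 6, seed = 10),
                       preprocess_responses)
    bins <- design_bins(design)
    feats <- build_task_features(design)
    fd <- delay_expand(feats, run_index = bins$run_id)
    train <- bins$split == "train" & bins$keep
    test <- bins$split == "test" & bins$keep
    alpha <- as.numeric(select_alpha_resampling(
      lapply(subjects, function(s)
        list(x = fd$data[train, ], y = s$data[train, ])),
      n_rep = 10, seed = 4))
    fits <- lapply(subjects, function(s)
      ridge_fit(fd$data[train, ], s$data[train, ], alpha,
                feature_names = feats$feature_names))
    evals <- mapply(function(f, s)
      evaluate_encoding(f, fd$data[test, ], s$data[test, ],
                        pos = bins$pos[test]),
      fits, subjects, SIMPLIFY = FALSE)
    list(design = design, truth = truth, atlas = atlas, subjects = subjects,
         bins = bins, feats = feats, fd = fd, train = train, test = test,
         alpha = alpha, fits = fits, evals = evals)
  })
}

# Two-region response object with a shared low-rank latent signal, used by
# the voxel-to-voxel reconstruction checks. The latent time courses are
# AR(1)-smooth (hemodynamic signals are strongly autocorrelated), which is
# what makes them predictable through the delayed feature basis.
ar1_latent <- function(t_total, k, phi = 0.95) {
  e <- matrix(rnorm(t_total * k), t_total, k) * sqrt(1 - phi^2)
  out <- apply(e, 2, function(v) as.numeric(stats::filter(v, phi,
                                                          "recursive")))
  matrix(out, t_total, k)
}

shared_latent_responses <- function(n_latent = 10, v_src = 60, v_tgt = 80,
                                    noise = 0.05, seed = 21,
                                    src_independent = FALSE, phi = 0.95) {
  design <- small_design()
  bins <- design_bins(design)
  set.seed(seed)
  t_total <- nrow(bins)
  lat <- ar1_latent(t_total, n_latent, phi)
  lat_src <- if (src_independent) ar1_latent(t_total, n_latent, phi) else lat
  src <- lat_src %*% matrix(rnorm(n_latent * v_src), n_latent) +
    noise * matrix(rnorm(t_total * v_src), t_total)
  tgt <- lat %*% matrix(rnorm(n_latent * v_tgt), n_latent) +
    noise * matrix(rnorm(t_total * v_tgt), t_total)
  structure(list(
    data = cbind(tgt, src),
    voxel_meta = data.frame(
      region = rep(c("cortex", "cerebellum"), c(v_tgt, v_src)),
      subregion = "x", subject_id = "sub01"),
    run_index = bins$run_id, split = bins$split, keep = bins$keep,
    bins = bins, tr_s = design$tr_s,
    n_test_repetitions = design$n_test_repetitions, preprocessed = TRUE),
    class = "cog_responses")
}

region_group_weights <- function(st, region) {
  sel <- st$truth$voxel_meta$region == region
  fits_rg <- lapply(st$fits, function(f) {
    f$weights <- f$weights[, sel, drop = FALSE]; f
  })
  evals_rg <- lapply(st$evals, function(e) list(q = e$q[sel]))
  gw <- group_task_weights(fits_rg, evals_rg)
  rownames(gw) <- st$design$task_names
  gw
}
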