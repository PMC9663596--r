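# End-to-end orchestration: synthetic generation -> preprocessing ->
# encoding -> RSA -> cognitive spaces -> CTF decoding -> reconstruction,
# with TSV outputs and a machine-readable summary manifest.

#' Default pipeline configuration
#'
#' Desk-scale settings: 24 tasks over 4 training and 2 test runs of 480 s
#' (960 training samples, 118 test samples per repetition, 4 repetitions),
#' 2,000 cortex / 600 cerebellum / 300 subcortex voxels, SNR 1, three
#' subjects, a 715-term atlas fully aligned with the task space, the
#' 18-value regularization grid, 5 task groups, and FDR q < 0.05. Any field
#' can be overridden through `run_pipeline(config = modifyList(...))`.
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    n_tasks = 24, n_train_runs = 4, n_test_runs = 2, run_duration_s = 480,
    tr_s = 2, n_test_repetitions = 4,
    regions = c(cortex = 2000, cerebellum = 600, subcortex = 300),
    cross_region_similarity = 0.8, snr = 1, drift_amplitude = 0.5,
    br_frac = 0.1, br_gain = 2,
    n_subjects = 3, n_terms = 715, atlas_alignment = 1,
    grid = alpha_grid(), n_folds = 10, n_resample = 20,
    fdr_q = 0.05, sensorimotor_threshold = 0.3, sensorimotor_reps = 20,
    exclude_sensorimotor = FALSE,
    n_pcs = 5, n_task_groups = 5, window_s = 6,
    n_perm = 500, k_pca = 100, global_mean_control = FALSE,
    design_seed = 1L, truth_seed = 2L, noise_seed = 10L, atlas_seed = 3L,
    group_seed = 4L, perm_seed = 5L, resample_seed = 6L)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full synthetic-data analysis pipeline
#'
#' Generates a design, ground truth, term atlas and multi-subject
#' responses, then runs preprocessing, encoding-model fitting (shared
#' regularization via 80/20 resampling across subjects), per-region RSA,
#' PCA cognitive spaces with term-based interpretation, leave-one-
#' subject-out CTF construction, novel-task decoding per region (optionally
#' after excluding sensorimotor voxels), and voxel-to-voxel reconstruction
#' of cortical activity. Deterministic given the seeds in `config`.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Optional directory for TSV outputs and `manifest.json`;
#'   outputs of completed stages are preserved if a later stage fails.
#' @param verbose Print stage progress.
#' @return List with all stage results and the `summary` manifest list.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         verbose = FALSE) {
  cfg <- utils::modifyList(default_config(), config)
  say <- function(...) if (verbose) message(...)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(name, m) {
    if (!is.null(out_dir)) write_matrix_tsv(m, file.path(out_dir, name))
  }

  say("generating design / truth / responses")
  design <- stage("design", generate_design(
    cfg$n_tasks, cfg$n_train_runs, cfg$n_test_runs, cfg$run_duration_s,
    seed = cfg$design_seed, tr_s = cfg$tr_s,
    n_test_repetitions = cfg$n_test_repetitions))
  truth <- stage("truth", generate_ground_truth(
    design, regions_spec = cfg$regions,
    cross_region_similarity = cfg$cross_region_similarity,
    snr = cfg$snr, drift_amplitude = cfg$drift_amplitude,
    br_frac = cfg$br_frac, br_gain = cfg$br_gain, seed = cfg$truth_seed))
  atlas <- stage("atlas", generate_term_atlas(
    truth, n_terms = cfg$n_terms, alignment = cfg$atlas_alignment,
    seed = cfg$atlas_seed))
  subjects <- stage("simulate", simulate_subjects(
    design, truth, cfg$n_subjects, seed = cfg$noise_seed))
  subjects <- stage("preprocess", lapply(subjects, preprocess_responses))

  say("fitting encoding models")
  bins <- design_bins(design)
  train <- bins$split == "train" & bins$keep
  test <- bins$split == "test" & bins$keep
  pos <- bins$pos[test]
  feats <- build_task_features(design)
  fd <- delay_expand(feats, run_index = bins$run_id)
  enc <- stage("encoding", {
    xy <- lapply(subjects, function(s)
      list(x = fd$data[train, ], y = s$data[train, ]))
    alpha_shared <- as.numeric(select_alpha_resampling(
      xy, grid = cfg$grid, n_rep = cfg$n_resample, seed = cfg$resample_seed))
    fits <- lapply(subjects, function(s)
      ridge_fit(fd$data[train, ], s$data[train, ], alpha_shared,
                feature_names = feats$feature_names,
                voxel_meta = s$voxel_meta))
    evals <- mapply(function(f, s)
      evaluate_encoding(f, fd$data[test, ], s$data[test, ], pos = pos,
                        q_threshold = cfg$fdr_q),
      fits, subjects, SIMPLIFY = FALSE)
    list(alpha = alpha_shared, fits = fits, evals = evals)
  })

  say("representational similarity analysis")
  regions <- names(cfg$regions)
  rsa <- stage("rsa", {
    gw <- list(); rsms <- list()
    for (rg in regions) {
      rsel <- truth$voxel_meta$region == rg
      fits_rg <- lapply(enc$fits, function(f) {
        f$weights <- f$weights[, rsel, drop = FALSE]; f
      })
      evals_rg <- lapply(enc$evals, function(e) list(q = e$q[rsel]))
      gw[[rg]] <- tryCatch(
        suppressWarnings(group_task_weights(fits_rg, evals_rg, cfg$fdr_q)),
        error = function(e) {
          warning("no predictive voxels in ", rg, "; using all voxels")
          group_task_weights(fits_rg, lapply(evals_rg, function(e2)
            list(q = rep(0, length(e2$q)))), cfg$fdr_q)
        })
      rownames(gw[[rg]]) <- design$task_names
      rsms[[rg]] <- compute_rsm(gw[[rg]], region = rg)
    }
    ord <- cluster_task_order(rsms[[1]])$order
    cmp <- list()
    if (length(regions) >= 2) {
      prs <- utils::combn(regions, 2)
      for (j in seq_len(ncol(prs))) {
        cc <- compare_rsms(rsms[[prs[1, j]]], rsms[[prs[2, j]]])
        cmp[[paste(prs[, j], collapse = "_vs_")]] <- cc
      }
    }
    for (rg in regions) emit(paste0("rsm_", rg, ".tsv"), rsms[[rg]]$matrix)
    list(group_weights = gw, rsms = rsms, task_order = ord,
         comparisons = cmp,
         sd = vapply(regions, function(rg)
           stats::sd(rsms[[rg]]$matrix[upper.tri(rsms[[rg]]$matrix)]),
           numeric(1)))
  })

  say("cognitive spaces")
  cogspace <- stage("cogspace", {
    out <- list()
    for (rg in regions) {
      gwr <- rsa$group_weights[[rg]]
      npc <- min(cfg$n_pcs, nrow(gwr) - 1, ncol(gwr))
      sp <- fit_cognitive_space(gwr, n_pcs = npc)
      m2d <- map_tasks_2d(sp)
      subj_of <- attr(gwr, "subject"); vox_of <- attr(gwr, "voxel")
      smap <- pc_score_map(sp, subjects = subj_of, subject_id = 1)
      gvox <- which(truth$voxel_meta$region == rg)[vox_of[subj_of == 1]]
      atlas_rg <- atlas
      atlas_rg$term_maps <- atlas$term_maps[, gvox, drop = FALSE]
      interp <- interpret_pcs(smap, atlas_rg)
      emit(paste0("cogspace_map_", rg, ".tsv"),
           as.matrix(m2d[, c("x", "y", "r", "g", "b")]))
      out[[rg]] <- list(space = sp, map2d = m2d, interpretation = interp)
    }
    out
  })

  say("CTF construction")
  weight_maps <- lapply(enc$fits, delay_average_weights)
  ctfs <- stage("ctf", lapply(names(subjects), function(sid)
    build_ctf(weight_maps, atlas, sid)))
  names(ctfs) <- names(subjects)

  say("novel-task decoding")
  decoding <- stage("decoding", {
    out <- list()
    for (sid in names(subjects)) {
      s <- subjects[[sid]]
      excl <- NULL
      if (isTRUE(cfg$exclude_sensorimotor)) {
        br <- delay_expand(build_br_features(design), run_index = bins$run_id)
        excl_all <- flag_sensorimotor_voxels(
          br$data[train, ], s$data[train, ], n_rep = cfg$sensorimotor_reps,
          threshold = cfg$sensorimotor_threshold, seed = cfg$perm_seed)
        excl <- excl_all
      }
      for (rg in regions) {
        rsel <- truth$voxel_meta$region == rg
        alpha_dec <- as.numeric(select_alpha_cv(
          delay_expand(s$data[, rsel, drop = FALSE],
                       run_index = s$run_index, tr_s = s$tr_s)$data[train, ],
          apply_ctf(feats, ctfs[[sid]])$data[train, ],
          grid = cfg$grid, n_folds = 5))
        res <- decode_novel_tasks(
          s, design, ctfs[[sid]], region = rg,
          voxel_exclude = if (is.null(excl)) NULL else excl[rsel],
          n_groups = cfg$n_task_groups, group_seed = cfg$group_seed,
          window_s = cfg$window_s, alpha = alpha_dec,
          n_perm = cfg$n_perm, seed = cfg$perm_seed)
        out[[sid]][[rg]] <- res
        emit(paste0("decoding_", rg, "_", sid, ".tsv"),
             cbind(accuracy = res$accuracy, task_score = res$task_score,
                   p = res$p_sign, q = res$q))
      }
    }
    out
  })

  say("reconstruction of cortical activity")
  recon <- stage("reconstruction", {
    out <- list()
    for (sid in names(subjects)) {
      s <- subjects[[sid]]
      if (isTRUE(cfg$global_mean_control)) s <- subtract_global_mean(s)
      cb <- pca_reduce_responses(s, "cerebellum", cfg$k_pca)
      sc <- pca_reduce_responses(s, "subcortex",
                                 min(cfg$k_pca, cfg$regions[["subcortex"]] - 1))
      m_cb <- fit_voxel2voxel(cb, s)
      m_sc <- fit_voxel2voxel(sc, s)
      m_both <- fit_voxel2voxel(list(cb, sc), s)
      out[[sid]] <- list(
        variance_retained = c(cerebellum = cb$variance_retained,
                              subcortex = sc$variance_retained),
        accuracy = c(cerebellum = mean(m_cb$result$r),
                     subcortex = mean(m_sc$result$r),
                     both = mean(m_both$result$r)),
        frac_significant = c(cerebellum = mean(m_cb$result$significant),
                             subcortex = mean(m_sc$result$significant),
                             both = mean(m_both$result$significant)))
    }
    out
  })

  summary <- list(
    config = cfg[c("n_tasks", "n_train_runs", "n_test_runs",
                   "run_duration_s", "snr", "cross_region_similarity",
                   "n_subjects")],
    samples = design_sample_counts(design),
    encoding_alpha = enc$alpha,
    rsm_rho = lapply(rsa$comparisons, `[[`, "rho"),
    rsm_sd = as.list(rsa$sd),
    mean_decoding_accuracy = lapply(decoding, function(s)
      lapply(s, `[[`, "mean_accuracy")),
    mean_task_score = lapply(decoding, function(s)
      lapply(s, `[[`, "mean_score")),
    reconstruction = recon)
  if (!is.null(out_dir)) {
    json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = 10,
                             pretty = TRUE)
    writeLines(json, file.path(out_dir, "manifest.json"))
  }
  list(design = design, truth = truth, atlas = atlas, encoding = enc,
       rsa = rsa, cogspace = cogspace, ctfs = ctfs, decoding = decoding,
       reconstruction = recon, summary = summary)
}
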