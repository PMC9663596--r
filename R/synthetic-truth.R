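# Ground-truth task weights with a controllable cross-region representational
# geometry, simulated delayed responses, and a synthetic term atlas emulating
# meta-analytic reverse-inference maps.

# Projection from latent task space to voxel space: rows orthonormal (scaled
# by sqrt(V)) and orthogonal to the constant vector, so that the Pearson
# correlation between task rows of W = T M equals the cosine of the latent
# rows exactly, identically in every region.
latent_projection <- function(n_voxels, n_latent) {
  if (n_voxels < n_latent + 1)
    stop("need at least n_latent + 1 voxels per region (got ", n_voxels, ")")
  m <- cbind(1, matrix(stats::rnorm(n_voxels * n_latent), n_voxels))
  q <- qr.Q(qr(m))[, 2:(n_latent + 1), drop = FALSE]
  t(q) * sqrt(n_voxels)
}

default_subregions <- function(region, n) {
  labels <- switch(region,
    cortex = sprintf("ctx_%d", 1:8),
    cerebellum = sprintf("MDTB_%d", 1:10),
    subcortex = c("hippocampus_L", "hippocampus_R", "caudate_L", "caudate_R",
                  "amygdala_L", "amygdala_R", "thalamus_L", "thalamus_R"),
    sprintf("%s_%d", region, 1:6))
  labels[(seq_len(n) - 1) %% length(labels) + 1][order(rep(seq_along(labels),
    length.out = n))]
}

#' Generate ground-truth task weights for multiple brain regions
#'
#' Draws per-region task x voxel weight matrices whose representational
#' geometries (task-by-task similarity structure) correlate across regions
#' at a requested level. Latent task profiles mix a shared and a
#' region-specific Gaussian component (with weight `s^(1/4)` on the shared
#' part, which makes the element-wise correlation of two regions'
#' similarity matrices equal the dial `s`) and are projected into voxel
#' space through per-region orthonormal bases.
#' The achieved value is verified at generation time with the package's own
#' representational similarity comparison and re-drawn (bounded retries) if
#' outside `tolerance`.
#'
#' @param design A `cog_design` (supplies the task inventory).
#' @param regions_spec Named integer vector/list of voxel counts per region,
#'   default `c(cortex = 2000, cerebellum = 600, subcortex = 300)` (a
#'   desk-scale reduction of typical region sizes).
#' @param cross_region_similarity Target correlation of representational
#'   geometry between regions, in `[0, 1]`.
#' @param snr Ratio of per-voxel signal SD to noise SD used later by
#'   [simulate_responses()] (default 1).
#' @param drift_amplitude Low-frequency drift scale relative to the median
#'   signal SD (default 0.5).
#' @param hrf_weights Amplitudes of the three delayed responses (2, 4, 6 s).
#' @param br_frac Fraction of voxels per region that additionally respond
#'   to button presses (default 0; used to plant sensorimotor voxels).
#' @param br_gain Gain of the button-response coupling for those voxels.
#' @param tolerance Acceptable deviation of the achieved cross-region
#'   similarity (default 0.05).
#' @param max_retries Bounded number of re-draws before failing with the
#'   achieved value.
#' @param seed Integer seed.
#' @return An object of class `cog_truth` with `weights_by_region`,
#'   `voxel_meta`, `br_weights`, and the generation parameters.
#' @export
generate_ground_truth <- function(design,
                                  regions_spec = c(cortex = 2000,
                                                   cerebellum = 600,
                                                   subcortex = 300),
                                  cross_region_similarity = 0.8,
                                  snr = 1, drift_amplitude = 0.5,
                                  hrf_weights = c(0.5, 1, 0.5),
                                  br_frac = 0, br_gain = 1,
                                  tolerance = 0.05, max_retries = 20,
                                  seed = 0L) {
  s <- cross_region_similarity
  if (s < 0 || s > 1) stop("cross_region_similarity must be in [0, 1]")
  n_tasks <- design$n_tasks
  regions <- names(regions_spec)
  if (is.null(regions)) stop("regions_spec must be named")
  with_seed(seed, {
    best <- NULL; best_gap <- Inf; achieved <- NA_real_
    for (try in seq_len(max_retries)) {
      shared <- matrix(stats::rnorm(n_tasks * n_tasks), n_tasks)
      weights <- list()
      # with t = a*S + b*O (b^2 = 1 - a^2), the similarity elements of two
      # regions correlate at a^4 (the a^2*b^2 cross terms are region-
      # specific), so a = s^(1/4) targets element correlation s
      a <- s^0.25
      for (rg in regions) {
        own <- matrix(stats::rnorm(n_tasks * n_tasks), n_tasks)
        lat <- a * shared + sqrt(1 - a^2) * own
        w <- lat %*% latent_projection(regions_spec[[rg]], n_tasks)
        rownames(w) <- design$task_names
        weights[[rg]] <- w
      }
      if (length(regions) < 2 || s == 1) { best <- weights; achieved <- s; break }
      rsms <- lapply(weights, compute_rsm)
      pairs <- utils::combn(length(regions), 2)
      rho <- mean(apply(pairs, 2, function(ix)
        compare_rsms(rsms[[ix[1]]], rsms[[ix[2]]])$rho))
      gap <- abs(rho - s)
      if (gap < best_gap) { best <- weights; best_gap <- gap; achieved <- rho }
      if (gap <= tolerance) break
    }
    if (length(regions) >= 2 && s < 1 && best_gap > tolerance)
      stop("could not reach cross_region_similarity ", s,
           " within tolerance; achieved ", round(achieved, 3))
    voxel_meta <- do.call(rbind, lapply(regions, function(rg) {
      n <- regions_spec[[rg]]
      data.frame(region = rg, subregion = default_subregions(rg, n),
                 stringsAsFactors = FALSE)
    }))
    rownames(voxel_meta) <- NULL
    v_total <- nrow(voxel_meta)
    br_w <- matrix(0, 4, v_total,
                   dimnames = list(c("L1", "L2", "R1", "R2"), NULL))
    if (br_frac > 0) {
      w_all <- do.call(cbind, best)
      scale_ref <- stats::sd(w_all)
      picked <- sample.int(v_total, max(1L, round(br_frac * v_total)))
      for (v in picked)
        br_w[sample.int(4, 1), v] <- br_gain * scale_ref
    }
    structure(list(
      weights_by_region = best, voxel_meta = voxel_meta,
      br_weights = br_w,
      cross_region_similarity = s, achieved_similarity = achieved,
      snr = snr, drift_amplitude = drift_amplitude,
      hrf_weights = hrf_weights, seed = as.integer(seed)),
      class = "cog_truth")
  })
}

# Shift matrix rows down by k within each run, zero-filling run starts.
shift_within_runs <- function(m, run_index, k) {
  if (k == 0) return(m)
  out <- matrix(0, nrow(m), ncol(m))
  for (r in unique(run_index)) {
    idx <- which(run_index == r)
    if (k < length(idx))
      out[idx[(k + 1):length(idx)], ] <- m[idx[1:(length(idx) - k)], , drop = FALSE]
  }
  out
}

#' Simulate voxel responses for a design and ground truth
#'
#' Responses follow the generating model the encoding analysis assumes: the
#' one-hot task design, shifted by 2, 4 and 6 s and weighted by the
#' hemodynamic amplitudes in `truth$hrf_weights`, multiplied by the true
#' task weights; plus (optionally) a button-press-driven component, slow
#' cosine drift (periods 180-360 s, removable by the 120-s median-filter
#' detrend), and i.i.d. Gaussian noise scaled per voxel to the requested
#' signal-to-noise ratio. Test runs repeat the stimulus order, so
#' repetitions share signal but carry independent noise.
#'
#' @param design A `cog_design`.
#' @param truth A `cog_truth` sharing the design's task inventory.
#' @param noise_seed Integer seed for drift and noise.
#' @param subject_id Label stored in the voxel metadata.
#' @return An object of class `cog_responses` with fields `data`
#'   (time x voxel), `voxel_meta`, `run_index`, `split`, `keep`, `bins`,
#'   `tr_s`, `n_test_repetitions`.
#' @export
simulate_responses <- function(design, truth, noise_seed = 0L,
                               subject_id = "sub01") {
  if (nrow(truth$weights_by_region[[1]]) != design$n_tasks)
    stop("design and truth do not share a task inventory")
  bins <- design_bins(design)
  run_index <- bins$run_id
  w_all <- do.call(cbind, truth$weights_by_region)
  f <- build_task_features(design)$data
  s0 <- f %*% w_all
  if (any(truth$br_weights != 0)) {
    b <- build_br_features(design)$data
    s0 <- s0 + b %*% truth$br_weights
  }
  delays <- c(2, 4, 6)
  signal <- matrix(0, nrow(s0), ncol(s0))
  for (d in seq_along(delays)) {
    signal <- signal + truth$hrf_weights[d] *
      shift_within_runs(s0, run_index, delays[d] / design$tr_s)
  }
  with_seed(noise_seed, {
    v <- ncol(signal)
    snr <- truth$snr
    sd_sig <- apply(signal, 2, stats::sd)
    ref_sd <- stats::median(sd_sig[sd_sig > 0])
    if (!is.finite(ref_sd) || ref_sd == 0) ref_sd <- 1
    if (snr == 0) {
      signal[] <- 0
      noise_sd <- rep(ref_sd, v)
    } else if (is.infinite(snr)) {
      noise_sd <- rep(0, v)
    } else {
      noise_sd <- ifelse(sd_sig > 0, sd_sig, ref_sd) / snr
    }
    drift <- matrix(0, nrow(signal), v)
    if (truth$drift_amplitude > 0) {
      for (r in unique(run_index)) {
        idx <- which(run_index == r)
        t_s <- (seq_along(idx) - 1) * design$tr_s
        periods <- stats::runif(2, 180, 360)
        phases <- stats::runif(2, 0, 2 * pi)
        basis <- cbind(cos(2 * pi * t_s / periods[1] + phases[1]),
                       cos(2 * pi * t_s / periods[2] + phases[2]))
        load <- matrix(stats::rnorm(2 * v), 2, v)
        drift[idx, ] <- basis %*% load *
          (truth$drift_amplitude * ref_sd / sqrt(2))
      }
    }
    noise <- sweep(matrix(stats::rnorm(length(signal)), nrow(signal)),
                   2, noise_sd, "*")
    data <- signal + drift + noise
    meta <- truth$voxel_meta
    meta$subject_id <- subject_id
    structure(list(data = data, voxel_meta = meta,
                   run_index = run_index, split = bins$split,
                   keep = bins$keep, bins = bins, tr_s = design$tr_s,
                   n_test_repetitions = design$n_test_repetitions,
                   preprocessed = FALSE),
              class = "cog_responses")
  })
}

#' Simulate several subjects from one ground truth
#'
#' @param design A `cog_design`.
#' @param truth A `cog_truth`.
#' @param n_subjects Number of subjects.
#' @param seed Base seed; subject i uses `seed + i`.
#' @return Named list of `cog_responses`.
#' @export
simulate_subjects <- function(design, truth, n_subjects, seed = 0L) {
  ids <- sprintf("sub%02d", seq_len(n_subjects))
  stats::setNames(lapply(seq_len(n_subjects), function(i)
    simulate_responses(design, truth, noise_seed = seed + i,
                       subject_id = ids[i])), ids)
}

#' Generate a synthetic term atlas
#'
#' Builds term x voxel maps emulating meta-analytic reverse-inference maps:
#' each term map is a linear combination of the true task weight maps
#' (coefficients drawn i.i.d. Gaussian, or supplied via `mixing`) blended
#' with an independent noise map. `alignment = 1` gives maps fully spanned
#' by the task space; `alignment = 0` gives pure noise, which removes any
#' basis for novel-task decoding.
#'
#' @param truth A `cog_truth`.
#' @param n_terms Number of terms (default 715).
#' @param alignment Blend weight in `[0, 1]`.
#' @param seed Integer seed.
#' @param mixing Optional terms x tasks coefficient matrix (e.g. the
#'   identity to make each term a single task's map).
#' @return An object of class `cog_term_atlas` with `term_names`,
#'   `term_maps` (term x voxel), and generation metadata.
#' @export
generate_term_atlas <- function(truth, n_terms = 715, alignment = 1,
                                seed = 0L, mixing = NULL) {
  w_all <- do.call(cbind, truth$weights_by_region)
  n_tasks <- nrow(w_all)
  with_seed(seed, {
    if (is.null(mixing))
      mixing <- matrix(stats::rnorm(n_terms * n_tasks), n_terms)
    if (ncol(mixing) != n_tasks || nrow(mixing) != n_terms)
      stop("mixing must be n_terms x n_tasks")
    raw <- mixing %*% w_all
    row_sd <- apply(raw, 1, stats::sd)
    raw <- raw / ifelse(row_sd > 0, row_sd, 1)
    noise <- matrix(stats::rnorm(n_terms * ncol(w_all)), n_terms)
    maps <- alignment * raw + (1 - alignment) * noise
    term_names <- sprintf("term%04d", seq_len(n_terms))
    rownames(maps) <- term_names
    structure(list(term_names = term_names, term_maps = maps,
                   generation_meta = list(seed = as.integer(seed),
                                          alignment = alignment,
                                          n_tasks = n_tasks)),
              class = "cog_term_atlas")
  })
}
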