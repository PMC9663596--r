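# Encoding models: preprocessing, delay-expanded ridge fits, evaluation on
# repetition-averaged test data, and sensorimotor-voxel flagging.

#' Detrend and normalize voxel responses
#'
#' Removes low-frequency drift with a running-median filter (120-s window by
#' default) and z-scores each voxel within each run. Runs shorter than the
#' filter window fall back to a run-length window with a warning. Constant
#' voxels are mapped to zero (the 0/0 guard).
#'
#' @param responses A `cog_responses` object (raw).
#' @param window_s Median-filter window in seconds (default 120).
#' @return The responses object with detrended, z-scored `data` and
#'   `preprocessed = TRUE`.
#' @export
preprocess_responses <- function(responses, window_s = 120) {
  x <- responses$data
  tr <- responses$tr_s
  for (r in unique(responses$run_index)) {
    idx <- which(responses$run_index == r)
    k <- floor(window_s / tr)
    if (k %% 2 == 0) k <- k + 1
    if (k > length(idx)) {
      warning("run ", r, " shorter than the filter window; using run length")
      k <- length(idx) - (1 - length(idx) %% 2)
    }
    xr <- x[idx, , drop = FALSE]
    if (k >= 3) {
      trend <- apply(xr, 2, function(v) stats::runmed(v, k, endrule = "median"))
      xr <- xr - trend
    } else {
      xr <- sweep(xr, 2, colMeans(xr))
    }
    mu <- colMeans(xr)
    sd <- apply(xr, 2, stats::sd)
    xr <- sweep(xr, 2, mu)
    xr <- sweep(xr, 2, ifelse(sd > 0, sd, 1), "/")
    xr[, sd == 0] <- 0
    x[idx, ] <- xr
  }
  responses$data <- x
  responses$preprocessed <- TRUE
  responses
}

#' Fit a delay-expanded ridge encoding model
#'
#' Solves `W = argmin ||R - F W||^2 + alpha ||W||^2` jointly for all voxels
#' (mathematically identical to per-voxel fits) on the training timepoints.
#'
#' @param design_matrix A `cog_delayed` object (or plain time x 3N matrix)
#'   restricted to training timepoints.
#' @param responses Training time x voxel matrix.
#' @param alpha Ridge penalty.
#' @param feature_names Base feature names (taken from the delayed design
#'   when available).
#' @param voxel_meta Optional per-voxel metadata stored with the fit.
#' @return An `encoding_fit` with `weights` (3N x V), `alpha`, `delays_s`,
#'   `feature_names`.
#' @export
ridge_fit <- function(design_matrix, responses, alpha,
                      feature_names = NULL, voxel_meta = NULL) {
  if (inherits(design_matrix, "cog_delayed")) {
    feature_names <- feature_names %||% design_matrix$source_feature_names
    delays <- design_matrix$delays_s
    x <- design_matrix$data
  } else {
    x <- as.matrix(design_matrix)
    delays <- attr(design_matrix, "delays_s") %||% c(2, 4, 6)
    feature_names <- feature_names %||%
      (colnames(x)[seq_len(ncol(x) / 3)] %||% sprintf("f%d", seq_len(ncol(x) / 3)))
  }
  w <- ridge_solve(x, as.matrix(responses), alpha)
  structure(list(weights = w, alpha = alpha, delays_s = delays,
                 feature_names = feature_names, voxel_meta = voxel_meta),
            class = "encoding_fit")
}

# Average matrix rows that share a repetition-template position.
# `pos` gives, per row, the template position (NA rows are dropped).
average_repetitions <- function(m, pos) {
  keep <- !is.na(pos)
  m <- m[keep, , drop = FALSE]
  pos <- pos[keep]
  counts <- as.vector(table(factor(pos, levels = sort(unique(pos)))))
  sums <- rowsum(m, group = pos)
  sums / counts
}

#' Evaluate an encoding model on repetition-averaged test data
#'
#' Averages the test repetitions (matched by template position) for both
#' the measured responses and the model predictions, computes the per-voxel
#' Pearson prediction accuracy, its one-sided p-value under the Gaussian
#' null, and the Benjamini-Hochberg q-value.
#'
#' @param fit An `encoding_fit`.
#' @param design_test Delayed design rows for the test timepoints
#'   (`cog_delayed` or matrix).
#' @param responses_test Test time x voxel matrix (all repetitions).
#' @param pos Per-test-timepoint repetition-template position (NA =
#'   discarded bin); if `NULL` no averaging is performed.
#' @param q_threshold FDR level for the significance mask (default 0.05).
#' @return List with `r`, `p`, `q`, `significant`, `n_test_samples`.
#' @export
evaluate_encoding <- function(fit, design_test, responses_test, pos = NULL,
                              q_threshold = 0.05) {
  x <- if (inherits(design_test, "cog_delayed")) design_test$data else
    as.matrix(design_test)
  y <- as.matrix(responses_test)
  if (!is.null(pos)) {
    if (length(pos) != nrow(y)) stop("pos length must match test rows")
    x <- average_repetitions(x, pos)
    y <- average_repetitions(y, pos)
  }
  pred <- x %*% fit$weights
  r <- colwise_cor(pred, y)
  p <- correlation_pvalue(r, nrow(y))
  f <- fdr_bh(p, q_threshold)
  list(r = r, p = p, q = f$q, significant = f$mask, n_test_samples = nrow(y))
}

#' Flag sensorimotor voxels
#'
#' Fits encoding models from sensorimotor features (button responses and/or
#' externally supplied visual/auditory features) on repeated random 80/20
#' splits of the training data and flags voxels whose mean validation
#' accuracy reaches `threshold` (default 0.3; 0.2 and 0.1 are the
#' conventional alternatives).
#'
#' @param sm_design Delayed sensorimotor design matrix over the training
#'   timepoints (`cog_delayed` or matrix).
#' @param responses Training time x voxel matrix.
#' @param n_rep Number of resampling repetitions (default 50).
#' @param holdout Validation fraction (default 0.2).
#' @param threshold Mean-accuracy threshold in `[0, 1]` (default 0.3).
#' @param alpha Ridge penalty; selected by cross-validation when `NULL`.
#' @param seed Integer seed for the splits.
#' @return Logical voxel mask with the per-voxel mean accuracy as attribute
#'   `mean_accuracy`.
#' @export
flag_sensorimotor_voxels <- function(sm_design, responses, n_rep = 50,
                                     holdout = 0.2, threshold = 0.3,
                                     alpha = NULL, seed = 1L) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  x <- if (inherits(sm_design, "cog_delayed")) sm_design$data else
    as.matrix(sm_design)
  y <- as.matrix(responses)
  if (is.null(alpha)) alpha <- as.numeric(select_alpha_cv(x, y))
  n <- nrow(x)
  n_val <- max(1L, round(holdout * n))
  acc <- with_seed(seed, {
    a <- matrix(NA_real_, n_rep, ncol(y))
    for (i in seq_len(n_rep)) {
      val <- sample.int(n, n_val)
      w <- ridge_solve(x[-val, , drop = FALSE], y[-val, , drop = FALSE], alpha)
      a[i, ] <- colwise_cor(x[val, , drop = FALSE] %*% w,
                            y[val, , drop = FALSE])
    }
    colMeans(a)
  })
  # threshold 0 is the degenerate boundary: every voxel meets it
  mask <- if (threshold == 0) rep(TRUE, length(acc)) else acc >= threshold
  attr(mask, "mean_accuracy") <- acc
  mask
}
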