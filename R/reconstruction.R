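# Voxel-to-voxel reconstruction: compress one region's activity by PCA and
# use it (alone or concatenated with another region's) as the feature matrix
# of an encoding model predicting cortical voxels.

#' PCA compression of region responses
#'
#' Fits a PCA basis on the training timepoints of one region's voxels and
#' projects the full timeline onto the first `k` components. The basis is
#' estimated on training data only, so projecting test timepoints never
#' uses test statistics.
#'
#' @param responses A preprocessed `cog_responses`.
#' @param region Region whose voxels are compressed.
#' @param k Number of components (full-scale analyses use 2,000; tests use
#'   much smaller values).
#' @return List of class `response_pc_basis` with `components` (voxel x k),
#'   `center`, `variance_retained`, `region`, and `projected`
#'   (time x k over the full timeline).
#' @export
pca_reduce_responses <- function(responses, region, k) {
  vox <- which(responses$voxel_meta$region == region)
  if (!length(vox)) stop("no voxels in region ", region)
  train <- responses$split == "train" & responses$keep
  x_train <- responses$data[train, vox, drop = FALSE]
  if (k > min(nrow(x_train), length(vox)))
    stop("k exceeds min(training samples, voxels)")
  pr <- stats::prcomp(x_train, center = TRUE, scale. = FALSE)
  comp <- pr$rotation[, seq_len(k), drop = FALSE]
  var_ret <- sum(pr$sdev[seq_len(k)]^2) / sum(pr$sdev^2)
  projected <- sweep(responses$data[, vox, drop = FALSE], 2, pr$center) %*% comp
  structure(list(components = comp, center = pr$center,
                 variance_retained = var_ret, k = k, region = region,
                 projected = projected),
            class = "response_pc_basis")
}

#' Voxel-to-voxel encoding model
#'
#' Uses PCA-compressed responses of one or more source regions (delay-
#' expanded like any feature matrix) to predict cortical voxel activity,
#' with ridge regression and repetition-averaged evaluation.
#'
#' @param source_projected Time x k matrix (or list of such matrices, which
#'   are column-concatenated, e.g. cerebellum + subcortex).
#' @param responses A preprocessed `cog_responses` holding the target
#'   voxels.
#' @param target_region Region to predict (default `"cortex"`).
#' @param alpha Ridge penalty; selected by cross-validation when `NULL`.
#' @param delays_s Delays applied to the source features (default 2/4/6 s;
#'   use `numeric(0)` semantics via `delay = FALSE`).
#' @param delay Whether to delay-expand the source features (default TRUE).
#' @param n_folds CV folds for alpha selection.
#' @param q_threshold FDR level for the significance mask.
#' @return List with `fit` (an `encoding_fit`), `result` (per-voxel
#'   accuracy, p, q, mask), `alpha`.
#' @export
fit_voxel2voxel <- function(source_projected, responses,
                            target_region = "cortex", alpha = NULL,
                            delays_s = c(2, 4, 6), delay = TRUE,
                            n_folds = 5, q_threshold = 0.05) {
  if (inherits(source_projected, "response_pc_basis")) {
    source_projected <- source_projected$projected
  } else if (is.list(source_projected) && !is.matrix(source_projected)) {
    source_projected <- do.call(cbind, lapply(source_projected, function(s)
      if (inherits(s, "response_pc_basis")) s$projected else as.matrix(s)))
  }
  x <- as.matrix(source_projected)
  if (nrow(x) != nrow(responses$data))
    stop("source and target must share timepoints")
  if (delay) {
    x <- delay_expand(x, run_index = responses$run_index,
                      tr_s = responses$tr_s, delays_s = delays_s)$data
  }
  vox <- which(responses$voxel_meta$region == target_region)
  if (!length(vox)) stop("no voxels in region ", target_region)
  y <- responses$data[, vox, drop = FALSE]
  train <- responses$split == "train" & responses$keep
  test <- responses$split == "test" & responses$keep
  if (is.null(alpha))
    alpha <- as.numeric(select_alpha_cv(x[train, , drop = FALSE],
                                        y[train, , drop = FALSE],
                                        n_folds = n_folds))
  fit <- ridge_fit(x[train, , drop = FALSE], y[train, , drop = FALSE], alpha,
                   feature_names = colnames(x) %||%
                     sprintf("pc%d", seq_len(ncol(x))))
  pos <- responses$bins$pos[test]
  result <- evaluate_encoding(fit, x[test, , drop = FALSE],
                              y[test, , drop = FALSE], pos = pos,
                              q_threshold = q_threshold)
  list(fit = fit, result = result, alpha = alpha, target_voxels = vox)
}

#' Subtract the global mean response
#'
#' Removes the per-timepoint average over all voxels (all regions) from
#' every voxel — the control that rules out a common additive signal as the
#' source of cross-region predictability.
#'
#' @param responses A `cog_responses`.
#' @return The responses object with the global mean removed.
#' @export
subtract_global_mean <- function(responses) {
  responses$data <- responses$data - rowMeans(responses$data)
  responses
}
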