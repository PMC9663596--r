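# Representational similarity analysis on task weight maps: group-level
# weight concatenation, task x task correlation matrices, single-linkage
# ordering, rank-percentile transform, and cross-region comparison.

#' Group-concatenated, delay-averaged task weights
#'
#' For each subject, keeps the voxels whose encoding prediction accuracy is
#' significant (`q < q_threshold`), averages the three delay blocks of the
#' fitted weights per task, and concatenates the retained voxel columns
#' across subjects into one task x voxel matrix used for group RSA and PCA.
#'
#' @param fits_by_subject List of `encoding_fit` objects (one per subject).
#' @param prediction_results Matching list of prediction results (from
#'   [evaluate_encoding()]) supplying per-voxel `q`.
#' @param q_threshold FDR threshold for keeping voxels (default 0.05).
#' @return A task x voxel matrix; the subject of each retained column is in
#'   attribute `subject`, its original voxel index in attribute `voxel`.
#' @export
group_task_weights <- function(fits_by_subject, prediction_results,
                               q_threshold = 0.05) {
  stopifnot(length(fits_by_subject) == length(prediction_results))
  cols <- list(); subj <- list(); vox <- list()
  for (i in seq_along(fits_by_subject)) {
    fit <- fits_by_subject[[i]]
    keep <- prediction_results[[i]]$q < q_threshold
    if (!any(keep)) {
      warning("subject ", i, " has no predictive voxels; skipped")
      next
    }
    w <- delay_average_weights(fit)[, keep, drop = FALSE]
    cols[[length(cols) + 1L]] <- w
    subj[[length(subj) + 1L]] <- rep(i, sum(keep))
    vox[[length(vox) + 1L]] <- which(keep)
  }
  if (!length(cols)) stop("no subject contributed predictive voxels")
  out <- do.call(cbind, cols)
  attr(out, "subject") <- unlist(subj)
  attr(out, "voxel") <- unlist(vox)
  out
}

#' Average the delay blocks of fitted encoding weights
#'
#' Collapses a (delays x N) x V weight matrix into the per-task N x V map
#' by averaging the delay blocks — the weight map used for RSA, PCA and
#' CTF construction.
#'
#' @param fit An `encoding_fit`.
#' @return N x V matrix of delay-averaged weights.
#' @export
delay_average_weights <- function(fit) {
  w <- fit$weights
  n <- length(fit$feature_names)
  n_delay <- nrow(w) / n
  stopifnot(n_delay == round(n_delay))
  out <- matrix(0, n, ncol(w), dimnames = list(fit$feature_names, NULL))
  for (d in seq_len(n_delay)) out <- out + w[(d - 1) * n + seq_len(n), , drop = FALSE]
  out / n_delay
}

#' Representational similarity matrix
#'
#' Pairwise Pearson correlations between the tasks' voxel-weight vectors.
#' Zero-variance task rows yield 0 similarity (with a warning).
#'
#' @param task_weights Task x voxel matrix (delay-averaged).
#' @param region Optional region label stored with the result.
#' @return An object of class `cog_rsm` with fields `matrix`, `region`.
#' @export
compute_rsm <- function(task_weights, region = NULL) {
  task_weights <- as.matrix(task_weights)
  if (nrow(task_weights) < 2) stop("need at least 2 tasks")
  sds <- apply(task_weights, 1, stats::sd)
  if (any(sds == 0)) warning("zero-variance task rows; similarities set to 0")
  m <- rowwise_cor(task_weights, task_weights)
  diag(m) <- 1
  dimnames(m) <- list(rownames(task_weights), rownames(task_weights))
  structure(list(matrix = m, region = region, task_order = NULL),
            class = "cog_rsm")
}

#' Order tasks by hierarchical clustering of the RSM
#'
#' Agglomerates tasks with single linkage ("minimum distance") on the
#' dissimilarity `1 - r` and returns the dendrogram leaf order, which can be
#' applied to other regions' RSMs for visual comparison.
#'
#' @param rsm A `cog_rsm`.
#' @return List with `order` (permutation of task indices) and `hclust`
#'   (the clustering object).
#' @export
cluster_task_order <- function(rsm) {
  d <- stats::as.dist(1 - rsm$matrix)
  hc <- stats::hclust(d, method = "single")
  list(order = hc$order, hclust = hc)
}

#' Rank-percentile transform of an RSM
#'
#' Ranks the unique off-diagonal similarities in ascending order, maps ranks
#' to `[0, 100]` (midranks for ties, so constant matrices map to 50), and
#' mirrors the result to the lower triangle. The diagonal is set to `NA`.
#'
#' @param rsm A `cog_rsm`.
#' @return A numeric matrix of percentiles.
#' @export
rank_percentile <- function(rsm) {
  m <- rsm$matrix
  ut <- upper.tri(m)
  v <- m[ut]
  n <- length(v)
  pct <- if (n == 1) 50 else (rank(v, ties.method = "average") - 1) / (n - 1) * 100
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  out[ut] <- pct
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

#' Export a task dendrogram as Newick text
#'
#' Serializes the clustering from [cluster_task_order()] in
#' nested-parenthesis (Newick) tree form.
#'
#' @param clustering Result of [cluster_task_order()] (or an `hclust`).
#' @param path Optional file; when `NULL` the string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
export_dendrogram <- function(clustering, path = NULL) {
  hc <- if (inherits(clustering, "hclust")) clustering else clustering$hclust
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the 'ape' package is required for Newick export")
  txt <- ape::write.tree(ape::as.phylo(hc))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Compare two RSMs
#'
#' Spearman correlation over the unique off-diagonal pairs (n = T(T-1)/2),
#' plus the standard deviation of each RSM's similarities over the same
#' set — the summary used to contrast how distinctly regions organize the
#' tasks.
#'
#' @param rsm_a,rsm_b `cog_rsm` objects over the same ordered task set.
#' @return List with `rho`, `n_pairs`, `sd_a`, `sd_b`.
#' @export
compare_rsms <- function(rsm_a, rsm_b) {
  ma <- rsm_a$matrix; mb <- rsm_b$matrix
  if (!identical(dim(ma), dim(mb)))
    stop("RSMs have different sizes")
  if (!is.null(rownames(ma)) && !is.null(rownames(mb)) &&
      !identical(rownames(ma), rownames(mb)))
    stop("RSMs have mismatched task order")
  ut <- upper.tri(ma)
  a <- ma[ut]; b <- mb[ut]
  list(rho = stats::cor(a, b, method = "spearman"),
       n_pairs = length(a),
       sd_a = stats::sd(a), sd_b = stats::sd(b))
}
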