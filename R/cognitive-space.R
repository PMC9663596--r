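# Principal-component cognitive spaces: PCA over group task weights, 2-D
# task maps with RGB coloring by the top three PCs, per-voxel score maps,
# metadata-based interpretation against a term atlas, and subregion
# task-selectivity profiles.

#' Fit a PCA cognitive space on task weights
#'
#' Performs centered PCA with tasks as observations and voxels as variables
#' (the mean task map is removed). Task-side coordinates are the loadings;
#' voxel-side coordinates are the scores. The sign of each PC is fixed so
#' that the largest-magnitude task loading is positive, making results
#' stable across runs.
#'
#' @param task_weights Task x voxel matrix (delay-averaged, typically
#'   significant voxels concatenated across subjects).
#' @param n_pcs Number of components to keep.
#' @return A `cognitive_space` with `loadings` (task x PC), `scores`
#'   (voxel x PC), `explained_variance_ratio`, `center`.
#' @export
fit_cognitive_space <- function(task_weights, n_pcs = 5) {
  x <- as.matrix(task_weights)
  if (n_pcs > min(dim(x))) stop("n_pcs exceeds min(tasks, voxels)")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  evr <- pr$sdev^2 / sum(pr$sdev^2)
  load <- pr$x[, seq_len(n_pcs), drop = FALSE]
  score <- pr$rotation[, seq_len(n_pcs), drop = FALSE]
  for (k in seq_len(n_pcs)) {
    flip <- sign(load[which.max(abs(load[, k])), k])
    if (flip < 0) { load[, k] <- -load[, k]; score[, k] <- -score[, k] }
  }
  structure(list(loadings = load, scores = score,
                 explained_variance_ratio = evr[seq_len(n_pcs)],
                 all_variance_ratio = evr, center = pr$center,
                 n_pcs = n_pcs),
            class = "cognitive_space")
}

#' Map tasks into the 2-D cognitive space
#'
#' Uses PC1 and PC2 loadings as x/y coordinates and colors each task by its
#' min-max-normalized loadings on the top three PCs (PC1 red, PC2 green,
#' PC3 blue). Degenerate (zero-variance) channels are fixed at 0.5.
#'
#' @param space A `cognitive_space` with at least 3 PCs.
#' @return A data.frame with columns `task`, `x`, `y`, `r`, `g`, `b`.
#' @export
map_tasks_2d <- function(space) {
  if (space$n_pcs < 3) stop("need at least 3 PCs for RGB coloring")
  l <- space$loadings
  norm01 <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) return(rep(0.5, length(v)))
    (v - rng[1]) / diff(rng)
  }
  data.frame(task = rownames(l) %||% sprintf("task%03d", seq_len(nrow(l))),
             x = l[, 1], y = l[, 2],
             r = norm01(l[, 1]), g = norm01(l[, 2]), b = norm01(l[, 3]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-subject normalized PC score maps
#'
#' Extracts the voxel scores belonging to one subject and z-normalizes each
#' PC over that subject's voxels, giving the relative contribution of each
#' voxel to the component (the PCA score map).
#'
#' @param space A `cognitive_space` fitted on group-concatenated weights.
#' @param subjects Per-voxel subject labels aligned with `space$scores`
#'   rows (e.g. attribute `subject` of [group_task_weights()]).
#' @param subject_id Subject to extract; `NULL` uses all voxels.
#' @return Voxel x PC matrix of z-scored PC scores.
#' @export
pc_score_map <- function(space, subjects = NULL, subject_id = NULL) {
  s <- space$scores
  if (!is.null(subject_id)) {
    if (is.null(subjects)) stop("per-voxel subject labels required")
    keep <- subjects == subject_id
    if (!any(keep)) stop("unknown subject: ", subject_id)
    s <- s[keep, , drop = FALSE]
  }
  z <- scale(s)
  z[, attr(z, "scaled:scale") == 0] <- 0
  z[, , drop = FALSE]
}

#' Metadata-based interpretation of PCs
#'
#' Correlates each PC score map with every term map of an atlas and returns
#' the ranked terms; the top and bottom `n_top` terms provide an objective
#' interpretation of the component's positive and negative poles.
#'
#' @param score_maps Voxel x PC matrix (e.g. from [pc_score_map()]).
#' @param atlas A `cog_term_atlas` whose voxel dimension matches the score
#'   map rows (subset atlas columns to the same voxels first).
#' @param n_top Number of terms per pole (default 10).
#' @return List (one element per PC) with `correlations` (named, ranked
#'   descending), `top_terms`, `bottom_terms`.
#' @export
interpret_pcs <- function(score_maps, atlas, n_top = 10) {
  maps <- as.matrix(score_maps)
  tm <- atlas$term_maps
  if (ncol(tm) != nrow(maps))
    stop("atlas voxel dimension (", ncol(tm),
         ") does not match score map (", nrow(maps), ")")
  out <- lapply(seq_len(ncol(maps)), function(k) {
    r <- drop(rowwise_cor(tm, t(maps[, k, drop = FALSE])))
    names(r) <- atlas$term_names
    ord <- order(r, decreasing = TRUE)
    list(correlations = r[ord],
         top_terms = names(r)[ord][seq_len(min(n_top, length(r)))],
         bottom_terms = rev(names(r)[ord])[seq_len(min(n_top, length(r)))])
  })
  names(out) <- colnames(maps) %||% sprintf("PC%d", seq_len(ncol(maps)))
  out
}

#' Mean task weights within a subregion
#'
#' Averages the task weight columns over the voxels carrying a subregion
#' label, retaining sign and magnitude as positive/negative task
#' selectivity of that subregion.
#'
#' @param task_weights Task x voxel matrix.
#' @param voxel_meta Data frame with a `subregion` column aligned to the
#'   weight columns.
#' @param subregion_label Label to profile (e.g. `"MDTB_2"`).
#' @return Named numeric vector of per-task mean weights.
#' @export
subregion_task_profile <- function(task_weights, voxel_meta, subregion_label) {
  sel <- voxel_meta$subregion == subregion_label
  if (!any(sel)) stop("empty subregion: ", subregion_label)
  w <- as.matrix(task_weights)[, sel, drop = FALSE]
  stats::setNames(rowMeans(w), rownames(task_weights))
}
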