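# Decoding models: leave-one-subject-out cognitive transform functions,
# ridge decoders from delayed responses to cognitive-factor features,
# novel-task cross-validation over task groups, task-score and one-vs-one
# metrics, and their significance tests.

#' Build a leave-one-subject-out cognitive transform function
#'
#' Correlates every task's (delay-averaged) weight map with every term map
#' of the atlas per subject, then averages the resulting tasks x terms
#' coefficient matrices over all subjects except the target, so the target
#' subject's CTF is independent of their own data.
#'
#' @param task_weight_maps_by_subject Named list of task x voxel matrices.
#' @param atlas A `cog_term_atlas` over the same voxel space (subset both
#'   to a region first if needed).
#' @param target_subject Name (or index) of the subject to exclude.
#' @return A `cog_ctf` with `matrix` (tasks x terms), `excluded_subject`,
#'   `source_subjects`.
#' @export
build_ctf <- function(task_weight_maps_by_subject, atlas, target_subject) {
  subjects <- names(task_weight_maps_by_subject) %||%
    as.character(seq_along(task_weight_maps_by_subject))
  names(task_weight_maps_by_subject) <- subjects
  if (length(subjects) < 2)
    stop("leave-one-subject-out CTF needs at least 2 subjects")
  if (is.numeric(target_subject)) target_subject <- subjects[target_subject]
  if (!target_subject %in% subjects) stop("unknown target subject")
  sources <- setdiff(subjects, target_subject)
  mats <- lapply(sources, function(s) {
    w <- as.matrix(task_weight_maps_by_subject[[s]])
    if (ncol(w) != ncol(atlas$term_maps))
      stop("weight map and atlas voxel dimensions differ")
    rowwise_cor(w, atlas$term_maps)
  })
  ctf <- Reduce(`+`, mats) / length(mats)
  colnames(ctf) <- atlas$term_names
  structure(list(matrix = ctf, excluded_subject = target_subject,
                 source_subjects = sources),
            class = "cog_ctf")
}

#' Fit a decoding model
#'
#' Ridge regression from delay-expanded voxel responses to cognitive-factor
#' features (the transpose direction of the encoding model), using the same
#' regularization machinery.
#'
#' @param responses_delayed Time x 3V delayed response matrix
#'   (`cog_delayed` or plain), training rows only.
#' @param factor_features Time x terms feature matrix over the same rows.
#' @param alpha Ridge penalty; selected by [select_alpha_cv()] when `NULL`.
#' @param n_folds Folds used when selecting alpha (default 5).
#' @return A `decoding_fit` with `weights` (3V x terms) and `alpha`.
#' @export
fit_decoder <- function(responses_delayed, factor_features, alpha = NULL,
                        n_folds = 5) {
  x <- if (inherits(responses_delayed, "cog_delayed")) responses_delayed$data
       else as.matrix(responses_delayed)
  y <- if (inherits(factor_features, "cog_features")) factor_features$data
       else as.matrix(factor_features)
  if (is.null(alpha)) alpha <- as.numeric(select_alpha_cv(x, y, n_folds = n_folds))
  w <- ridge_solve(x, y, alpha)
  structure(list(weights = w, alpha = alpha),
            class = "decoding_fit")
}

#' Randomly partition tasks into groups
#'
#' Splits the task inventory into `n_groups` disjoint, exhaustive groups of
#' as-even-as-possible sizes (103 tasks and 5 groups give sizes 21, 21, 21,
#' 20, 20 in some order).
#'
#' @param tasks Vector of task ids or names.
#' @param n_groups Number of groups (default 5).
#' @param seed Integer seed.
#' @return List of task vectors.
#' @export
split_task_groups <- function(tasks, n_groups = 5, seed = 0L) {
  if (n_groups > length(tasks)) stop("more groups than tasks")
  with_seed(seed, {
    shuffled <- sample(tasks)
    sizes <- tabulate(rep(seq_len(n_groups), length.out = length(tasks)),
                      n_groups)   # sizes differ by at most one
    split(shuffled, rep(seq_len(n_groups), times = sizes))
  })
}

#' Timepoint masks for novel-task cross-validation
#'
#' For a set of target tasks, identifies the TR bins during their trials
#' and within `window_s` (default 6 s) after trial offset. In `"train"`
#' mode those bins are excluded (mask is TRUE for usable bins); in
#' `"test"` mode only those bins are kept, so activity evoked by the target
#' tasks never enters model fitting.
#'
#' @param design A `cog_design`.
#' @param target_tasks Task ids (integer) or names.
#' @param window_s Post-offset exclusion window (multiple of TR).
#' @param mode `"train"` or `"test"`.
#' @return Logical vector over the design's full concatenated timeline.
#' @export
exclude_target_timepoints <- function(design, target_tasks, window_s = 6,
                                      mode = c("train", "test")) {
  mode <- match.arg(mode)
  if (window_s %% design$tr_s != 0) stop("window_s must be a multiple of tr_s")
  if (is.character(target_tasks))
    target_tasks <- match(target_tasks, design$task_names)
  bins <- design_bins(design)
  target <- rep(FALSE, nrow(bins))
  tri <- design$trials[design$trials$task_id %in% target_tasks, , drop = FALSE]
  run_offset <- c(0, cumsum(design$runs$duration_s / design$tr_s))
  names(run_offset) <- c(design$runs$run_id, "end")
  for (i in seq_len(nrow(tri))) {
    off <- run_offset[as.character(tri$run_id[i])]
    starts <- bins$t_in_run[bins$run_id == tri$run_id[i]]
    sel <- which(starts >= tri$onset_s[i] - 1e-9 &
                 starts < tri$onset_s[i] + tri$duration_s[i] + window_s - 1e-9)
    target[off + sel] <- TRUE
  }
  if (mode == "train") !target else target
}

# Bins of the test repetition template attributed to each task: bins whose
# start lies during a trial, or in its `window_s` tail. A position can belong
# to several tasks (a tail overlapping the next trial).
rep_task_positions <- function(design, window_s = 6) {
  bins <- design_bins(design)
  out <- vector("list", design$n_tasks)
  test_runs <- design$runs$run_id[design$runs$split == "test"]
  tri <- design$trials[design$trials$run_id %in% test_runs, , drop = FALSE]
  for (i in seq_len(nrow(tri))) {
    sel <- bins$run_id == tri$run_id[i] &
      bins$t_in_run >= tri$onset_s[i] - 1e-9 &
      bins$t_in_run < tri$onset_s[i] + tri$duration_s[i] + window_s - 1e-9
    pos <- unique(stats::na.omit(bins$pos[sel]))
    k <- tri$task_id[i]
    out[[k]] <- sort(unique(c(out[[k]], pos)))
  }
  out
}

#' Task scores from decoded cognitive-factor vectors
#'
#' Correlates each decoded timepoint vector with each task's CTF row, then
#' averages over the timepoints attributed to each task (its trial bins
#' plus the post-offset window). Decoded vectors with zero variance score 0
#' with a warning.
#'
#' @param decoded Timepoints x terms matrix of decoded features (rows are
#'   repetition-template positions given by `positions`).
#' @param ctf A `cog_ctf` or tasks x terms matrix.
#' @param task_positions List (per task) of template positions, e.g. from
#'   the internal attribution used by [decode_novel_tasks()].
#' @param positions Template position of each decoded row.
#' @return List with `score_matrix` (decoded row x task), `cross_scores`
#'   (task x task: row = scoring task's bins, column = CTF row), and
#'   `task_score` (per-task time-averaged score, the diagonal).
#' @export
task_scores <- function(decoded, ctf, task_positions, positions) {
  if (inherits(ctf, "cog_ctf")) ctf <- ctf$matrix
  decoded <- as.matrix(decoded)
  if (any(apply(decoded, 1, stats::sd) == 0))
    warning("zero-variance decoded vector(s); their scores are 0")
  sm <- rowwise_cor(decoded, ctf)   # rows x tasks
  n_tasks <- nrow(ctf)
  cross <- matrix(NA_real_, n_tasks, n_tasks,
                  dimnames = list(rownames(ctf), rownames(ctf)))
  for (k in seq_len(n_tasks)) {
    rows <- which(positions %in% task_positions[[k]])
    if (length(rows))
      cross[k, ] <- colMeans(sm[rows, , drop = FALSE])
  }
  list(score_matrix = sm, cross_scores = cross,
       task_score = diag(cross))
}

#' One-vs-one decoding accuracy from a cross-score table
#'
#' For each target task, performs binary comparisons against every other
#' task: the target wins a comparison when its own time-averaged score
#' (within its test timepoints) exceeds the competitor CTF's score over the
#' same timepoints. Ties score half a win. Chance level is 0.5.
#'
#' @param cross_scores Task x task matrix (rows = scoring task's bins).
#' @return Per-task accuracy in `[0, 1]`, with the per-task win counts as
#'   attribute `wins` and comparison count as attribute `n_comparisons`.
#' @export
one_vs_one_accuracy <- function(cross_scores) {
  n <- nrow(cross_scores)
  own <- diag(cross_scores)
  acc <- numeric(n); wins <- numeric(n)
  for (k in seq_len(n)) {
    others <- cross_scores[k, -k]
    wins[k] <- sum(own[k] > others) + 0.5 * sum(own[k] == others)
    acc[k] <- wins[k] / (n - 1)
  }
  names(acc) <- rownames(cross_scores)
  attr(acc, "wins") <- wins
  attr(acc, "n_comparisons") <- n - 1
  acc
}

#' Significance of task decoding
#'
#' Per task, a one-sided sign test over the binary one-vs-one comparisons
#' (ties dropped), corrected across tasks with Benjamini-Hochberg FDR; and
#' a label-permutation test for the mean accuracy and mean task score:
#' the assignment of test trials to task labels is shuffled (whole trials,
#' preserving temporal structure) and both statistics recomputed.
#'
#' @param scores Result of [task_scores()] (needs `cross_scores`).
#' @param n_perm Number of permutations (default 5000; smaller values are
#'   appropriate for quick checks).
#' @param seed Integer seed for the permutations.
#' @param q_threshold FDR level (default 0.05).
#' @return List with `accuracy`, `task_score`, `p_sign`, `q`,
#'   `significant`, `perm` (null distributions and p-values for the mean
#'   accuracy and mean score).
#' @export
test_task_significance <- function(scores, n_perm = 5000, seed = 1L,
                                   q_threshold = 0.05) {
  cross <- scores$cross_scores
  n <- nrow(cross)
  acc <- one_vs_one_accuracy(cross)
  p <- numeric(n)
  for (k in seq_len(n)) {
    others <- cross[k, -k]
    wins <- sum(cross[k, k] > others)
    ties <- sum(cross[k, k] == others)
    p[k] <- sign_test_one_sided(wins, n - 1 - ties)
  }
  f <- fdr_bh(p, q_threshold)
  mean_stat <- function(perm) {
    own <- cross[cbind(perm, seq_len(n))]
    a <- vapply(seq_len(n), function(k) {
      others <- cross[perm[k], -k]
      (sum(own[k] > others) + 0.5 * sum(own[k] == others)) / (n - 1)
    }, numeric(1))
    c(mean(a), mean(own))
  }
  obs <- mean_stat(seq_len(n))
  null <- with_seed(seed, vapply(seq_len(n_perm),
                                 function(i) mean_stat(sample.int(n)),
                                 numeric(2)))
  perm <- list(
    null_accuracy = null[1, ], null_score = null[2, ],
    p_accuracy = (1 + sum(null[1, ] >= obs[1])) / (1 + n_perm),
    p_score = (1 + sum(null[2, ] >= obs[2])) / (1 + n_perm))
  list(accuracy = acc, task_score = diag(cross), p_sign = p, q = f$q,
       significant = f$mask, mean_accuracy = obs[1], mean_score = obs[2],
       perm = perm)
}

#' Novel-task decoding pipeline for one subject and region
#'
#' Runs the full novel-task cross-validation: the tasks are partitioned
#' into groups; for each group a decoder is trained on training timepoints
#' that exclude the group's trials and their 6-s tails, then applied to the
#' repetition-averaged test timepoints belonging to that group; decoded
#' features at timepoints covered by several group models are averaged.
#' Task scores, one-vs-one accuracies and significance tests follow.
#'
#' @param responses A preprocessed `cog_responses`.
#' @param design The matching `cog_design`.
#' @param ctf The subject's leave-one-subject-out `cog_ctf`.
#' @param region Region to decode from (`NULL` = all voxels).
#' @param voxel_exclude Optional logical mask (over the selected region's
#'   voxels) of voxels to drop, e.g. flagged sensorimotor voxels.
#' @param groups Task groups (default: [split_task_groups()] with
#'   `n_groups` and `group_seed`).
#' @param n_groups Number of task groups (default 5).
#' @param group_seed Seed for the partition.
#' @param window_s Exclusion window after trial offset (default 6 s).
#' @param alpha Ridge penalty for the decoders; `NULL` selects per group by
#'   cross-validation.
#' @param n_perm Permutations for the mean-statistic test (default 1000).
#' @param seed Seed for the permutation test.
#' @return List with the per-task results (`accuracy`, `task_score`, `q`,
#'   `significant`, ...), the decoded feature matrix, and bookkeeping
#'   (`groups`, `alphas`, `train_masks`).
#' @export
decode_novel_tasks <- function(responses, design, ctf, region = NULL,
                               voxel_exclude = NULL, groups = NULL,
                               n_groups = 5, group_seed = 0L, window_s = 6,
                               alpha = NULL, n_perm = 1000, seed = 1L) {
  stopifnot(inherits(responses, "cog_responses"))
  vox <- if (is.null(region)) seq_len(ncol(responses$data)) else
    which(responses$voxel_meta$region == region)
  if (!length(vox)) stop("no voxels in region ", region)
  if (!is.null(voxel_exclude)) vox <- vox[!voxel_exclude]
  if (is.null(groups))
    groups <- split_task_groups(seq_len(design$n_tasks), n_groups, group_seed)

  bins <- design_bins(design)
  rd <- delay_expand(responses$data[, vox, drop = FALSE],
                     run_index = responses$run_index, tr_s = design$tr_s)
  ff <- apply_ctf(build_task_features(design), ctf)

  train_rows <- which(bins$split == "train" & bins$keep)
  test_rows <- which(bins$split == "test" & bins$keep)
  pos <- bins$pos[test_rows]
  x_test_avg <- average_repetitions(rd$data[test_rows, , drop = FALSE], pos)
  upos <- sort(unique(pos))

  task_pos <- rep_task_positions(design, window_s)
  dec_sum <- matrix(0, length(upos), ncol(ff$data))
  dec_cnt <- numeric(length(upos))
  alphas <- numeric(length(groups)); train_masks <- list()

  for (g in seq_along(groups)) {
    keep_mask <- exclude_target_timepoints(design, groups[[g]], window_s,
                                           mode = "train")
    tr <- train_rows[keep_mask[train_rows]]
    train_masks[[g]] <- keep_mask
    fitg <- fit_decoder(rd$data[tr, , drop = FALSE],
                        ff$data[tr, , drop = FALSE], alpha = alpha)
    alphas[g] <- fitg$alpha
    gpos <- sort(unique(unlist(task_pos[groups[[g]]])))
    sel <- which(upos %in% gpos)
    if (length(sel)) {
      dec <- x_test_avg[sel, , drop = FALSE] %*% fitg$weights
      dec_sum[sel, ] <- dec_sum[sel, ] + dec
      dec_cnt[sel] <- dec_cnt[sel] + 1
    }
  }
  covered <- dec_cnt > 0
  decoded <- dec_sum[covered, , drop = FALSE] / dec_cnt[covered]
  dpos <- upos[covered]

  sc <- task_scores(decoded, ctf, task_pos, dpos)
  sig <- test_task_significance(sc, n_perm = n_perm, seed = seed)
  c(sig,
    list(scores = sc, decoded = decoded, decoded_positions = dpos,
         groups = groups, alphas = alphas, train_masks = train_masks,
         voxels = vox))
}
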