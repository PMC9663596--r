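# Feature construction: one-hot task-type features, button-response counts,
# hemodynamic delay expansion, and cognitive-factor (CTF-transformed) features.

new_features <- function(data, feature_names, tr_s, delayed = FALSE) {
  data <- as.matrix(data)
  stopifnot(ncol(data) == length(feature_names))
  colnames(data) <- feature_names
  structure(list(data = data, feature_names = feature_names,
                 tr_s = tr_s, delayed = delayed),
            class = "cog_features")
}

#' One-hot task-type features
#'
#' Builds a time x task binary matrix over the design's full concatenated
#' timeline. A TR bin counts as "during" a trial iff the bin's start time
#' lies in `[onset, onset + duration)`; feedback and rest bins are all-zero,
#' so each row has at most one nonzero entry.
#'
#' @param design A `cog_design`.
#' @return A `cog_features` object with one column per task.
#' @export
build_task_features <- function(design) {
  if (design$n_tasks < 1) stop("design has no tasks")
  if (any(!design$trials$task %in% design$task_names))
    stop("unknown task label in trials")
  bins <- design_bins(design)
  tmat <- matrix(0, nrow(bins), design$n_tasks,
                 dimnames = list(NULL, design$task_names))
  run_offset <- c(0, cumsum(design$runs$duration_s / design$tr_s))
  names(run_offset) <- c(design$runs$run_id, "end")
  for (i in seq_len(nrow(design$trials))) {
    tr <- design$trials[i, ]
    off <- run_offset[as.character(tr$run_id)]
    b0 <- off + floor(tr$onset_s / design$tr_s) + 1
    # bins whose start lies in [onset, onset + duration)
    starts <- bins$t_in_run[bins$run_id == tr$run_id]
    sel <- which(starts >= tr$onset_s - 1e-9 &
                 starts < tr$onset_s + tr$duration_s - 1e-9)
    tmat[off + sel, tr$task_id] <- 1
  }
  new_features(tmat, design$task_names, design$tr_s)
}

#' Button-response features
#'
#' Counts button presses per TR bin for each of the four buttons (L1, L2,
#' R1, R2). Presses are counted per second and summed within each TR bin.
#'
#' @param design A `cog_design` with a `button_events` table.
#' @return A `cog_features` object with four columns.
#' @export
build_br_features <- function(design) {
  buttons <- c("L1", "L2", "R1", "R2")
  ev <- design$button_events
  if (is.null(ev)) stop("design has no button_events table")
  if (nrow(ev) && any(!ev$button %in% buttons))
    stop("unknown button_id: ", paste(setdiff(ev$button, buttons), collapse = ", "))
  bins <- design_bins(design)
  out <- matrix(0, nrow(bins), 4, dimnames = list(NULL, buttons))
  if (nrow(ev)) {
    run_offset <- c(0, cumsum(design$runs$duration_s / design$tr_s))
    names(run_offset) <- c(design$runs$run_id, "end")
    bin_idx <- run_offset[as.character(ev$run_id)] +
      floor(ev$time_s / design$tr_s) + 1
    for (b in seq_along(buttons)) {
      sel <- ev$button == buttons[b]
      if (any(sel)) {
        tab <- table(bin_idx[sel])
        out[as.integer(names(tab)), b] <- as.integer(tab)
      }
    }
  }
  new_features(out, buttons, design$tr_s)
}

#' Hemodynamic delay expansion
#'
#' Concatenates copies of a time x N feature matrix shifted by the given
#' delays (default 2, 4 and 6 s), producing a time x 3N design that absorbs
#' the slow hemodynamic response. Shifting is performed within each run
#' (zero-filled at run starts), so no information leaks across run
#' boundaries. Columns are delay-major: all N features at the first delay,
#' then all N at the second, etc., so per-delay weights are contiguous
#' slices.
#'
#' @param x A `cog_features` object or a plain time x N matrix.
#' @param run_index Per-timepoint run id (required for plain matrices;
#'   taken from `design_bins` otherwise not needed because features built by
#'   this package carry the full timeline).
#' @param tr_s Repetition time in seconds.
#' @param delays_s Delays in seconds, each a multiple of `tr_s`.
#' @return A `cog_delayed` object with fields `data`, `delays_s`,
#'   `source_feature_names`.
#' @export
delay_expand <- function(x, run_index, tr_s = NULL, delays_s = c(2, 4, 6)) {
  if (inherits(x, "cog_features")) {
    tr_s <- tr_s %||% x$tr_s
    feature_names <- x$feature_names
    m <- x$data
  } else {
    m <- as.matrix(x)
    feature_names <- colnames(m) %||% sprintf("f%d", seq_len(ncol(m)))
    if (is.null(tr_s)) stop("tr_s required for plain matrices")
  }
  if (length(run_index) != nrow(m))
    stop("run_index length must match the number of timepoints")
  if (any(delays_s %% tr_s != 0))
    stop("all delays must be multiples of tr_s")
  n <- ncol(m)
  out <- matrix(0, nrow(m), n * length(delays_s))
  runs <- unique(run_index)
  for (d in seq_along(delays_s)) {
    k <- delays_s[d] / tr_s
    cols <- (d - 1) * n + seq_len(n)
    for (r in runs) {
      idx <- which(run_index == r)
      if (k < length(idx)) {
        out[idx[(k + 1):length(idx)], cols] <- m[idx[1:(length(idx) - k)], , drop = FALSE]
      }
    }
  }
  colnames(out) <- paste0(rep(feature_names, length(delays_s)), "_d",
                          rep(delays_s, each = n))
  structure(list(data = out, delays_s = delays_s,
                 source_feature_names = feature_names, tr_s = tr_s),
            class = "cog_delayed")
}

#' Cognitive-factor features via the cognitive transform function
#'
#' Projects one-hot task features into a continuous term space by
#' multiplying with a tasks x terms CTF: each timepoint's row becomes the
#' CTF row of the task active at that timepoint (zeros elsewhere).
#'
#' @param task_features Undelayed `cog_features` from [build_task_features()].
#' @param ctf A tasks x terms matrix, or a `cog_ctf` object.
#' @return A `cog_features` object with one column per term.
#' @export
apply_ctf <- function(task_features, ctf) {
  if (inherits(ctf, "cog_ctf")) ctf <- ctf$matrix
  ctf <- as.matrix(ctf)
  if (isTRUE(task_features$delayed))
    stop("apply_ctf expects undelayed task features")
  if (ncol(task_features$data) != nrow(ctf))
    stop("task dimension mismatch: ", ncol(task_features$data),
         " features vs ", nrow(ctf), " CTF rows")
  out <- task_features$data %*% ctf
  terms <- colnames(ctf) %||% sprintf("term%04d", seq_len(ncol(ctf)))
  new_features(out, terms, task_features$tr_s)
}
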