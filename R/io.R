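# Plain-text serialization: BIDS-events-like TSV for designs, TSV matrices
# for responses/weights, and a loader that puts externally supplied data
# onto the same types the synthetic path produces.

#' Write design events as a BIDS-events-like TSV
#'
#' One row per trial/feedback/rest event with columns `onset`, `duration`,
#' `trial_type`, `run`, `split`.
#'
#' @param design A `cog_design`.
#' @param path Output file.
#' @export
write_events_tsv <- function(design, path) {
  ev <- rbind(
    data.frame(onset = design$trials$onset_s,
               duration = design$trials$duration_s,
               trial_type = design$trials$task,
               run = design$trials$run_id),
    data.frame(onset = design$feedback_events$onset_s,
               duration = design$feedback_events$duration_s,
               trial_type = "feedback",
               run = design$feedback_events$run_id),
    data.frame(onset = design$rest_events$onset_s,
               duration = design$rest_events$duration_s,
               trial_type = "rest",
               run = design$rest_events$run_id))
  ev$split <- design$runs$split[match(ev$run, design$runs$run_id)]
  ev <- ev[order(ev$run, ev$onset), ]
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-events-like TSV
#'
#' @param path Events TSV with columns `onset`, `duration`, `trial_type`,
#'   `run` (and optionally `split`).
#' @return Data frame of events.
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a numeric matrix as TSV
#'
#' @param m Matrix (column names become the header).
#' @param path Output file.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(as.matrix(m), path, sep = "\t", quote = FALSE,
                     row.names = FALSE,
                     col.names = colnames(m) %||% paste0("V", seq_len(ncol(m))))
  invisible(path)
}

#' Read a numeric matrix from TSV
#'
#' @param path File written by [write_matrix_tsv()].
#' @return Numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              check.names = FALSE))
}

#' Load externally supplied response data
#'
#' Assembles a `cog_responses` object (and per-bin bookkeeping) from a
#' response matrix TSV, an events TSV and a voxel-label TSV, so real data
#' flows through exactly the same downstream code path as synthetic data.
#'
#' @param response_file TSV of time x voxel responses.
#' @param events_file BIDS-events-like TSV (see [write_events_tsv()]);
#'   `trial_type` values other than `feedback`/`rest` are task labels.
#' @param labels_file TSV with one row per voxel and columns `region`,
#'   `subregion` (optional `subject_id`).
#' @param run_table Data frame with `run_id`, `duration_s`, `split`.
#' @param tr_s Repetition time in seconds.
#' @return List with `responses` (`cog_responses`) and `design`
#'   (`cog_design`).
#' @export
load_real_data <- function(response_file, events_file, labels_file,
                           run_table, tr_s = 2) {
  data <- read_matrix_tsv(response_file)
  ev <- read_events_tsv(events_file)
  meta <- utils::read.table(labels_file, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  if (nrow(meta) != ncol(data))
    stop("label/voxel count mismatch: ", labels_file, " has ", nrow(meta),
         " rows but ", response_file, " has ", ncol(data), " voxels")
  expected_rows <- sum(run_table$duration_s) / tr_s
  if (nrow(data) != expected_rows)
    stop("truncated response file ", response_file, ": expected ",
         expected_rows, " rows, found ", nrow(data))
  is_task <- !ev$trial_type %in% c("feedback", "rest")
  task_names <- sort(unique(ev$trial_type[is_task]))
  trials <- ev[is_task, ]
  trials <- data.frame(run_id = trials$run, task_id = match(trials$trial_type,
                                                            task_names),
                       onset_s = trials$onset, duration_s = trials$duration,
                       task = trials$trial_type, stringsAsFactors = FALSE)
  if (anyNA(trials$task_id)) stop("events contain an unknown task")
  fb <- ev[ev$trial_type == "feedback", ]
  rs <- ev[ev$trial_type == "rest", ]
  design <- structure(list(
    n_tasks = length(task_names), task_names = task_names, tr_s = tr_s,
    runs = run_table,
    trials = trials[order(trials$run_id, trials$onset_s), ],
    feedback_events = data.frame(run_id = fb$run, onset_s = fb$onset,
                                 duration_s = fb$duration),
    rest_events = data.frame(run_id = rs$run, onset_s = rs$onset,
                             duration_s = rs$duration),
    button_events = data.frame(run_id = integer(0), time_s = numeric(0),
                               button = character(0)),
    n_test_repetitions = 1L,
    test_bin_map = NULL, discard_initial_rest = FALSE,
    seed = NA_integer_), class = "cog_design")
  # single-repetition bin map over test runs
  bm <- list(); pos <- 0L
  for (i in which(run_table$split == "test")) {
    nb <- run_table$duration_s[i] / tr_s
    bm[[length(bm) + 1L]] <- data.frame(run_id = run_table$run_id[i],
                                        bin = seq_len(nb), rep = 1L,
                                        pos = pos + seq_len(nb))
    pos <- pos + nb
  }
  design$test_bin_map <- if (length(bm)) do.call(rbind, bm) else
    data.frame(run_id = integer(0), bin = integer(0), rep = integer(0),
               pos = integer(0))
  design$test_rep_len_s <- pos * tr_s
  bins <- design_bins(design)
  if (!"subject_id" %in% names(meta)) meta$subject_id <- "sub01"
  responses <- structure(list(
    data = data, voxel_meta = meta, run_index = bins$run_id,
    split = bins$split, keep = bins$keep, bins = bins, tr_s = tr_s,
    n_test_repetitions = 1L, preprocessed = FALSE),
    class = "cog_responses")
  list(responses = responses, design = design)
}
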