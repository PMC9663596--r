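# Synthetic multi-run event designs emulating a dense multitask fMRI session:
# trials of 6-12 s, 2-s feedback events, 6-s rest at the start and end of each
# run, pseudorandomized task order in training runs, and a fixed task order
# repeated a configurable number of times across the test runs.

# Draw `n` trial durations (multiples of tr_s within [lo, hi]) that sum
# exactly to `total`, by random draws followed by +/- tr_s repairs.
fill_durations <- function(n, total, tr_s, lo = 6, hi = 12) {
  lo <- ceiling(lo / tr_s) * tr_s
  hi <- floor(hi / tr_s) * tr_s
  if (n == 0) {
    if (total != 0) stop("cannot fill ", total, " s with no trials")
    return(numeric(0))
  }
  if (lo > hi) stop("no admissible trial duration for tr_s = ", tr_s)
  if (total < n * lo || total > n * hi || total %% tr_s != 0)
    stop("cannot fit ", n, " trials of ", lo, "-", hi, " s into ", total, " s")
  choices <- seq(lo, hi, by = tr_s)
  d <- sample(choices, n, replace = TRUE)
  guard <- 0L
  while (sum(d) != total) {
    step <- if (sum(d) > total) -tr_s else tr_s
    i <- sample.int(n, 1L)
    cand <- d[i] + step
    if (cand >= lo && cand <= hi) d[i] <- cand
    guard <- guard + 1L
    if (guard > 100000L) stop("duration repair failed to converge")
  }
  d
}

# Interleave m trials (with given durations and task ids) and f 2-s feedback
# events after a leading rest of `rest_s`, all within one contiguous segment.
# Feedbacks are placed after randomly chosen trials (never before the first).
layout_segment <- function(task_ids, durations, f, rest_s, seg_onset) {
  m <- length(task_ids)
  kinds <- character(0); tasks <- integer(0); durs <- numeric(0)
  if (rest_s > 0) {
    kinds <- "rest"; tasks <- NA_integer_; durs <- rest_s
  }
  if (m > 0) {
    slots <- if (f > 0) tabulate(sample.int(m, f, replace = TRUE), nbins = m)
             else integer(m)
    for (i in seq_len(m)) {
      kinds <- c(kinds, "trial"); tasks <- c(tasks, task_ids[i])
      durs <- c(durs, durations[i])
      if (slots[i] > 0) {
        kinds <- c(kinds, rep("feedback", slots[i]))
        tasks <- c(tasks, rep(NA_integer_, slots[i]))
        durs <- c(durs, rep(2, slots[i]))
      }
    }
  } else if (f > 0) {
    kinds <- c(kinds, rep("feedback", f))
    tasks <- c(tasks, rep(NA_integer_, f))
    durs <- c(durs, rep(2, f))
  }
  onset <- seg_onset + cumsum(c(0, durs))[seq_along(durs)]
  data.frame(kind = kinds, task_id = tasks, onset_s = onset,
             duration_s = durs, stringsAsFactors = FALSE)
}

# Split `total` items into k parts proportional to `weights` (largest
# remainder), respecting per-part [lo, hi] bounds.
apportion <- function(total, weights, lo, hi) {
  k <- length(weights)
  raw <- total * weights / sum(weights)
  parts <- floor(raw)
  rem <- total - sum(parts)
  if (rem > 0) {
    ord <- order(raw - parts, decreasing = TRUE)
    parts[ord[seq_len(rem)]] <- parts[ord[seq_len(rem)]] + 1
  }
  parts <- pmin(pmax(parts, lo), hi)
  guard <- 0L
  while (sum(parts) != total) {
    d <- total - sum(parts)
    if (d > 0) {
      i <- which(parts < hi)
      if (!length(i)) stop("apportion infeasible")
      i <- i[which.max(hi[i] - parts[i])]
      parts[i] <- parts[i] + 1
    } else {
      i <- which(parts > lo)
      if (!length(i)) stop("apportion infeasible")
      i <- i[which.max(parts[i] - lo[i])]
      parts[i] <- parts[i] - 1
    }
    guard <- guard + 1L
    if (guard > 10000L) stop("apportion failed to converge")
  }
  parts
}

# Build the repeated-order test template and its layout across test runs.
# Returns NULL if the repetition structure cannot fit.
build_test_replica <- function(n_tasks, n_test_runs, run_duration_s, tr_s,
                               n_rep, feedback_per_run) {
  content_run <- run_duration_s - 6          # 6-s end rest appended per run
  t0 <- n_test_runs * content_run
  # choose the smallest number of extra discarded feedbacks E so that the
  # remaining template divides into n_rep repetitions of whole TR bins
  found <- NULL
  for (E in 0:(min(t0 %/% 2, 4 * n_rep * tr_s))) {
    rl <- (t0 - 2 * E) / n_rep
    if (rl > 0 && rl %% tr_s == 0) { found <- list(E = E, rep_len = rl); break }
  }
  if (is.null(found)) return(NULL)
  E <- found$E; rep_len <- found$rep_len
  extras <- integer(n_test_runs)
  if (E > 0) {
    idx <- pmax(1L, pmin(n_test_runs, round(seq_len(E) * n_test_runs / E)))
    for (i in idx) extras[i] <- extras[i] + 1L
  }
  run_tmpl_len <- content_run - 2 * extras   # template seconds held by each run
  if (any(run_tmpl_len <= 0)) return(NULL)
  cum0 <- cumsum(c(0, run_tmpl_len))[seq_len(n_test_runs)]
  offsets <- sort(unique(cum0 %% rep_len))
  segs <- diff(c(offsets, offsets[1] + rep_len))
  if (any(segs < 12)) return(NULL)           # each segment: 6-s rest + >= 1 bin
  n_seg <- length(segs)
  content_rep <- rep_len - 6 * n_seg
  f_lo <- max(0, ceiling((content_rep - 12 * n_tasks) / 2))
  f_hi <- floor((content_rep - 6 * n_tasks) / 2)
  if (f_hi < f_lo) return(NULL)
  f_target <- round((feedback_per_run * n_test_runs - E) / n_rep)
  f_rep <- min(max(f_target, f_lo), f_hi)
  # split feedbacks then trials across segments
  for (attempt in 1:50) {
    f_seg <- tryCatch(
      apportion(f_rep, segs - 6, lo = rep(0, n_seg),
                hi = floor((segs - 6 - 6) / 2)),
      error = function(e) NULL)
    if (is.null(f_seg)) { f_rep <- max(f_lo, f_rep - 1); next }
    s_seg <- segs - 6 - 2 * f_seg
    m_lo <- ceiling(s_seg / 12); m_hi <- floor(s_seg / 6)
    if (sum(m_lo) <= n_tasks && n_tasks <= sum(m_hi)) {
      m_seg <- tryCatch(apportion(n_tasks, pmax(s_seg, 1), m_lo, m_hi),
                        error = function(e) NULL)
      if (!is.null(m_seg)) {
        return(list(E = E, rep_len = rep_len, extras = extras,
                    run_tmpl_len = run_tmpl_len, offsets = offsets,
                    segs = segs, f_seg = f_seg, s_seg = s_seg, m_seg = m_seg))
      }
    }
    if (f_rep > f_lo) f_rep <- f_rep - 1 else return(NULL)
  }
  NULL
}

#' Generate a synthetic multitask experiment design
#'
#' Creates a multi-run event design with 6-12 s trials, 2-s feedback events,
#' and 6-s no-task periods at the start and end of every run. Training runs
#' present the tasks in pseudorandomized order (concatenated random
#' permutations, so every task occurs in the training split); test runs
#' present all tasks in one fixed order repeated `n_test_repetitions` times
#' across the whole test split, with the 6-s end rests and a few extra
#' feedback bins marked as discarded so that the retained test timeline
#' divides exactly into identical repetitions. With the full-scale defaults
#' (103 tasks, 12 training + 6 test runs of 556 s, TR 2 s) this yields 3,336
#' training samples and 412 retained test samples per repetition. If the
#' repetition structure cannot fit (very small designs), the test split falls
#' back to a single pseudorandomized pass covering every task.
#'
#' @param n_tasks Number of distinct tasks (>= 2).
#' @param n_train_runs,n_test_runs Run counts per split.
#' @param run_duration_s Run duration in seconds (multiple of `tr_s`).
#' @param seed Integer seed; the design is a pure function of it.
#' @param tr_s Repetition time in seconds (default 2).
#' @param n_test_repetitions Target number of identical test repetitions
#'   (default 4).
#' @param feedback_per_run Target number of 2-s feedback events per run
#'   (default 11, i.e. within the 9-13 range of the emulated sessions).
#' @param button_task_frac Fraction of tasks that elicit button presses
#'   (default 0.25); each such task is bound to one of the four buttons.
#' @param press_rate_hz Mean press rate during button-task trials (default 1).
#' @param discard_initial_rest If `TRUE`, the 6-s rest opening each run is
#'   marked as discarded from analysis; by default it is retained, matching
#'   the sample count convention above.
#' @return An object of class `cog_design`.
#' @export
generate_design <- function(n_tasks, n_train_runs, n_test_runs, run_duration_s,
                            seed = 0L, tr_s = 2, n_test_repetitions = 4,
                            feedback_per_run = 11, button_task_frac = 0.25,
                            press_rate_hz = 1, discard_initial_rest = FALSE) {
  n_tasks <- as.integer(n_tasks)
  n_test_repetitions <- as.integer(n_test_repetitions)
  if (n_tasks < 2) stop("n_tasks must be at least 2")
  if (run_duration_s %% tr_s != 0) stop("run_duration_s must be a multiple of tr_s")
  if (n_train_runs < 1 || n_test_runs < 1) stop("need at least one run per split")
  with_seed(seed, {
    task_names <- sprintf("task%03d", seq_len(n_tasks))
    runs <- data.frame(
      run_id = seq_len(n_train_runs + n_test_runs),
      duration_s = run_duration_s,
      split = rep(c("train", "test"), c(n_train_runs, n_test_runs)),
      stringsAsFactors = FALSE)

    events <- list(); bin_map <- list()

    # ---- training runs: stream of concatenated permutations ----
    content <- run_duration_s - 12
    f_lo <- max(0, ceiling((content - 12 * n_tasks * 100) / 2)) # no upper trial cap
    f_run <- feedback_per_run
    # per-run trial count bounds given f_run feedbacks
    pick_m <- function(s) {
      m_lo <- ceiling(s / 12); m_hi <- floor(s / 6)
      if (m_hi < 1) stop("run too short to place any trial (capacity error)")
      min(max(round(s / 9), m_lo), m_hi)
    }
    f_run <- min(f_run, max(0, floor((content - 6) / 2) - 3))
    s_run <- content - 2 * f_run
    m_run <- pick_m(s_run)
    if (m_run * n_train_runs < n_tasks)
      stop("training runs too short to present every task (capacity error)")
    stream <- unlist(lapply(seq_len(ceiling(m_run * n_train_runs / n_tasks) + 1),
                            function(i) sample.int(n_tasks)))
    ptr <- 1L
    for (r in which(runs$split == "train")) {
      ids <- stream[ptr:(ptr + m_run - 1L)]; ptr <- ptr + m_run
      durs <- fill_durations(m_run, s_run, tr_s)
      seg <- layout_segment(ids, durs, f_run, rest_s = 6, seg_onset = 0)
      seg <- rbind(seg, data.frame(kind = "rest", task_id = NA_integer_,
                                   onset_s = run_duration_s - 6, duration_s = 6))
      seg$run_id <- r
      events[[length(events) + 1L]] <- seg
    }

    # ---- test runs: repeated fixed-order template when it fits ----
    test_order <- sample.int(n_tasks)
    replica <- if (n_test_repetitions >= 2)
      build_test_replica(n_tasks, n_test_runs, run_duration_s, tr_s,
                         n_test_repetitions, feedback_per_run) else NULL
    test_run_ids <- which(runs$split == "test")

    if (!is.null(replica)) {
      n_rep <- n_test_repetitions
      durs <- fill_durations(n_tasks, sum(replica$s_seg), tr_s)
      # durations must respect the per-segment totals: refill per segment
      idx0 <- 0L
      tmpl <- list(); seg_onset <- 0
      for (j in seq_along(replica$segs)) {
        m <- replica$m_seg[j]
        ids <- test_order[(idx0 + 1L):(idx0 + m)]; idx0 <- idx0 + m
        dj <- fill_durations(m, replica$s_seg[j], tr_s)
        tmpl[[j]] <- layout_segment(ids, dj, replica$f_seg[j],
                                    rest_s = 6, seg_onset = seg_onset)
        seg_onset <- seg_onset + replica$segs[j]
      }
      tmpl <- do.call(rbind, tmpl)
      # unroll the template n_rep times and cut into runs
      stream_ev <- do.call(rbind, lapply(seq_len(n_rep), function(k) {
        e <- tmpl; e$onset_s <- e$onset_s + (k - 1) * replica$rep_len; e
      }))
      run_start <- cumsum(c(0, replica$run_tmpl_len))
      for (i in seq_along(test_run_ids)) {
        r <- test_run_ids[i]
        lo <- run_start[i]; hi <- run_start[i] + replica$run_tmpl_len[i]
        sel <- stream_ev$onset_s >= lo - 1e-9 & stream_ev$onset_s < hi - 1e-9
        seg <- stream_ev[sel, , drop = FALSE]
        seg$onset_s <- seg$onset_s - lo
        extra <- replica$extras[i]
        app <- data.frame(kind = c(rep("feedback", extra), "rest"),
                          task_id = NA_integer_,
                          onset_s = run_duration_s - 6 - 2 * extra +
                            c(if (extra > 0) 2 * (seq_len(extra) - 1) else numeric(0), 2 * extra),
                          duration_s = c(rep(2, extra), 6))
        seg <- rbind(seg, app)
        seg$run_id <- r
        events[[length(events) + 1L]] <- seg
        # bin map: retained bins carry repetition index and within-rep position
        n_bins <- run_duration_s / tr_s
        starts <- (seq_len(n_bins) - 1) * tr_s
        tmpl_pos <- lo + starts
        keep <- starts < run_duration_s - 6 - 2 * extra
        rep_idx <- ifelse(keep, tmpl_pos %/% replica$rep_len + 1, NA_integer_)
        pos <- ifelse(keep, (tmpl_pos %% replica$rep_len) / tr_s + 1, NA_integer_)
        bin_map[[length(bin_map) + 1L]] <-
          data.frame(run_id = r, bin = seq_len(n_bins),
                     rep = as.integer(rep_idx), pos = as.integer(pos))
      }
      rep_len <- replica$rep_len
    } else {
      n_rep <- 1L
      # single-pass test split built like a training run but covering all tasks
      f_run <- min(feedback_per_run, max(0, floor((content - 6 * 1) / 2) - 3))
      total_content <- n_test_runs * content
      # choose per-run trial counts so all tasks fit at least once
      s_run <- content - 2 * f_run
      m_run <- tryCatch(pick_m(s_run), error = function(e) stop(
        "test run too short to place any trial (capacity error)"))
      if (m_run * n_test_runs < n_tasks)
        stop("test runs too short to present every task (capacity error)")
      stream <- unlist(lapply(seq_len(ceiling(m_run * n_test_runs / n_tasks) + 1),
                              function(i) sample.int(n_tasks)))
      # force coverage: lead with one full fixed order
      stream <- c(test_order, stream)
      ptr <- 1L
      pos_counter <- 0L
      for (r in test_run_ids) {
        ids <- stream[ptr:(ptr + m_run - 1L)]; ptr <- ptr + m_run
        durs <- fill_durations(m_run, s_run, tr_s)
        seg <- layout_segment(ids, durs, f_run, rest_s = 6, seg_onset = 0)
        seg <- rbind(seg, data.frame(kind = "rest", task_id = NA_integer_,
                                     onset_s = run_duration_s - 6, duration_s = 6))
        seg$run_id <- r
        events[[length(events) + 1L]] <- seg
        n_bins <- run_duration_s / tr_s
        bin_map[[length(bin_map) + 1L]] <-
          data.frame(run_id = r, bin = seq_len(n_bins), rep = 1L,
                     pos = pos_counter + seq_len(n_bins))
        pos_counter <- pos_counter + n_bins
      }
      rep_len <- pos_counter * tr_s
    }

    events <- do.call(rbind, events)
    rownames(events) <- NULL
    trials <- events[events$kind == "trial",
                     c("run_id", "task_id", "onset_s", "duration_s")]
    trials$task <- task_names[trials$task_id]
    rownames(trials) <- NULL
    feedback <- events[events$kind == "feedback",
                       c("run_id", "onset_s", "duration_s")]
    rownames(feedback) <- NULL
    rest <- events[events$kind == "rest", c("run_id", "onset_s", "duration_s")]
    rownames(rest) <- NULL

    # button events: a fixed subset of tasks maps to one of four buttons
    buttons <- c("L1", "L2", "R1", "R2")
    n_btn_tasks <- round(button_task_frac * n_tasks)
    btn_assign <- rep(NA_character_, n_tasks)
    if (n_btn_tasks > 0) {
      bt <- sample.int(n_tasks, n_btn_tasks)
      btn_assign[bt] <- buttons[(seq_along(bt) - 1L) %% 4L + 1L]
    }
    press <- list()
    for (i in seq_len(nrow(trials))) {
      b <- btn_assign[trials$task_id[i]]
      if (is.na(b)) next
      np <- stats::rpois(1, press_rate_hz * trials$duration_s[i])
      if (np == 0) next
      press[[length(press) + 1L]] <- data.frame(
        run_id = trials$run_id[i],
        time_s = sort(stats::runif(np, trials$onset_s[i],
                                   trials$onset_s[i] + trials$duration_s[i] - 1e-6)),
        button = b, stringsAsFactors = FALSE)
    }
    button_events <- if (length(press)) do.call(rbind, press) else
      data.frame(run_id = integer(0), time_s = numeric(0),
                 button = character(0), stringsAsFactors = FALSE)
    rownames(button_events) <- NULL

    design <- structure(list(
      n_tasks = n_tasks, task_names = task_names, tr_s = tr_s,
      runs = runs, trials = trials, feedback_events = feedback,
      rest_events = rest,
      button_events = button_events, button_assignment = btn_assign,
      n_test_repetitions = n_rep, test_rep_len_s = rep_len,
      test_bin_map = do.call(rbind, bin_map),
      discard_initial_rest = discard_initial_rest,
      seed = as.integer(seed)), class = "cog_design")
    validate_design(design)
    design
  })
}

validate_design <- function(design) {
  tr <- design$tr_s
  for (r in design$runs$run_id) {
    ev <- design_events_in_run(design, r)
    ev <- ev[order(ev$onset_s), ]
    if (nrow(ev)) {
      ends <- ev$onset_s + ev$duration_s
      if (any(ev$onset_s[-1] < ends[-nrow(ev)] - 1e-9))
        stop("overlapping events in run ", r)
      if (abs(max(ends) - design$runs$duration_s[design$runs$run_id == r]) > 1e-9)
        stop("run ", r, " does not fill its duration exactly")
    }
    tri <- design$trials[design$trials$run_id == r, ]
    if (nrow(tri) && (any(tri$duration_s < 6 - 1e-9) || any(tri$duration_s > 12 + 1e-9)))
      stop("trial duration outside [6, 12] s in run ", r)
  }
  for (sp in c("train", "test")) {
    rr <- design$runs$run_id[design$runs$split == sp]
    present <- unique(design$trials$task_id[design$trials$run_id %in% rr])
    if (length(present) < design$n_tasks)
      stop("not every task appears in the ", sp, " split")
  }
  invisible(design)
}

# All events (trials, feedback, rest) of one run.
design_events_in_run <- function(design, run_id) {
  tri <- design$trials[design$trials$run_id == run_id,
                       c("onset_s", "duration_s")]
  fb <- design$feedback_events[design$feedback_events$run_id == run_id,
                               c("onset_s", "duration_s")]
  rs <- design$rest_events[design$rest_events$run_id == run_id,
                           c("onset_s", "duration_s")]
  rbind(tri, fb, rs)
}

#' Per-bin bookkeeping for a design
#'
#' Returns one row per TR bin of the concatenated timeline (runs in order):
#' run id, split, bin start time within the run, whether the bin is retained
#' for analysis, and for retained test bins the repetition index and the
#' position within the repetition template.
#'
#' @param design A `cog_design`.
#' @return A data.frame with columns `run_id`, `split`, `t_in_run`, `keep`,
#'   `rep`, `pos`.
#' @export
design_bins <- function(design) {
  tr <- design$tr_s
  out <- lapply(seq_len(nrow(design$runs)), function(i) {
    r <- design$runs$run_id[i]
    nb <- design$runs$duration_s[i] / tr
    df <- data.frame(run_id = r, split = design$runs$split[i],
                     t_in_run = (seq_len(nb) - 1) * tr,
                     keep = TRUE, rep = NA_integer_, pos = NA_integer_)
    if (design$runs$split[i] == "test") {
      bm <- design$test_bin_map[design$test_bin_map$run_id == r, ]
      df$rep <- bm$rep[match(seq_len(nb), bm$bin)]
      df$pos <- bm$pos[match(seq_len(nb), bm$bin)]
      df$keep <- !is.na(df$pos)
    }
    if (design$discard_initial_rest) df$keep[df$t_in_run < 6] <- FALSE
    df
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Number of retained samples per split
#'
#' @param design A `cog_design`.
#' @return Named list with `train` (retained training bins), `test_total`
#'   (retained test bins across repetitions) and `test_per_repetition`.
#' @export
design_sample_counts <- function(design) {
  b <- design_bins(design)
  list(train = sum(b$split == "train" & b$keep),
       test_total = sum(b$split == "test" & b$keep),
       test_per_repetition = length(unique(stats::na.omit(b$pos))))
}

#' @export
print.cog_design <- function(x, ...) {
  cnt <- design_sample_counts(x)
  cat("<cog_design> ", x$n_tasks, " tasks, ",
      sum(x$runs$split == "train"), " train + ",
      sum(x$runs$split == "test"), " test runs of ",
      x$runs$duration_s[1], " s (TR ", x$tr_s, " s)\n",
      "  trials: ", nrow(x$trials), "; test repetitions: ",
      x$n_test_repetitions, "\n",
      "  samples: ", cnt$train, " train, ", cnt$test_per_repetition,
      " test per repetition\n", sep = "")
  invisible(x)
}
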