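test_that("designs are deterministic, exactly packed, and cover all tasks", {
  d1 <- small_design(); d2 <- small_design()
  expect_identical(d1, d2)
  expect_false(identical(d1, small_design(seed = 99L)))

  for (d in list(tiny_design(), d1)) {
    # every run's trial + feedback + rest time fills the run exactly
    for (r in d$runs$run_id) {
      tot <- sum(d$trials$duration_s[d$trials$run_id == r]) +
        sum(d$feedback_events$duration_s[d$feedback_events$run_id == r]) +
        sum(d$rest_events$duration_s[d$rest_events$run_id == r])
      expect_equal(tot, d$runs$duration_s[d$runs$run_id == r])
    }
    # trials ordered, non-overlapping, durations within [6, 12]
    for (r in d$runs$run_id) {
      tri <- d$trials[d$trials$run_id == r, ]
      if (nrow(tri) > 1) {
        expect_true(all(diff(tri$onset_s) > 0))
        expect_true(all(tri$onset_s[-1] >=
                          (tri$onset_s + tri$duration_s)[-nrow(tri)]))
      }
      expect_true(all(tri$duration_s >= 6 & tri$duration_s <= 12))
    }
    # both splits present every task
    for (sp in c("train", "test")) {
      rr <- d$runs$run_id[d$runs$split == sp]
      expect_setequal(unique(d$trials$task_id[d$trials$run_id %in% rr]),
                      seq_len(d$n_tasks))
    }
  }
})

test_that("the full-scale replica design yields the published sample counts", {
  d <- generate_design(103, 12, 6, 556, seed = 0)
  cnt <- design_sample_counts(d)
  expect_identical(cnt$train, 3336L)
  expect_identical(cnt$test_per_repetition, 412L)
  expect_identical(d$n_test_repetitions, 4L)
  # feedback occurs 9-13 times per run
  fb <- table(factor(d$feedback_events$run_id, levels = d$runs$run_id))
  expect_true(all(fb >= 9 & fb <= 13))
})

test_that("test runs repeat the same task order in every repetition", {
  d <- small_design()
  bins <- design_bins(d)
  f <- build_task_features(d)$data
  # per (rep, pos), the active task must be identical across repetitions
  test <- bins$split == "test" & bins$keep
  task_at <- apply(f[test, , drop = FALSE], 1, function(r)
    if (any(r > 0)) which(r > 0) else 0L)
  by_pos <- split(task_at, bins$pos[test])
  expect_true(all(vapply(by_pos, function(v) length(unique(v)) == 1,
                         logical(1))))
  expect_identical(d$n_test_repetitions, 4L)
})

test_that("tiny designs fall back to a single covered test pass", {
  d <- generate_design(2, 1, 1, 60, seed = 0)
  expect_identical(d$n_test_repetitions, 1L)
  expect_setequal(unique(d$trials$task_id), 1:2)
})

test_that("impossible designs raise a capacity error", {
  expect_error(generate_design(50, 1, 1, 60, seed = 0), "capacity")
})

test_that("ground-truth geometry dial is recovered by RSA on true weights", {
  d <- memo("dial_design", function()
    generate_design(50, 2, 1, 600, seed = 5))
  regions <- c(cortex = 120, cerebellum = 80)
  for (s in c(0, 0.5, 0.9)) {
    tr <- generate_ground_truth(d, regions, cross_region_similarity = s,
                                seed = 7)
    rsm_a <- compute_rsm(tr$weights_by_region$cortex)
    rsm_b <- compute_rsm(tr$weights_by_region$cerebellum)
    expect_lt(abs(compare_rsms(rsm_a, rsm_b)$rho - s), 0.051)
  }
  # the fully shared limit gives identical similarity matrices
  tr1 <- generate_ground_truth(d, regions, cross_region_similarity = 1,
                               seed = 7)
  expect_equal(compute_rsm(tr1$weights_by_region$cortex)$matrix,
               compute_rsm(tr1$weights_by_region$cerebellum)$matrix,
               tolerance = 1e-10)
})

test_that("independent-geometry regions decorrelate over many seeds", {
  d <- memo("dial_design", function()
    generate_design(50, 2, 1, 600, seed = 5))
  rhos <- vapply(1:20, function(sd) {
    tr <- generate_ground_truth(d, c(a = 60, b = 60),
                                cross_region_similarity = 0, seed = sd)
    compare_rsms(compute_rsm(tr$weights_by_region$a),
                 compute_rsm(tr$weights_by_region$b))$rho
  }, numeric(1))
  expect_lt(mean(abs(rhos)), 0.15)
})

test_that("simulated responses are seed-pure and respect the SNR limits", {
  d <- tiny_design()
  tr <- generate_ground_truth(d, c(cortex = 30), cross_region_similarity = 1,
                              snr = Inf, drift_amplitude = 0, seed = 1)
  r1 <- simulate_responses(d, tr, noise_seed = 4)
  r2 <- simulate_responses(d, tr, noise_seed = 4)
  expect_identical(r1$data, r2$data)
  tr_noisy <- generate_ground_truth(d, c(cortex = 30),
                                    cross_region_similarity = 1,
                                    snr = 1, seed = 1)
  expect_identical(simulate_responses(d, tr_noisy, noise_seed = 4)$data,
                   simulate_responses(d, tr_noisy, noise_seed = 4)$data)
  expect_false(identical(simulate_responses(d, tr_noisy, noise_seed = 4)$data,
                         simulate_responses(d, tr_noisy, noise_seed = 5)$data))

  # noiseless limit: small-alpha encoding fit recovers the true weights
  bins <- design_bins(d)
  fd <- delay_expand(build_task_features(d), run_index = bins$run_id)
  train <- bins$split == "train"
  fit <- ridge_fit(fd$data[train, ], r1$data[train, ], alpha = 1e-8,
                   feature_names = d$task_names)
  wa <- delay_average_weights(fit)
  rec <- diag(cor(t(wa), t(tr$weights_by_region$cortex)))
  expect_true(all(rec > 0.99))

  # pure-noise limit: prediction accuracy centers on zero
  tr0 <- generate_ground_truth(d, c(cortex = 40), cross_region_similarity = 1,
                               snr = 0, drift_amplitude = 0, seed = 1)
  r0 <- suppressWarnings(preprocess_responses(simulate_responses(d, tr0, noise_seed = 4)))
  fit0 <- ridge_fit(fd$data[train, ], r0$data[train, ], alpha = 1,
                    feature_names = d$task_names)
  ev0 <- evaluate_encoding(fit0, fd$data[!train, ], r0$data[!train, ],
                           pos = bins$pos[!train])
  expect_lt(abs(median(ev0$r)), 0.2)
})

test_that("preprocessing z-scores every voxel within every run", {
  d <- tiny_design()
  tr <- generate_ground_truth(d, c(cortex = 25), cross_region_similarity = 1,
                              snr = 1, seed = 2)
  r <- suppressWarnings(preprocess_responses(simulate_responses(d, tr, noise_seed = 1)))
  for (run in unique(r$run_index)) {
    x <- r$data[r$run_index == run, ]
    expect_lt(max(abs(colMeans(x))), 1e-6)
    expect_lt(max(abs(apply(x, 2, sd) - 1)), 1e-6)
  }
})

test_that("the term atlas has the documented shape and alignment behavior", {
  d <- tiny_design()
  tr <- generate_ground_truth(d, c(cortex = 30), cross_region_similarity = 1,
                              seed = 3)
  at <- generate_term_atlas(tr, seed = 1)
  expect_identical(nrow(at$term_maps), 715L)
  # identity mixing at full alignment reproduces the task maps themselves
  at_id <- generate_term_atlas(tr, n_terms = d$n_tasks, alignment = 1,
                               seed = 1, mixing = diag(d$n_tasks))
  w <- tr$weights_by_region$cortex
  ctf <- build_ctf(list(a = w, b = w), at_id, "a")
  expect_equal(unname(ctf$matrix),
               unname(cor(t(w), t(at_id$term_maps))), tolerance = 1e-8)
  expect_true(all(diag(ctf$matrix) > 0.999))
})
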