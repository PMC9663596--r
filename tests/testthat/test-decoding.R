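test_that("CTF construction is leave-one-subject-out and hand-verifiable", {
  # 2 tasks x 2 terms toy with hand-computable correlations
  w1 <- rbind(c(1, 2, 3, 4), c(4, 3, 2, 1))
  w2 <- rbind(c(1, 3, 2, 4), c(2, 1, 4, 3))
  atlas <- structure(list(term_names = c("tm1", "tm2"),
                          term_maps = rbind(c(1, 2, 4, 3), c(4, 4, 1, 1))),
                     class = "cog_term_atlas")
  ctf_a <- build_ctf(list(a = w1, b = w2), atlas, "a")
  expect_identical(ctf_a$excluded_subject, "a")
  expect_identical(ctf_a$source_subjects, "b")
  expect_equal(unname(ctf_a$matrix),
               unname(cor(t(w2), t(atlas$term_maps))), tolerance = 1e-12)
  # target's own data never enters its CTF
  w1_pert <- w1 + matrix(rnorm(8), 2, 4)
  ctf_a2 <- build_ctf(list(a = w1_pert, b = w2), atlas, "a")
  expect_identical(ctf_a$matrix, ctf_a2$matrix)
  # identical subjects: CTF equals any single subject's matrix
  ctf_id <- build_ctf(list(a = w1, b = w1, c = w1), atlas, "c")
  expect_equal(unname(ctf_id$matrix), unname(cor(t(w1), t(atlas$term_maps))))
  expect_error(build_ctf(list(a = w1), atlas, "a"), "at least 2")
})

test_that("task groups partition evenly and reproducibly", {
  g <- split_task_groups(1:103, 5, seed = 1)
  expect_setequal(unlist(g), 1:103)
  expect_setequal(lengths(g), c(21, 21, 21, 20, 20))
  expect_identical(g, split_task_groups(1:103, 5, seed = 1))
  expect_false(identical(g, split_task_groups(1:103, 5, seed = 2)))
  expect_true(all(lengths(split_task_groups(1:10, 5, seed = 1)) == 2))
  expect_error(split_task_groups(1:3, 5), "more groups")
})

test_that("target-timepoint masks cover trials plus the 6-s tail exactly", {
  # single trial at 10-18 s: excluded bins must span 10-24 s
  design <- tiny_design()
  tri <- design$trials[1, ]
  mask <- exclude_target_timepoints(design, tri$task_id, mode = "train")
  bins <- design_bins(design)
  in_run <- bins$run_id == tri$run_id
  trials_of_task <- design$trials[design$trials$task_id == tri$task_id, ]
  expected_excluded <- rep(FALSE, nrow(bins))
  run_off <- c(0, cumsum(design$runs$duration_s / design$tr_s))
  for (i in seq_len(nrow(trials_of_task))) {
    tt <- trials_of_task[i, ]
    sel <- which(bins$run_id == tt$run_id &
                 bins$t_in_run >= tt$onset_s &
                 bins$t_in_run < tt$onset_s + tt$duration_s + 6)
    expected_excluded[sel] <- TRUE
  }
  expect_identical(!mask, expected_excluded)
  # test mode is the complement logic
  expect_identical(exclude_target_timepoints(design, tri$task_id,
                                             mode = "test"),
                   expected_excluded)
  # no target tasks: everything kept
  expect_true(all(exclude_target_timepoints(design, integer(0),
                                            mode = "train")))
  expect_error(exclude_target_timepoints(design, 1, window_s = 3), "multiple")
})

test_that("decoders invert noiseless linear systems and shrink to zero", {
  set.seed(17)
  n <- 80; v <- 20; k <- 6
  x <- matrix(rnorm(n * v), n, v)
  b <- matrix(rnorm(v * k), v, k)
  y <- x %*% b
  fit <- fit_decoder(x, y, alpha = 1e-8)
  expect_gt(min(colwise_cor(x %*% fit$weights, y)), 0.999)
  fit_inf <- fit_decoder(x, y, alpha = 1e12)
  expect_lt(max(abs(x %*% fit_inf$weights)), 1e-4)
  # uninformative voxels decode nothing
  y_ind <- matrix(rnorm(n * k), n, k)
  fit0 <- fit_decoder(x[1:40, ], y_ind[1:40, ], alpha = 10)
  r <- colwise_cor(x[41:80, ] %*% fit0$weights, y_ind[41:80, ])
  expect_lt(mean(abs(r)), 0.35)
})

test_that("task scores recover planted CTF rows and zero out orthogonality", {
  set.seed(18)
  n_tasks <- 4; n_terms <- 12
  ctf <- matrix(rnorm(n_tasks * n_terms), n_tasks, n_terms,
                dimnames = list(paste0("t", 1:n_tasks), NULL))
  task_pos <- split(1:8, rep(1:n_tasks, each = 2))
  decoded <- ctf[rep(1:n_tasks, each = 2), ]
  sc <- task_scores(decoded, ctf, task_pos, positions = 1:8)
  expect_equal(unname(sc$task_score), rep(1, n_tasks), tolerance = 1e-12)
  # 3-task toy verified by direct correlation
  d3 <- matrix(rnorm(3 * n_terms), 3, n_terms)
  sc3 <- task_scores(d3, ctf, split(1:3, 1:3)[c(1, 2, 3, 1)], positions = 1:3)
  for (i in 1:3) for (k in 1:n_tasks)
    expect_equal(sc3$cross_scores[i, k], cor(d3[i, ], ctf[k, ]))
  # orthogonal decoded vectors score ~0 (centered random vs centered random)
  dec0 <- matrix(rnorm(200 * n_terms), 200, n_terms)
  sc0 <- task_scores(dec0, ctf,
                     c(list(1:200), rep(list(integer(0)), n_tasks - 1)),
                     positions = 1:200)
  expect_lt(abs(sc0$cross_scores[1, 1]), 0.15)
})

test_that("one-vs-one accuracy matches brute-force comparison counting", {
  cross <- rbind(c(0.9, 0.1, 0.3), c(0.2, 0.5, 0.5), c(0.4, 0.6, 0.2))
  acc <- one_vs_one_accuracy(cross)
  # task 1 beats both (acc 1); task 2 beats task 1 and ties task 3 (0.75);
  # task 3 loses both (0)
  expect_equal(as.vector(acc), c(1, 0.75, 0))
  # target always highest
  expect_equal(as.vector(one_vs_one_accuracy(diag(3) + 1))[1], 1)
  # i.i.d. scores average to chance over many draws
  set.seed(19)
  mean_acc <- mean(replicate(200, {
    m <- matrix(rnorm(25), 5, 5)
    mean(one_vs_one_accuracy(m))
  }))
  expect_lt(abs(mean_acc - 0.5), 0.02)
})

test_that("sign tests and label permutations calibrate the decoding metrics", {
  set.seed(20)
  n <- 20
  cross <- matrix(rnorm(n * n), n, n)
  sc <- list(cross_scores = cross)
  out <- test_task_significance(sc, n_perm = 300, seed = 4)
  expect_true(all(out$p_sign >= 0 & out$p_sign <= 1))
  expect_true(all(out$q >= out$p_sign - 1e-12))
  # null data: permutation p not extreme, mean accuracy near 0.5
  expect_gt(out$perm$p_accuracy, 0.01)
  expect_lt(abs(mean(out$perm$null_accuracy) - 0.5), 0.05)
  expect_lt(abs(mean(out$perm$null_score)), 0.1)
  # strong diagonal: everything significant
  cross2 <- matrix(0, n, n); diag(cross2) <- 1
  out2 <- test_task_significance(list(cross_scores = cross2),
                                 n_perm = 300, seed = 4)
  expect_true(all(out2$significant))
  expect_equal(out2$perm$p_accuracy, 1 / 301)
})
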