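test_that("PCA spaces reproduce known spectra and reconstruct the input", {
  # orthonormal construction with a known spectrum
  set.seed(12)
  # task-side basis orthogonal to the constant vector, so column means are
  # zero and the planted spectrum survives centering exactly
  q <- qr.Q(qr(cbind(1, matrix(rnorm(90), 10, 9))))[, 2:5]
  v <- qr.Q(qr(matrix(rnorm(400), 20, 20)))[, 1:4]
  ev <- c(9, 4, 1, 0.25)
  x <- q %*% diag(sqrt(ev * 9)) %*% t(v)  # tasks x voxels, rank 4
  sp <- fit_cognitive_space(x, n_pcs = 4)
  expect_equal(sp$explained_variance_ratio, ev / sum(ev), tolerance = 1e-6)
  # full reconstruction from loadings and scores
  rec <- sp$loadings %*% t(sp$scores)
  expect_equal(rec + matrix(sp$center, 10, 20, byrow = TRUE), x,
               tolerance = 1e-8)
  # rank-1 input: PC1 explains ~everything
  x1 <- outer(rnorm(8), rnorm(30))
  sp1 <- fit_cognitive_space(x1, n_pcs = 2)
  expect_gt(sp1$explained_variance_ratio[1], 0.999)
  expect_error(fit_cognitive_space(x1, n_pcs = 50), "n_pcs")
  # task permutation permutes loadings correspondingly
  perm <- sample(10)
  sp_p <- fit_cognitive_space(x[perm, ], n_pcs = 4)
  expect_equal(abs(sp_p$loadings), abs(sp$loadings[perm, ]), tolerance = 1e-6)
})

test_that("2-D maps read coordinates from loadings with min-max colors", {
  set.seed(13)
  x <- matrix(rnorm(6 * 40), 6, 40,
              dimnames = list(paste0("t", 1:6), NULL))
  sp <- fit_cognitive_space(x, n_pcs = 3)
  m <- map_tasks_2d(sp)
  expect_equal(m$x, unname(sp$loadings[, 1]))
  expect_equal(m$y, unname(sp$loadings[, 2]))
  expect_equal(m$r[which.max(m$x)], 1)
  expect_equal(m$r[which.min(m$x)], 0)
  expect_true(all(m$r >= 0 & m$r <= 1 & m$b >= 0 & m$b <= 1))
  # degenerate channel pinned at 0.5
  spd <- sp; spd$loadings[, 3] <- 2
  expect_true(all(map_tasks_2d(spd)$b == 0.5))
})

test_that("score maps are z-normalized per subject", {
  set.seed(14)
  x <- matrix(rnorm(8 * 60), 8, 60)
  sp <- fit_cognitive_space(x, n_pcs = 3)
  subj <- rep(c("s1", "s2"), each = 30)
  m1 <- pc_score_map(sp, subjects = subj, subject_id = "s1")
  expect_identical(nrow(m1), 30L)
  expect_lt(max(abs(colMeans(m1))), 1e-12)
  expect_equal(unname(apply(m1, 2, sd)), rep(1, 3))
  expect_error(pc_score_map(sp, subjects = subj, subject_id = "nope"),
               "unknown subject")
  # all voxels when no subject requested
  expect_identical(nrow(pc_score_map(sp)), 60L)
})

test_that("PC interpretation ranks planted terms at the top", {
  set.seed(15)
  v <- 200
  maps <- matrix(rnorm(v * 2), v, 2)
  atlas <- list(term_names = c(paste0("noise", 1:20), "planted"),
                term_maps = rbind(matrix(rnorm(20 * v), 20), t(maps[, 1])))
  class(atlas) <- "cog_term_atlas"
  interp <- interpret_pcs(maps, atlas, n_top = 5)
  expect_identical(interp[[1]]$top_terms[1], "planted")
  expect_gt(interp[[1]]$correlations[1], 0.999)
  # pure-noise terms correlate weakly
  expect_lt(max(abs(interp[[2]]$correlations[names(interp[[2]]$correlations)
                                             != "planted"])), 0.35)
  # consistent voxel permutation leaves interpretation unchanged
  perm <- sample(v)
  atlas_p <- atlas; atlas_p$term_maps <- atlas$term_maps[, perm]
  interp_p <- interpret_pcs(maps[perm, ], atlas_p, n_top = 5)
  expect_equal(interp_p[[1]]$correlations, interp[[1]]$correlations,
               tolerance = 1e-12)
  expect_error(interpret_pcs(maps[1:10, ], atlas), "does not match")
})

test_that("subregion profiles average the right voxels with sign retained", {
  w <- rbind(taskA = c(3, 1, -1), taskB = c(-2, 0, 5))
  meta <- data.frame(subregion = c("hip", "hip", "cau"))
  expect_equal(subregion_task_profile(w, meta, "hip"),
               c(taskA = 2, taskB = -1))
  expect_equal(subregion_task_profile(w, meta, "cau"),
               c(taskA = -1, taskB = 5))
  expect_error(subregion_task_profile(w, meta, "amy"), "empty subregion")
  expect_equal(unname(subregion_task_profile(w * 0, meta, "hip")), c(0, 0))
  # planted preference: the preferring task has the largest positive mean
  set.seed(16)
  w2 <- matrix(rnorm(5 * 40), 5, 40,
               dimnames = list(paste0("t", 1:5), NULL))
  w2[3, 1:10] <- w2[3, 1:10] + 5
  meta2 <- data.frame(subregion = rep(c("a", "b"), c(10, 30)))
  prof <- subregion_task_profile(w2, meta2, "a")
  expect_identical(names(which.max(prof)), "t3")
})
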