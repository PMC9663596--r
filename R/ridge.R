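# L2-regularized multi-output regression solved jointly for all output
# columns. W = argmin ||Y - XW||^2 + alpha ||W||^2 has the closed form
# (X'X + alpha I)^-1 X'Y; we eigendecompose whichever Gram matrix is smaller
# (X'X when features <= samples, XX' otherwise), which makes sweeping a grid
# of alphas cheap after a single decomposition.

#' Default regularization grid
#'
#' Eighteen log-spaced values, the powers of two from 1 to 2^17.
#'
#' @return Numeric vector of length 18.
#' @export
alpha_grid <- function() 2^(0:17)

# Decompose X once; returns closures for weights and predictions per alpha.
ridge_context <- function(x, y) {
  stop_if_not_finite(x, "design matrix")
  stop_if_not_finite(y, "response matrix")
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), nrow(x) >= 2)
  t_n <- nrow(x); p <- ncol(x)
  if (p <= t_n) {
    eg <- eigen(crossprod(x), symmetric = TRUE)
    v <- eg$vectors
    d2 <- pmax(eg$values, 0)
    a <- crossprod(x, y)              # P x N
    va <- crossprod(v, a)             # P x N
    list(
      mode = "primal",
      weights = function(alpha) v %*% (va / (d2 + alpha)),
      predict = function(alpha, x_new) (x_new %*% v) %*% (va / (d2 + alpha)))
  } else {
    eg <- eigen(tcrossprod(x), symmetric = TRUE)
    u <- eg$vectors
    d2 <- pmax(eg$values, 0)
    uy <- crossprod(u, y)             # T x N
    list(
      mode = "dual",
      weights = function(alpha) crossprod(x, u %*% (uy / (d2 + alpha))),
      predict = function(alpha, x_new) (tcrossprod(x_new, x) %*% u) %*%
        (uy / (d2 + alpha)))
  }
}

# One-shot ridge solution.
ridge_solve <- function(x, y, alpha) {
  ridge_context(x, y)$weights(alpha)
}

# Contiguous temporal fold assignment (block CV).
block_folds <- function(n, n_folds) {
  rep(seq_len(n_folds), times = diff(floor(seq(0, n, length.out = n_folds + 1))))
}

#' Select the ridge parameter by k-fold cross-validation
#'
#' Splits the training timepoints into `n_folds` contiguous temporal blocks
#' (limiting autocorrelation leakage between folds), fits the ridge model on
#' each training complement for every value of the grid, and returns the
#' grid value maximizing the mean held-out Pearson correlation (averaged
#' over output columns, then over folds). Ties resolve to the first maximum.
#'
#' @param x Time x features design matrix (already delay-expanded).
#' @param y Time x outputs response matrix.
#' @param grid Regularization grid (default [alpha_grid()], 18 values).
#' @param n_folds Number of folds (default 10).
#' @return The selected alpha (scalar). The full per-alpha score curve is
#'   attached as attribute `scores`.
#' @export
select_alpha_cv <- function(x, y, grid = alpha_grid(), n_folds = 10) {
  if (length(grid) < 1) stop("empty regularization grid")
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  n_folds <- min(n_folds, n)
  folds <- block_folds(n, n_folds)
  scores <- matrix(NA_real_, n_folds, length(grid))
  for (f in seq_len(n_folds)) {
    tr <- folds != f; te <- !tr
    ctx <- ridge_context(x[tr, , drop = FALSE], y[tr, , drop = FALSE])
    for (a in seq_along(grid)) {
      pred <- ctx$predict(grid[a], x[te, , drop = FALSE])
      scores[f, a] <- mean(colwise_cor(pred, y[te, , drop = FALSE]))
    }
  }
  mean_scores <- colMeans(scores)
  best <- which.max(mean_scores)    # first maximum on ties
  structure(grid[best], scores = mean_scores)
}

#' Select a shared ridge parameter by repeated 80/20 resampling
#'
#' For each subject, randomly splits the training samples into 80% fit and
#' 20% validation sets, fits the ridge model for every grid value, and
#' records the mean validation correlation; the procedure is repeated
#' `n_rep` times (default 50). Per-alpha scores are averaged across
#' repetitions and then across subjects, and the argmax is returned. The
#' shared value keeps the scale of weight estimates comparable across
#' subjects for group-level representational analyses.
#'
#' @param xy_list List with one element per subject, each a list with
#'   elements `x` (time x features) and `y` (time x outputs).
#' @param grid Regularization grid (default [alpha_grid()]).
#' @param n_rep Number of resampling repetitions (default 50).
#' @param holdout Validation fraction in (0, 1) (default 0.2).
#' @param seed Integer seed for the random splits.
#' @return The selected alpha, with per-alpha mean scores as attribute
#'   `scores`.
#' @export
select_alpha_resampling <- function(xy_list, grid = alpha_grid(),
                                    n_rep = 50, holdout = 0.2, seed = 1L) {
  if (length(grid) < 1) stop("empty regularization grid")
  if (holdout <= 0 || holdout >= 1) stop("holdout must be in (0, 1)")
  if (length(xy_list) < 1) stop("need at least one subject")
  with_seed(seed, {
    # the same split sequence is reused for every subject, so identical
    # subjects select exactly the alpha a single-subject run would
    n0 <- nrow(as.matrix(xy_list[[1]]$x))
    splits <- lapply(seq_len(n_rep), function(i)
      sample.int(n0, max(1L, round(holdout * n0))))
    subj_scores <- vapply(xy_list, function(sub) {
      x <- as.matrix(sub$x); y <- as.matrix(sub$y)
      n <- nrow(x)
      n_val <- max(1L, round(holdout * n))
      acc <- matrix(NA_real_, n_rep, length(grid))
      for (rix in seq_len(n_rep)) {
        val <- if (n == n0) splits[[rix]] else sample.int(n, n_val)
        ctx <- ridge_context(x[-val, , drop = FALSE], y[-val, , drop = FALSE])
        for (a in seq_along(grid)) {
          pred <- ctx$predict(grid[a], x[val, , drop = FALSE])
          acc[rix, a] <- mean(colwise_cor(pred, y[val, , drop = FALSE]))
        }
      }
      colMeans(acc)
    }, numeric(length(grid)))
    mean_scores <- rowMeans(matrix(subj_scores, nrow = length(grid)))
    best <- which.max(mean_scores)
    structure(grid[best], scores = mean_scores)
  })
}
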