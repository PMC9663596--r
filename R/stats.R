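#' One-sided p-value for a sample correlation under the Gaussian null
#'
#' Probability that the correlation between two independent Gaussian random
#' vectors of length `n` is at least `r`. Uses the exact null density of the
#' sample correlation coefficient under independence, computed through the
#' t-transform `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of
#' freedom. This is the reference null for encoding-model prediction
#' accuracies evaluated on `n` test samples.
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @param n Sample length (>= 3).
#' @return One-sided p-value(s), same length as `r`.
#' @export
correlation_pvalue <- function(r, n) {
  if (n < 3) stop("n must be at least 3")
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must be <= 1")
  r <- pmin(1, pmax(-1, r))
  p <- numeric(length(r))
  at_one <- r >= 1
  at_mone <- r <= -1
  mid <- !at_one & !at_mone
  tt <- r[mid] * sqrt((n - 2) / (1 - r[mid]^2))
  p[mid] <- stats::pt(tt, df = n - 2, lower.tail = FALSE)
  p[at_one] <- 0
  p[at_mone] <- 1
  p
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjustment of p-values with a significance mask at `q_threshold`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param q_threshold FDR level for the mask (default 0.05).
#' @return List with `q` (adjusted values) and `mask` (`q < q_threshold`).
#' @export
fdr_bh <- function(p, q_threshold = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, mask = q < q_threshold)
}

#' Exact one-sided sign test
#'
#' Upper-tail binomial probability of observing at least `n_wins` successes
#' out of `n_total` comparisons at success probability 1/2. Used to test
#' per-task one-vs-one decoding records (e.g. 102 comparisons per task).
#'
#' @param n_wins Number of wins (can be a vector).
#' @param n_total Number of comparisons.
#' @return One-sided p-value(s).
#' @export
sign_test_one_sided <- function(n_wins, n_total) {
  if (any(n_wins < 0) || any(n_wins > n_total)) stop("n_wins must be in [0, n_total]")
  stats::pbinom(n_wins - 1, size = n_total, prob = 0.5, lower.tail = FALSE)
}

#' Permutation null distribution and p-value
#'
#' Repeatedly applies `shuffler` (which must return an exchangeable
#' relabeling of the data) and recomputes `statistic_fn`, returning the
#' empirical null and the one-sided add-one p-value
#' `(1 + #\{null >= observed\}) / (1 + n_iter)`.
#'
#' @param observed Observed value of the statistic.
#' @param statistic_fn Function taking one shuffled dataset, returning a scalar.
#' @param shuffler Function of no arguments returning a shuffled dataset.
#' @param n_iter Number of permutations (default 5000, as used for decoding
#'   label-shuffling tests).
#' @param seed Integer seed.
#' @return List with `null` (numeric vector) and `p`.
#' @export
permutation_null <- function(observed, statistic_fn, shuffler,
                             n_iter = 5000, seed = 1L) {
  if (n_iter < 1) stop("n_iter must be at least 1")
  if (n_iter < 100) warning("fewer than 100 permutations gives a coarse p-value")
  null <- with_seed(seed, vapply(seq_len(n_iter),
                                 function(i) statistic_fn(shuffler()),
                                 numeric(1)))
  p <- (1 + sum(null >= observed)) / (1 + n_iter)
  list(null = null, p = p)
}
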