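#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators are pure in their seeds.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Column-wise Pearson correlation between two matrices with matching dims.
# Zero-variance columns (on either side) yield 0, the degenerate-voxel rule.
colwise_cor <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b), ncol(a) == ncol(b))
  n <- nrow(a)
  a <- sweep(a, 2L, colMeans(a))
  b <- sweep(b, 2L, colMeans(b))
  sa <- sqrt(colSums(a^2))
  sb <- sqrt(colSums(b^2))
  num <- colSums(a * b)
  den <- sa * sb
  r <- ifelse(den > 0, num / den, 0)
  pmin(1, pmax(-1, r))
}

# Pearson correlation of each row of `m` against each row of `ref`:
# returns nrow(m) x nrow(ref). Degenerate rows give 0.
rowwise_cor <- function(m, ref) {
  m <- as.matrix(m); ref <- as.matrix(ref)
  stopifnot(ncol(m) == ncol(ref))
  mc <- m - rowMeans(m)
  rc <- ref - rowMeans(ref)
  sm <- sqrt(rowSums(mc^2))
  sr <- sqrt(rowSums(rc^2))
  num <- tcrossprod(mc, rc)
  den <- outer(sm, sr)
  r <- ifelse(den > 0, num / den, 0)
  matrix(pmin(1, pmax(-1, r)), nrow(m), nrow(ref),
         dimnames = list(rownames(m), rownames(ref)))
}

stop_if_not_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
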