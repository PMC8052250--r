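# Internal helpers shared across modules.

# Euclidean norms of the rows of a matrix.
row_norms <- function(m) sqrt(rowSums(m^2))

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.  All stochastic operations in the
# package route through this so that a single integer seed fixes the result.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic fan-out of one master seed into per-component child seeds.
# Kept below 2^31 so the result is always a valid R integer seed.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483629)
}

# Pairwise Euclidean distances between rows of a (n x N) and rows of b (m x N).
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Arc length of a polyline given as a matrix of ordered points.
polyline_length <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 2L) return(0)
  sum(row_norms(diff(pts)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
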