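# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed below 2^31 from a base seed and an index.
subSeed <- function(seed, index) {
  as.integer((as.numeric(seed) + 10007 * as.numeric(index)) %% 2147483647)
}

#' Strict upper-triangle values of a dissimilarity matrix
#'
#' Values are taken column-major over entries with row < column (21 values
#' for 7 conditions), the vectorization used throughout the pipeline.
#'
#' @param x a \linkS4class{DissimilarityMatrix} or square matrix.
#' @return numeric vector of strict upper-triangle entries.
#' @export
upperTriangle <- function(x) {
  m <- if (is(x, "DissimilarityMatrix")) rdmValues(x) else as.matrix(x)
  m[upper.tri(m)]
}

#' Strict lower-triangle values of a dissimilarity matrix
#'
#' Column-major over entries with row > column; frozen as the
#' vectorization order for searchlight regression.
#'
#' @param x a \linkS4class{DissimilarityMatrix} or square matrix.
#' @return numeric vector of strict lower-triangle entries.
#' @export
lowerTriangle <- function(x) {
  m <- if (is(x, "DissimilarityMatrix")) rdmValues(x) else as.matrix(x)
  m[lower.tri(m)]
}

# Rebuild a symmetric zero-diagonal matrix from strict lower-triangle values.
symmetricFromLower <- function(v, n, labels = NULL) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

# Nearest valid correlation matrix: eigenvalue clipping at zero followed by
# unit-diagonal renormalization. Used when subject-level jitter pushes an
# implied correlation matrix off the PSD cone.
clipToCorrelation <- function(C) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  C2 <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(pmax(diag(C2), .Machine$double.eps))
  C2 <- C2 / tcrossprod(d)
  diag(C2) <- 1
  (C2 + t(C2)) / 2
}

# Factor a correlation matrix as C = L L^T via eigen decomposition with
# clipping; rows of L generate variables with correlation C.
correlationFactor <- function(C, tol = 1e-10) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    stop("implied correlation matrix is not positive semidefinite")
  vals <- pmax(e$values, 0)
  keep <- vals > tol * max(vals)
  e$vectors[, keep, drop = FALSE] %*% diag(sqrt(vals[keep]),
                                           sum(keep), sum(keep))
}

# k x n matrix whose rows are exactly zero-mean and orthonormal in the
# sample sense (n must be >= k + 1); basis for exact-correlation sampling.
orthonormalRows <- function(k, n) {
  stopifnot(n >= k + 1)
  Z <- matrix(stats::rnorm(n * (k + 1)), nrow = n)
  Z[, 1] <- 1
  Q <- qr.Q(qr(Z))
  t(Q[, 2:(k + 1), drop = FALSE])
}

# linear index <-> (i, j, k) helpers for 3-D grids
linearToVoxel <- function(idx, dims) {
  idx0 <- idx - 1L
  cbind(idx0 %% dims[1],
        (idx0 %/% dims[1]) %% dims[2],
        idx0 %/% (dims[1] * dims[2])) + 1L
}

voxelToLinear <- function(vox, dims) {
  vox <- matrix(vox, ncol = 3)
  (vox[, 3] - 1L) * dims[1] * dims[2] + (vox[, 2] - 1L) * dims[1] + vox[, 1]
}
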