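# Independent oracles used across test files. These re-derive expected
# values from first principles and must stay independent of the package
# implementation paths they check.

# Ward2 agglomeration via the Lance-Williams recurrence run directly on
# squared dissimilarities, reporting square-rooted merge heights.
lanceWilliamsWard2 <- function(d) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  sizes <- rep(1, n)
  active <- seq_len(n)
  id <- -seq_len(n)                      # hclust merge coding
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  for (m in seq_len(n - 1)) {
    best <- c(NA, NA); bestVal <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (ii >= jj) next
      i <- active[ii]; j <- active[jj]
      if (d2[i, j] < bestVal) { bestVal <- d2[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights[m] <- sqrt(bestVal)
    merges[m, ] <- sort(c(id[i], id[j]))
    ni <- sizes[i]; nj <- sizes[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- sizes[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
        (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    id[i] <- m
    active <- setdiff(active, j)
  }
  list(merge = merges, height = heights)
}

# Dense-grid argmax of the double-gamma expression (peak location oracle).
doubleGammaArgmax <- function() {
  tt <- seq(0, 32, by = 1e-4)
  h <- dgamma(tt, shape = 6, scale = 1) - dgamma(tt, shape = 16, scale = 1) / 6
  tt[which.max(h)]
}

# Textbook Pearson correlation (direct formula, no stats::cor).
pearsonDirect <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# A small symmetric zero-diagonal matrix as a labelled RDM.
toyRdm <- function(v, n, labels = paste0("e", seq_len(n)),
                   type = "general") {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  DissimilarityMatrix(m, labels = labels, type = type)
}

# RDM of pairwise Euclidean distances between planar points.
planarRdm <- function(pts, transform = identity) {
  d <- transform(as.matrix(dist(pts)))
  diag(d) <- 0
  DissimilarityMatrix(d, labels = paste0("p", seq_len(nrow(pts))),
                      type = "general")
}

# Joint all-trials GLM oracle: independently constructed boxcar+HRF
# design (microtime convolution via direct summation), OLS per voxel,
# returning the per-trial coefficients.
jointGlmOracle <- function(bold, events, TR, hrfDt = TR / 16) {
  nScans <- dim(bold)[4]
  tt <- seq(0, 32, by = hrfDt)
  h <- dgamma(tt, shape = 6, scale = 1) - dgamma(tt, shape = 16, scale = 1) / 6
  h <- h / max(h)
  nMicro <- ceiling(nScans * TR / hrfDt) + length(h)
  X <- sapply(seq_len(nrow(events)), function(i) {
    u <- numeric(nMicro)
    a <- floor(events$onset[i] / hrfDt) + 1
    b <- ceiling((events$onset[i] + events$duration[i]) / hrfDt)
    u[a:min(b, nMicro)] <- 1
    conv <- numeric(nMicro)
    for (k in seq_along(h))            # direct convolution sum
      conv[k:nMicro] <- conv[k:nMicro] + h[k] * u[1:(nMicro - k + 1)]
    idx <- floor(((seq_len(nScans) - 1) + 0.5) * TR / hrfDt) + 1
    conv[idx] * hrfDt
  })
  Y <- t(matrix(bold, prod(dim(bold)[1:3]), nScans))
  qr.coef(qr(X), Y)
}

# independent linear-index -> voxel-triple conversion
linearToVoxelTest <- function(idx, dims) {
  i0 <- idx - 1
  c(i0 %% dims[1] + 1, (i0 %/% dims[1]) %% dims[2] + 1,
    i0 %/% (dims[1] * dims[2]) + 1)
}
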