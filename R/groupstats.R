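#' @useDynLib emorsa, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Coerce a list of StatMaps / 3-D arrays into an n x V matrix + dims.
subjectMatrix <- function(maps) {
  arrs <- lapply(maps, function(m)
    if (is(m, "StatMap")) mapValues(m) else m)
  dims <- dim(arrs[[1]])
  for (a in arrs)
    if (!identical(dim(a), dims)) stop("subject maps must share one grid")
  X <- do.call(rbind, lapply(arrs, as.vector))
  list(X = X, dims = dims)
}

#' Group one-sample t map
#'
#' Per voxel \eqn{t = \bar{x} / (s / \sqrt{n})} across subjects with
#' \eqn{n - 1} degrees of freedom, for one-sided tests against zero.
#' Voxels with zero between-subject variance receive t = 0 by convention.
#'
#' @param maps list of subject \linkS4class{StatMap}s or 3-D arrays on a
#'   shared grid (at least 3 subjects).
#' @return a \linkS4class{StatMap} of kind \code{"t"}.
#' @export
groupTmap <- function(maps) {
  if (length(maps) < 3) stop("need at least 3 subjects")
  sm <- subjectMatrix(maps)
  n <- nrow(sm$X)
  m <- colMeans(sm$X)
  sd <- sqrt(colSums(sweep(sm$X, 2, m)^2) / (n - 1))
  t <- ifelse(sd > 0, m / (sd / sqrt(n)), 0)
  StatMap(array(t, sm$dims), kind = "t", df = n - 1)
}

#' Threshold-free cluster enhancement
#'
#' Enhances the positive part of a statistic map by integrating, over
#' thresholds h in steps of \code{dh}, the term
#' \eqn{e(h)^E \, h^H \, dh}, where \eqn{e(h)} is the size of the
#' suprathreshold connected component containing the voxel. Defaults are
#' the field-standard E = 0.5, H = 2 with 26-connectivity and
#' \code{dh = max/100}.
#'
#' @param stat a \linkS4class{StatMap} or 3-D array.
#' @param E extent exponent.
#' @param H height exponent.
#' @param dh integration step; default \code{max(stat)/100}.
#' @param connectivity 6, 18 or 26.
#' @return a \linkS4class{StatMap} of kind \code{"tfce"}.
#' @export
tfce <- function(stat, E = 0.5, H = 2, dh = NULL,
                 connectivity = c(26L, 18L, 6L)) {
  connectivity <- as.integer(connectivity)[1]
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("'connectivity' must be 6, 18 or 26")
  v <- if (is(stat, "StatMap")) mapValues(stat) else stat
  dims <- dim(v)
  stopifnot(length(dims) == 3)
  if (any(!is.finite(v))) stop("statistic map must be finite")
  mx <- max(v)
  if (is.null(dh)) dh <- if (mx > 0) mx / 100 else 1
  if (E <= 0 || H <= 0 || dh <= 0)
    stop("'E', 'H' and 'dh' must be positive")
  out <- .tfce_cpp(as.numeric(v), as.integer(dims), E, H, dh,
                   connectivity)
  StatMap(array(out, dims), kind = "tfce")
}

# Sign matrix for the permutation null: full enumeration when feasible,
# otherwise fair-coin draws.
signMatrix <- function(n, nPerm) {
  if (2^n <= nPerm) {
    g <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))
    dimnames(g) <- NULL
    storage.mode(g) <- "integer"
    g
  } else {
    matrix(sample(c(1L, -1L), nPerm * n, replace = TRUE), nPerm, n)
  }
}

#' One-sample sign-permutation test with TFCE and max-statistic FWE
#'
#' Tests, one-sided, whether subject maps are positive on average. The
#' observed statistic is the TFCE enhancement of the group t map. The null
#' is built by randomly flipping each subject's map sign (fair coin; all
#' \eqn{2^n} patterns enumerated when that is no more than \code{nPerm}),
#' recomputing t and TFCE, and recording the maximum over voxels — giving
#' family-wise error control at the map level. Corrected p values use the
#' add-one convention \eqn{p = (1 + \#\{max_{perm} \ge obs\}) / (nPerm + 1)}
#' and are converted to one-sided z scores capped at the permutation
#' resolution; the significance mask applies \code{zThreshold} (default
#' 1.65, i.e. corrected p < 0.05 one-tailed).
#'
#' @param maps list of subject \linkS4class{StatMap}s or 3-D arrays (at
#'   least 5 subjects).
#' @param nPerm number of permutations.
#' @param E,H,connectivity TFCE parameters (see \code{\link{tfce}});
#'   \code{nSteps} integration steps with dh = max/nSteps per map.
#' @param nSteps TFCE integration steps.
#' @param seed RNG seed for the sign flips.
#' @param mask optional 3-D logical array restricting inference.
#' @param zThreshold z cut for the significance mask.
#' @return a \linkS4class{PermutationResult}.
#' @export
signPermutationTest <- function(maps, nPerm = 10000L, E = 0.5, H = 2,
                                connectivity = 26L, nSteps = 100L,
                                seed = 1L, mask = NULL,
                                zThreshold = 1.65) {
  if (length(maps) < 5) stop("need at least 5 subjects")
  if (nPerm < 100) warning("fewer than 100 permutations: p values are coarse")
  sm <- subjectMatrix(maps)
  X <- sm$X
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), sm$dims))
    X[, !as.vector(mask)] <- 0
  }
  n <- nrow(X)
  signs <- withSeed(seed, signMatrix(n, nPerm))
  nPerm <- nrow(signs)
  res <- .sign_perm_cpp(X, signs, as.integer(sm$dims), E, H,
                        as.integer(nSteps), as.integer(connectivity))
  obs <- res$tfce
  p <- (1 + vapply(obs, function(o) sum(res$nullMax >= o),
                   numeric(1))) / (nPerm + 1)
  pCap <- 1 / (nPerm + 1)
  z <- stats::qnorm(1 - pmax(p, pCap))
  z <- pmin(z, stats::qnorm(1 - pCap))
  inMask <- if (is.null(mask)) rep(TRUE, ncol(X)) else as.vector(mask)
  p[!inMask] <- 1
  z[!inMask] <- 0
  sig <- array(z >= zThreshold & inMask, sm$dims)
  new("PermutationResult",
      tMap = StatMap(array(res$t, sm$dims), kind = "t", df = n - 1),
      observedTfce = StatMap(array(obs, sm$dims), kind = "tfce"),
      nullMax = as.numeric(res$nullMax),
      pCorrected = StatMap(array(p, sm$dims), kind = "p_corrected"),
      zMap = StatMap(array(z, sm$dims), kind = "z"),
      significant = sig, nPerm = as.integer(nPerm),
      seed = as.integer(seed), zThreshold = zThreshold)
}

#' Voxelwise repeated-measures F test over emotion conditions
#'
#' Per voxel, a one-way repeated-measures ANOVA with condition as the
#' fixed factor and subject as the blocking factor:
#' \eqn{F = MS_{cond} / MS_{error}} on \eqn{(c - 1, (c - 1)(n - 1))}
#' degrees of freedom (c = 7 emotions gives df = (6, 6(n - 1))). A
#' simplified whole-map main-effect test used to define activation masks
#' for conjunction with the permutation machinery in place of parametric
#' random-field cluster correction.
#'
#' @param conditionMeans list over subjects of (condition x voxel)
#'   matrices, or a 3-D array (subject, condition, voxel).
#' @param dims optional grid shape for the output map.
#' @return a \linkS4class{StatMap} of kind \code{"F"}; constant voxels
#'   receive F = 0.
#' @export
voxelwiseEmotionF <- function(conditionMeans, dims = NULL) {
  if (is.list(conditionMeans)) {
    nc <- nrow(conditionMeans[[1]])
    arr <- array(0, c(length(conditionMeans), nc,
                      ncol(conditionMeans[[1]])))
    for (i in seq_along(conditionMeans)) arr[i, , ] <- conditionMeans[[i]]
  } else arr <- conditionMeans
  n <- dim(arr)[1]; cc <- dim(arr)[2]; V <- dim(arr)[3]
  if (n < 3) stop("need at least 3 subjects")
  Fv <- vapply(seq_len(V), function(v) {
    x <- arr[, , v]
    gm <- mean(x)
    condM <- colMeans(x)
    subjM <- rowMeans(x)
    ssCond <- n * sum((condM - gm)^2)
    resid <- x - outer(subjM, condM, `+`) + gm
    ssErr <- sum(resid^2)
    if (ssErr <= 0) return(0)
    (ssCond / (cc - 1)) / (ssErr / ((cc - 1) * (n - 1)))
  }, numeric(1))
  if (is.null(dims)) dims <- c(V, 1L, 1L)
  StatMap(array(Fv, dims), kind = "F", df = c(cc - 1, (cc - 1) * (n - 1)))
}

#' Minimum-statistic conjunction of two maps
#'
#' Elementwise minimum of two statistic maps of the same kind, plus the
#' conjunction mask: voxels significant in \emph{both} maps under the
#' supplied per-map corrected thresholds (the conjunction-null criterion).
#'
#' @param mapA,mapB \linkS4class{StatMap}s of the same kind on one grid.
#' @param threshold significance threshold applied to each map; a single
#'   value or a vector of two (per map).
#' @return list with \code{min} (a \linkS4class{StatMap}) and \code{mask}
#'   (3-D logical array).
#' @export
conjunctionMin <- function(mapA, mapB, threshold) {
  if (mapKind(mapA) != mapKind(mapB))
    stop("statistic kinds must match")
  a <- mapValues(mapA); b <- mapValues(mapB)
  if (!identical(dim(a), dim(b))) stop("maps must share one grid")
  thr <- rep(threshold, length.out = 2)
  list(min = StatMap(pmin(a, b), kind = mapKind(mapA)),
       mask = array(a >= thr[1] & b >= thr[2], dim(a)))
}
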