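#' Build searchlight spheres over a mask
#'
#' One searchlight per in-mask voxel, with membership decided by Euclidean
#' distance in world (scanner mm) coordinates under the affine — so
#' anisotropic voxels produce correctly shaped spheres. Centers retaining
#' fewer than \code{minVoxels} in-mask members are dropped and reported.
#'
#' @param mask 3-D logical/numeric array.
#' @param affine 4 x 4 voxel-to-world matrix (translation irrelevant).
#' @param radiusMm sphere radius in mm.
#' @param minVoxels minimum members per searchlight.
#' @return list with \code{searchlights} (each a list with \code{center}
#'   voxel triple, \code{centerIndex} linear index, \code{members} linear
#'   indices), \code{dropped} (linear indices of dropped centers),
#'   \code{radiusMm}.
#' @export
buildSearchlights <- function(mask, affine, radiusMm = 4, minVoxels = 3L) {
  if (radiusMm <= 0) stop("'radiusMm' must be positive")
  dims <- dim(mask)
  mask <- array(as.logical(mask), dims)
  if (!any(mask)) stop("mask is empty")
  A <- affine[1:3, 1:3]
  if (abs(det(A)) < .Machine$double.eps) stop("affine is not invertible")
  # candidate integer offsets within the world-space radius
  maxOff <- rep(ceiling(radiusMm / min(svd(A)$d)) + 1L, 3)  # safe bound
  og <- as.matrix(expand.grid(-maxOff[1]:maxOff[1],
                              -maxOff[2]:maxOff[2],
                              -maxOff[3]:maxOff[3]))
  wdist <- sqrt(colSums((A %*% t(og))^2))
  offsets <- og[wdist <= radiusMm + 1e-9, , drop = FALSE]
  centers <- which(mask)
  centerVox <- linearToVoxel(centers, dims)
  sls <- vector("list", length(centers))
  dropped <- integer(0)
  keep <- logical(length(centers))
  for (i in seq_along(centers)) {
    vox <- sweep(offsets, 2, centerVox[i, ], "+")
    ok <- vox[, 1] >= 1 & vox[, 1] <= dims[1] &
          vox[, 2] >= 1 & vox[, 2] <= dims[2] &
          vox[, 3] >= 1 & vox[, 3] <= dims[3]
    mem <- voxelToLinear(vox[ok, , drop = FALSE], dims)
    mem <- mem[mask[mem]]
    if (length(mem) < minVoxels) {
      dropped <- c(dropped, centers[i])
      next
    }
    keep[i] <- TRUE
    sls[[i]] <- list(center = centerVox[i, ], centerIndex = centers[i],
                     members = sort(mem))
  }
  list(searchlights = sls[keep], dropped = dropped, radiusMm = radiusMm,
       dims = dims)
}

#' Neural RDM within one searchlight
#'
#' Averages trial betas within each emotion to one pattern vector over the
#' sphere's voxels and returns the Pearson correlation distance between
#' the per-emotion patterns.
#'
#' @param betas a \linkS4class{BetaVolumeSet} (trial metadata must carry
#'   an \code{emotion} column).
#' @param sl one searchlight (element of
#'   \code{buildSearchlights()$searchlights}).
#' @param labels emotion labels defining RDM order; default: sorted unique
#'   labels present.
#' @return a \linkS4class{DissimilarityMatrix}, or \code{NULL} when a
#'   pattern is constant (degenerate center).
#' @export
neuralRdm <- function(betas, sl, labels = NULL) {
  flat <- matrix(betaArray(betas), ncol = dim(betaArray(betas))[4])
  emo <- trialInfo(betas)$emotion
  if (is.null(labels)) labels <- sort(unique(emo))
  if (length(sl$members) < 3) return(NULL)
  patt <- vapply(labels, function(e)
    rowMeans(flat[sl$members, emo == e, drop = FALSE]),
    numeric(length(sl$members)))
  if (any(apply(patt, 2, stats::sd) == 0)) return(NULL)
  d <- 1 - stats::cor(patt)
  d <- pmin(pmax((d + t(d)) / 2, 0), 2)
  d[abs(d) < 1e-12] <- 0               # snap numerically-zero distances
  diag(d) <- 0
  DissimilarityMatrix(d, labels = labels, type = "correlation")
}

#' Regress a neural RDM on model RDMs
#'
#' Vectorizes the strict lower triangles (column-major over row > column)
#' of the neural and model dissimilarity matrices, z-scores response and
#' predictors, fits ordinary least squares with an intercept, and
#' Fisher-transforms (atanh) the standardized coefficients after clipping
#' them to \eqn{\pm(1 - 10^{-7})}. With a single model the standardized
#' coefficient equals the Pearson correlation of the two triangles, so the
#' output is exactly \code{atanh(r)}.
#'
#' @param neural neural \linkS4class{DissimilarityMatrix}.
#' @param models list of model \linkS4class{DissimilarityMatrix} objects
#'   (named; names label the output).
#' @param standardize z-score response and predictors (default TRUE).
#' @param intercept include an intercept (default TRUE).
#' @param eps clipping margin before atanh.
#' @return named numeric vector of Fisher-transformed coefficients, one
#'   per model.
#' @export
rsaRegress <- function(neural, models, standardize = TRUE,
                       intercept = TRUE, eps = 1e-7) {
  if (!length(models)) stop("need at least one model RDM")
  if (is(models, "DissimilarityMatrix")) models <- list(models)
  y <- lowerTriangle(neural)
  Xm <- vapply(models, lowerTriangle, numeric(length(y)))
  if (is.null(colnames(Xm)))
    colnames(Xm) <- paste0("model", seq_len(ncol(Xm)))
  if (stats::sd(y) == 0) stop("zero-variance neural triangle")
  if (any(apply(Xm, 2, stats::sd) == 0))
    stop("zero-variance model triangle")
  if (standardize) {
    y <- as.vector(scale(y))
    Xm <- apply(Xm, 2, function(c) as.vector(scale(c)))
  }
  D <- if (intercept) cbind(`(Intercept)` = 1, Xm) else Xm
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) stop("collinear model RDMs")
  b <- qr.coef(qrD, y)
  b <- b[colnames(Xm)]
  b <- pmin(pmax(b, -1 + eps), 1 - eps)
  atanh(b)
}

#' Searchlight representational similarity analysis
#'
#' Runs \code{\link{neuralRdm}} + \code{\link{rsaRegress}} at every valid
#' searchlight center within the mask and writes each model's
#' Fisher-transformed coefficient back to the center voxel.
#'
#' @param betas a \linkS4class{BetaVolumeSet}.
#' @param models named list of model \linkS4class{DissimilarityMatrix}
#'   objects; labels must match the trial emotion labels.
#' @param mask analysis mask; defaults to the beta set's mask.
#' @param radiusMm searchlight radius in mm.
#' @param minVoxels minimum sphere size.
#' @param standardize,intercept passed to \code{\link{rsaRegress}}.
#' @return an \linkS4class{RsaResultMap}.
#' @export
runSearchlight <- function(betas, models, mask = volumeMask(betas),
                           radiusMm = 4, minVoxels = 3L,
                           standardize = TRUE, intercept = TRUE) {
  if (is(models, "DissimilarityMatrix")) models <- list(conceptual = models)
  if (is.null(names(models)))
    names(models) <- paste0("model", seq_along(models))
  labels <- rdmLabels(models[[1]])
  emo <- trialInfo(betas)$emotion
  if (!all(labels %in% emo))
    stop("model labels must appear among trial emotions")
  dims <- dim(betaArray(betas))[1:3]
  flat <- matrix(betaArray(betas), ncol = dim(betaArray(betas))[4])
  # per-emotion mean volumes, computed once
  means <- vapply(labels, function(e)
    rowMeans(flat[, emo == e, drop = FALSE]), numeric(nrow(flat)))
  Xm <- vapply(models, lowerTriangle,
               numeric(length(labels) * (length(labels) - 1) / 2))
  sl <- buildSearchlights(mask, volumeAffine(betas), radiusMm, minVoxels)
  coef <- array(NA_real_, c(dims, length(models)),
                dimnames = c(rep(list(NULL), 3), list(names(models))))
  centerMask <- array(FALSE, dims)
  dropped <- sl$dropped
  nM <- length(models)
  for (s in sl$searchlights) {
    patt <- means[s$members, , drop = FALSE]
    sds <- apply(patt, 2, stats::sd)
    if (any(sds == 0)) { dropped <- c(dropped, s$centerIndex); next }
    d <- 1 - stats::cor(patt)
    y <- d[lower.tri(d)]
    if (stats::sd(y) == 0) { dropped <- c(dropped, s$centerIndex); next }
    b <- tryCatch(
      rsaRegressVec(y, Xm, standardize, intercept),
      error = function(e) NULL)
    if (is.null(b)) { dropped <- c(dropped, s$centerIndex); next }
    vox <- s$center
    coef[vox[1], vox[2], vox[3], ] <- b
    centerMask[vox[1], vox[2], vox[3]] <- TRUE
  }
  new("RsaResultMap", coefficients = coef, centerMask = centerMask,
      affine = volumeAffine(betas), dropped = as.integer(sort(dropped)))
}

# fast path of rsaRegress on raw triangle vectors
rsaRegressVec <- function(y, Xm, standardize = TRUE, intercept = TRUE,
                          eps = 1e-7) {
  if (any(apply(Xm, 2, stats::sd) == 0))
    stop("zero-variance model triangle")
  if (standardize) {
    y <- as.vector(scale(y))
    Xm <- apply(Xm, 2, function(c) as.vector(scale(c)))
  }
  if (ncol(Xm) == 1 && standardize) {
    b <- sum(y * Xm[, 1]) / (length(y) - 1)   # correlation
  } else {
    D <- if (intercept) cbind(1, Xm) else Xm
    qrD <- qr(D)
    if (qrD$rank < ncol(D)) stop("collinear model RDMs")
    b <- qr.coef(qrD, y)
    b <- b[(ncol(D) - ncol(Xm) + 1):ncol(D)]
  }
  atanh(pmin(pmax(b, -1 + eps), 1 - eps))
}
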