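#' Canonical double-gamma hemodynamic response function
#'
#' The canonical HRF as the difference of two gamma densities: response
#' peak delay 6 s, undershoot delay 16 s, both with dispersion 1 s,
#' undershoot scaled by 1/6, supported on [0, 32] s. The kernel is
#' peak-normalized to 1 and starts at exactly 0.
#'
#' @param dt sampling resolution in seconds, in (0, 1].
#' @param length kernel length in seconds.
#' @return list with \code{samples}, \code{dt}, \code{length}, \code{time}.
#' @export
canonicalHrf <- function(dt = 0.1, length = 32) {
  if (dt <= 0 || dt > 1) stop("'dt' must lie in (0, 1]")
  tt <- seq(0, length, by = dt)
  h <- stats::dgamma(tt, shape = 6, scale = 1) -
    stats::dgamma(tt, shape = 16, scale = 1) / 6
  h <- h / max(h)
  list(samples = h, dt = dt, length = length, time = tt)
}

#' Discrete-cosine high-pass filter basis
#'
#' Returns the DCT regressors spanning fluctuations slower than the
#' cutoff: \code{floor(2 * T * TR / cutoff)} cosine columns, mutually
#' orthonormal over the scan, as used for a 128-s high-pass filter.
#'
#' @param nScans number of time points T.
#' @param TR repetition time in seconds.
#' @param cutoff filter cutoff period in seconds.
#' @return matrix with \code{nScans} rows; zero columns when the scan is
#'   shorter than half the cutoff period.
#' @export
dctHighpass <- function(nScans, TR, cutoff = 128) {
  if (nScans < 2) stop("'nScans' must be at least 2")
  if (cutoff <= 2 * TR)
    stop("'cutoff' must exceed twice the TR")
  K <- floor(2 * nScans * TR / cutoff)
  tt <- seq_len(nScans) - 1
  cols <- vapply(seq_len(K), function(k)
    sqrt(2 / nScans) * cos(pi * (2 * tt + 1) * k / (2 * nScans)),
    numeric(nScans))
  if (K == 0) cols <- matrix(0, nScans, 0)
  colnames(cols) <- if (K > 0) paste0("dct", seq_len(K))
  cols
}

# Boxcar-convolved trial regressors sampled at the TR.
# Convolution happens on a microtime grid (dt = hrf$dt), with the volume
# sampled at a slice-time reference of 0.5 TR.
trialRegressors <- function(events, hrf, TR, nScans) {
  dt <- hrf$dt
  nMicro <- ceiling(nScans * TR / dt) + length(hrf$samples)
  sampleIdx <- pmin(nMicro,
                    floor(((seq_len(nScans) - 1) + 0.5) * TR / dt) + 1L)
  X <- vapply(seq_len(nrow(events)), function(i) {
    u <- numeric(nMicro)
    a <- floor(events$onset[i] / dt) + 1L
    b <- max(a, ceiling((events$onset[i] + events$duration[i]) / dt))
    u[a:min(b, nMicro)] <- 1
    conv <- stats::convolve(u, rev(hrf$samples), type = "open")[seq_len(nMicro)]
    conv[sampleIdx] * dt
  }, numeric(nScans))
  colnames(X) <- paste0("trial", seq_len(nrow(events)))
  X
}

# Assemble the LSS design for one target trial.
lssDesign <- function(X, target, nuisance, dct, intercept = TRUE) {
  others <- if (ncol(X) > 1)
    rowSums(X[, -target, drop = FALSE])
  else NULL
  cols <- cbind(target_trial = X[, target],
                other_trials = others)
  if (!is.null(nuisance) && ncol(nuisance) > 0)
    cols <- cbind(cols, as.matrix(nuisance))
  if (ncol(dct) > 0) cols <- cbind(cols, dct)
  if (intercept) cols <- cbind(cols, intercept = 1)
  cols
}

#' Least Squares Separate single-trial beta estimation
#'
#' Fits, for every trial, an ordinary-least-squares GLM in which the
#' target trial has its own boxcar-convolved regressor while all other
#' trials are collapsed into a single regressor, alongside any nuisance
#' regressors, the discrete-cosine high-pass basis (128-s cutoff by
#' default) and an intercept. The target coefficient per masked voxel is
#' returned as one beta volume per trial. No prewhitening is applied.
#'
#' @param bold 4-D array (x, y, z, time).
#' @param events data.frame with \code{onset}, \code{duration} (seconds);
#'   extra columns (e.g. \code{emotion}, \code{catch}) are carried into
#'   the output metadata.
#' @param mask 3-D logical array; voxels outside are returned as 0.
#' @param nuisance optional numeric matrix/data.frame of nuisance
#'   regressors (time points x regressors).
#' @param TR repetition time in seconds.
#' @param hrf HRF kernel from \code{\link{canonicalHrf}}; default uses a
#'   microtime resolution of TR/16.
#' @param highpassCutoff DCT filter cutoff in seconds; \code{NULL}
#'   disables filtering.
#' @param boxcarDuration optional single duration (seconds) overriding the
#'   per-event durations, e.g. to model a full 12-s trial epoch.
#' @param intercept include an intercept column (default TRUE). Disabling
#'   it (with filtering off) makes the target regressor exactly orthogonal
#'   to the rest of the design when trials are separated by more than the
#'   HRF length, in which case LSS coincides with the joint all-trials GLM.
#' @param affine voxel-to-world matrix stored in the result.
#' @return a \linkS4class{BetaVolumeSet} with one volume per event row.
#' @export
fitLss <- function(bold, events, mask = NULL, nuisance = NULL, TR,
                   hrf = canonicalHrf(TR / 16), highpassCutoff = 128,
                   boxcarDuration = NULL, intercept = TRUE,
                   affine = diag(4)) {
  dims <- dim(bold)
  stopifnot(length(dims) == 4)
  nScans <- dims[4]
  if (is.null(mask)) mask <- array(TRUE, dims[1:3])
  mask <- array(as.logical(mask), dims[1:3])
  if (!any(mask)) stop("mask is empty")
  ev <- events
  if (!is.null(boxcarDuration)) ev$duration <- boxcarDuration
  if (max(ev$onset + ev$duration) > nScans * TR)
    stop("events extend beyond the scan")
  X <- trialRegressors(ev, hrf, TR, nScans)
  if (any(colSums(abs(X)) == 0)) stop("all-zero target trial regressor")
  dct <- if (is.null(highpassCutoff)) matrix(0, nScans, 0)
         else dctHighpass(nScans, TR, highpassCutoff)
  Y <- t(matrix(bold, prod(dims[1:3]), nScans))[, as.vector(mask),
                                                drop = FALSE]
  nTrials <- nrow(ev)
  out <- array(0, c(dims[1:3], nTrials))
  flat <- matrix(out, prod(dims[1:3]), nTrials)
  for (tr in seq_len(nTrials)) {
    D <- lssDesign(X, tr, nuisance, dct, intercept)
    qrD <- qr(D)
    if (qrD$rank < ncol(D)) {
      drop <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
      stop("rank-deficient design for trial ", tr,
           "; collinear column(s): ", paste(drop, collapse = ", "))
    }
    beta <- qr.coef(qrD, Y)
    flat[as.vector(mask), tr] <- beta[1, ]
  }
  keep <- intersect(c("emotion", "trial_type", "modality", "session",
                      "catch", "block", "trial"), names(events))
  meta <- cbind(data.frame(trial = seq_len(nTrials)),
                events[, setdiff(keep, "trial"), drop = FALSE])
  BetaVolumeSet(array(flat, c(dims[1:3], nTrials)), mask = mask,
                affine = affine, trials = meta)
}
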