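#' A plausible 7-emotion conceptual dissimilarity prototype
#'
#' Synthetic group-level RDM built from a circumplex-style configuration:
#' each emotion is a unit vector at a fixed angle, so pairwise correlations
#' are cosines of angular differences and \eqn{1 - \cos} distances form a
#' valid (positive semidefinite) correlation-distance structure. Nearby
#' angles encode conceptually close emotions (fear/anger, sad/disgust),
#' happy sits opposite the negative cluster and neutral off to the side.
#'
#' @param shrink multiply off-diagonal dissimilarities by this factor in
#'   (0, 1] to tighten or relax the geometry.
#' @return a \linkS4class{DissimilarityMatrix} (correlation type).
#' @export
exampleEmotionRdm <- function(shrink = 0.8) {
  stopifnot(shrink > 0, shrink <= 1)
  angles <- c(angry = 115, disgusted = 160, fearful = 95, happy = 345,
              sad = 190, surprised = 40, neutral = 265) * pi / 180
  C <- cos(outer(angles, angles, "-"))
  d <- shrink * (1 - C)
  diag(d) <- 0
  DissimilarityMatrix(d, labels = names(angles), type = "correlation")
}

#' Planted synthetic world
#'
#' Defines the generative conditions for synthetic behavioral and imaging
#' data: a group-prototype conceptual RDM, the spread of subject-specific
#' deviations from it, observation noise, and the imaging grid with a
#' designated signal region whose emotion patterns will carry each
#' subject's RDM.
#'
#' @param targetRdm group prototype \linkS4class{DissimilarityMatrix};
#'   implied correlation matrix \code{1 - targetRdm} must be positive
#'   semidefinite.
#' @param idiosyncrasySd SD of the symmetric jitter added to the prototype
#'   to form each subject's RDM (between-subject variability).
#' @param noiseSd observation noise SD (rating noise / trial-level beta
#'   noise, in units of the unit-variance planted patterns).
#' @param gridShape 3 positive integers, imaging grid.
#' @param signalRegion linear voxel indices of the signal region.
#' @param voxelSizeMm voxel size in mm (3 reals).
#' @param seed integer seed fixing all randomness derived from the world.
#' @return a list of class \code{"PlantedWorld"}.
#' @export
plantedWorld <- function(targetRdm = exampleEmotionRdm(),
                         idiosyncrasySd = 0.1, noiseSd = 1,
                         gridShape = c(10L, 10L, 10L),
                         signalRegion = NULL,
                         voxelSizeMm = c(3, 3, 3), seed = 1L) {
  stopifnot(is(targetRdm, "DissimilarityMatrix"),
            idiosyncrasySd >= 0, noiseSd >= 0,
            length(gridShape) == 3, all(gridShape >= 1),
            length(voxelSizeMm) == 3, all(voxelSizeMm > 0))
  d <- rdmValues(targetRdm)
  if (min(d) < 0 || max(d) > 2)
    stop("target RDM entries must lie in [0, 2]")
  ev <- eigen(1 - d, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("implied correlation matrix (1 - target RDM) is not positive ",
         "semidefinite; reject this world")
  nVox <- prod(gridShape)
  if (is.null(signalRegion)) {
    ctr <- pmax(1L, round(gridShape / 2) - 1L)
    span <- lapply(1:3, function(a)
      ctr[a]:min(gridShape[a], ctr[a] + 2L))
    vox <- as.matrix(expand.grid(span[[1]], span[[2]], span[[3]]))
    signalRegion <- voxelToLinear(vox, gridShape)
  }
  signalRegion <- sort(unique(as.integer(signalRegion)))
  if (any(signalRegion < 1 | signalRegion > nVox))
    stop("signalRegion must index voxels inside the grid")
  world <- list(targetRdm = targetRdm,
                idiosyncrasySd = idiosyncrasySd, noiseSd = noiseSd,
                gridShape = as.integer(gridShape),
                signalRegion = signalRegion,
                voxelSizeMm = as.numeric(voxelSizeMm),
                seed = as.integer(seed))
  class(world) <- "PlantedWorld"
  world
}

#' Subject-specific conceptual RDM under a planted world
#'
#' Jitters the group prototype with symmetric Gaussian noise of SD
#' \code{idiosyncrasySd}, clips entries to [0, 2], and projects the
#' implied correlation matrix back onto the valid (PSD, unit-diagonal)
#' cone by eigenvalue clipping, so every subject RDM remains a legitimate
#' correlation distance.
#'
#' @param world a \code{\link{plantedWorld}}.
#' @param subjectId positive integer; together with the world seed this
#'   fixes the subject's RDM.
#' @return a \linkS4class{DissimilarityMatrix}.
#' @export
subjectRdm <- function(world, subjectId) {
  stopifnot(inherits(world, "PlantedWorld"))
  d <- rdmValues(world$targetRdm)
  n <- nrow(d)
  if (world$idiosyncrasySd == 0) return(world$targetRdm)
  withSeed(subSeed(world$seed, subjectId), {
    jit <- matrix(stats::rnorm(n * n, sd = world$idiosyncrasySd), n, n)
    jit[lower.tri(jit, diag = TRUE)] <- 0
    jit <- jit + t(jit)
    ds <- pmin(pmax(d + jit, 0), 2)
    diag(ds) <- 0
    C <- clipToCorrelation(1 - ds)
    ds <- 1 - C
    ds <- pmin(pmax(ds, 0), 2)
    diag(ds) <- 0
    DissimilarityMatrix(ds, labels = rdmLabels(world$targetRdm),
                        type = "correlation")
  })
}

#' Generate one subject's emotion-word rating matrix
#'
#' Draws emotion prototype vectors over the feature words whose pairwise
#' empirical correlations equal exactly \code{1 - } the subject's RDM
#' (centered, whitened Gaussian basis multiplied by a factor of the implied
#' correlation matrix), then affine-maps each row to mean 4, SD 1.2 on the
#' 7-point scale, adds rating noise, rounds half-up and clips to [1, 7].
#' With \code{discretize = FALSE} the continuous pre-rounding values are
#' returned, which reproduce the subject RDM exactly at zero noise.
#'
#' @param world a \code{\link{plantedWorld}}.
#' @param subjectId positive integer subject index.
#' @param spec a \code{\link{designSpec}} (provides word count, labels,
#'   scale bounds).
#' @param discretize round and clip to the integer rating scale.
#' @return numeric matrix, emotions x words, with dimnames.
#' @export
genSubjectRatings <- function(world, subjectId, spec = designSpec(),
                              discretize = TRUE) {
  stopifnot(inherits(world, "PlantedWorld"), inherits(spec, "DesignSpec"))
  rdmS <- subjectRdm(world, subjectId)
  d <- rdmValues(rdmS)
  n <- nrow(d)
  if (spec$nWords < n + 1)
    stop("need at least nEmotions + 1 words for the exact construction")
  L <- correlationFactor(clipToCorrelation(1 - d))
  withSeed(subSeed(world$seed, 7919 * subjectId + 1), {
    Z <- orthonormalRows(ncol(L), spec$nWords)
    P <- L %*% Z                       # rows: empirical correlation 1 - d
    P <- P / pmax(apply(P, 1, stats::sd), .Machine$double.eps)
    R <- 4 + 1.2 * P
    if (world$noiseSd > 0)
      R <- R + matrix(stats::rnorm(length(R), sd = world$noiseSd), n)
    R
  }) -> R
  dimnames(R) <- list(rdmLabels(rdmS),
                      paste0("word", sprintf("%02d", seq_len(spec$nWords))))
  if (discretize) {
    R <- floor(R + 0.5)               # round half-up
    R[] <- pmin(pmax(R, spec$ratingScale[1]), spec$ratingScale[2])
  }
  R
}

#' Generate confusion counts from a conceptual RDM
#'
#' Response probabilities for true category i follow a softmax in negative
#' dissimilarity, \eqn{p(j | i) \propto \exp(-d_{ij} / \tau)} with
#' \eqn{d_{ii} = 0}, so the correct response dominates and confusions decay
#' with conceptual distance. Row counts are multinomial draws with
#' \code{nTrialsPerEmotion} trials.
#'
#' @param conceptualRdm a \linkS4class{DissimilarityMatrix}.
#' @param temperature softmax temperature, > 0; small values approach
#'   perfect categorization.
#' @param nTrialsPerEmotion trials presented per true category.
#' @param seed RNG seed.
#' @return a \linkS4class{ConfusionMatrix}.
#' @export
genConfusions <- function(conceptualRdm, temperature = 0.3,
                          nTrialsPerEmotion = 100L, seed = 1L) {
  stopifnot(is(conceptualRdm, "DissimilarityMatrix"))
  if (temperature <= 0) stop("'temperature' must be > 0")
  d <- rdmValues(conceptualRdm)
  n <- nrow(d)
  withSeed(seed, {
    counts <- t(vapply(seq_len(n), function(i) {
      p <- exp(-d[i, ] / temperature)
      as.integer(stats::rmultinom(1, nTrialsPerEmotion, p))
    }, integer(n)))
    counts
  }) -> counts
  ConfusionMatrix(counts, labels = rdmLabels(conceptualRdm))
}

#' Generate per-trial beta volumes with planted representational geometry
#'
#' Within the world's signal region, per-emotion mean patterns are
#' constructed so their pairwise empirical Pearson correlations equal
#' exactly \code{1 - subjectRdm} (regions of at least nEmotions + 1 voxels;
#' smaller regions fall back to an in-expectation construction). Each trial
#' volume is its emotion's pattern plus iid Gaussian noise of SD
#' \code{world$noiseSd} everywhere; voxels outside the region carry pure
#' noise. Patterns are standardized to zero mean, unit SD across region
#' voxels, so \code{noiseSd} is in pattern-SD units.
#'
#' @param world a \code{\link{plantedWorld}}.
#' @param subjectRdm the subject's conceptual RDM to plant.
#' @param trialsPerEmotion number of trials per emotion category.
#' @param seed RNG seed; defaults to the world seed.
#' @return a \linkS4class{BetaVolumeSet}; trial metadata holds the emotion
#'   labels.
#' @export
genBetaVolumes <- function(world, subjectRdm, trialsPerEmotion = 4L,
                           seed = world$seed) {
  stopifnot(inherits(world, "PlantedWorld"),
            is(subjectRdm, "DissimilarityMatrix"), trialsPerEmotion >= 1)
  region <- world$signalRegion
  if (length(region) < 3)
    stop("signal region smaller than 3 voxels: pattern correlations ",
         "would be undefined downstream")
  d <- rdmValues(subjectRdm)
  n <- nrow(d)
  labels <- rdmLabels(subjectRdm)
  nVox <- prod(world$gridShape)
  nTrials <- n * trialsPerEmotion
  L <- correlationFactor(clipToCorrelation(1 - d))
  withSeed(seed, {
    patterns <- if (length(region) >= n + 1) {
      L %*% orthonormalRows(ncol(L), length(region))
    } else {
      L %*% matrix(stats::rnorm(ncol(L) * length(region)), ncol(L))
    }
    patterns <- patterns - rowMeans(patterns)
    patterns <- patterns / pmax(apply(patterns, 1, stats::sd),
                                .Machine$double.eps)
    betas <- array(0, c(nVox, nTrials))
    emo <- rep(labels, each = trialsPerEmotion)
    for (tr in seq_len(nTrials))
      betas[region, tr] <- patterns[match(emo[tr], labels), ]
    if (world$noiseSd > 0)
      betas <- betas + matrix(stats::rnorm(nVox * nTrials,
                                           sd = world$noiseSd), nVox)
    list(betas = betas, emo = emo)
  }) -> g
  affine <- diag(c(world$voxelSizeMm, 1))
  BetaVolumeSet(array(g$betas, c(world$gridShape, nTrials)),
                mask = array(TRUE, world$gridShape), affine = affine,
                trials = data.frame(trial = seq_len(nTrials),
                                    emotion = g$emo,
                                    stringsAsFactors = FALSE))
}

#' Calibrate trial noise to a target RDM recovery correlation
#'
#' Finds, by bisection on Monte-Carlo replicates, the trial-level noise SD
#' at which the empirical emotion-pattern RDM recovered from generated
#' betas correlates at the target level (default 0.5, upper-triangle
#' Pearson) with the planted subject RDM. The recovery is evaluated at the
#' unit the downstream analysis uses: by default a single searchlight
#' sphere centered inside the signal region (\code{unit = "searchlight"}),
#' alternatively the whole region (\code{unit = "region"}).
#'
#' @param world a \code{\link{plantedWorld}} (its \code{noiseSd} is
#'   ignored).
#' @param trialsPerEmotion trials per emotion used downstream.
#' @param target desired correlation between recovered and planted RDM.
#' @param unit evaluation unit: \code{"searchlight"} (sphere of
#'   \code{radiusMm} at the region center) or \code{"region"}.
#' @param radiusMm sphere radius for the searchlight unit.
#' @param nRep Monte-Carlo replicates per candidate noise level.
#' @param interval search interval for the noise SD.
#' @param seed RNG seed for the calibration replicates.
#' @return the calibrated noise SD (numeric scalar).
#' @export
calibrateBetaNoise <- function(world, trialsPerEmotion = 4L, target = 0.5,
                               unit = c("searchlight", "region"),
                               radiusMm = 4, nRep = 24L,
                               interval = c(0.05, 20), seed = 1L) {
  stopifnot(inherits(world, "PlantedWorld"), target > 0, target < 1)
  unit <- match.arg(unit)
  idx <- if (unit == "region") {
    world$signalRegion
  } else {
    # sphere at the region-center voxel
    ctr <- world$signalRegion[ceiling(length(world$signalRegion) / 2)]
    aff <- diag(c(world$voxelSizeMm, 1))
    sl <- buildSearchlights(array(TRUE, world$gridShape), aff, radiusMm)
    Filter(function(s) s$centerIndex == ctr, sl$searchlights)[[1]]$members
  }
  meanRecovery <- function(sd) {
    w <- world
    w$noiseSd <- sd
    rs <- vapply(seq_len(nRep), function(r) {
      rdmS <- subjectRdm(w, r)
      bvs <- genBetaVolumes(w, rdmS, trialsPerEmotion,
                            seed = subSeed(seed, r))
      flat <- matrix(betaArray(bvs), nrow = prod(w$gridShape))
      emo <- trialInfo(bvs)$emotion
      means <- vapply(rdmLabels(rdmS), function(e)
        rowMeans(flat[idx, emo == e, drop = FALSE]),
        numeric(length(idx)))
      emp <- 1 - stats::cor(means)
      stats::cor(upperTriangle(emp), upperTriangle(rdmValues(rdmS)))
    }, numeric(1))
    mean(rs)
  }
  lo <- interval[1]; hi <- interval[2]
  if (meanRecovery(lo) < target)
    return(lo)                         # even minimal noise undershoots
  for (it in 1:12) {
    mid <- sqrt(lo * hi)               # geometric bisection, sd > 0
    if (meanRecovery(mid) > target) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Forward-model a BOLD time series from an event table
#'
#' Each voxel's series is the sum over trials of amplitude times the
#' trial's boxcar convolved with the HRF, sampled at the TR, plus iid
#' Gaussian noise. Used to exercise single-trial estimation with known
#' ground truth.
#'
#' @param events data.frame with \code{onset} and \code{duration} seconds.
#' @param amplitudes per-trial amplitudes: a vector (shared by all voxels)
#'   or a trials x voxels matrix.
#' @param hrf an \code{\link{canonicalHrf}} kernel (list with
#'   \code{samples}, \code{dt}).
#' @param TR repetition time, seconds.
#' @param noiseSd Gaussian noise SD.
#' @param seed RNG seed.
#' @param dims grid shape for the output volume.
#' @param nScans number of volumes; default covers the last event plus
#'   20 s.
#' @param drift optional amplitude of an additive low-frequency cosine
#'   drift (period twice the scan length), for high-pass filter testing.
#' @return 4-D array (x, y, z, time).
#' @export
genBold <- function(events, amplitudes, hrf = canonicalHrf(TR / 16),
                    TR = 1.5, noiseSd = 0, seed = 1L, dims = c(2L, 2L, 2L),
                    nScans = NULL, drift = 0) {
  if (TR <= 0) stop("'TR' must be positive")
  nVox <- prod(dims)
  nTrials <- nrow(events)
  if (is.null(nScans))
    nScans <- ceiling((max(events$onset + events$duration) + 20) / TR)
  if (max(events$onset) >= nScans * TR)
    stop("events extend beyond the scan")
  A <- if (is.matrix(amplitudes)) amplitudes
       else matrix(amplitudes, nTrials, nVox)
  stopifnot(nrow(A) == nTrials, ncol(A) == nVox)
  X <- trialRegressors(events, hrf, TR, nScans)   # nScans x nTrials
  Y <- X %*% A                                    # nScans x nVox
  if (drift != 0) {
    tsec <- (seq_len(nScans) - 1) * TR
    Y <- Y + drift * cos(pi * tsec / (nScans * TR))
  }
  if (noiseSd > 0)
    Y <- Y + withSeed(seed, matrix(stats::rnorm(nScans * nVox,
                                                sd = noiseSd), nScans))
  array(t(Y), c(dims, nScans))
}

#' Generate a pure sine tone
#'
#' @param f0 frequency in Hz; must be below the Nyquist frequency.
#' @param sr sample rate in Hz.
#' @param duration seconds.
#' @return numeric waveform of \code{round(sr * duration)} samples, unit
#'   amplitude.
#' @export
genTone <- function(f0, sr = 22050, duration = 1) {
  if (f0 <= 0 || f0 >= sr / 2)
    stop("'f0' must lie strictly between 0 and the Nyquist frequency sr/2")
  n <- round(sr * duration)
  sin(2 * pi * f0 * (seq_len(n) - 1) / sr)
}
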