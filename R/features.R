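#' Fundamental-frequency estimation by autocorrelation
#'
#' Frames the waveform, computes each frame's normalized autocorrelation,
#' and takes the lag of the autocorrelation peak inside the
#' \code{[sr/fmax, sr/fmin]} lag range as the period, refined by parabolic
#' interpolation. Frames whose peak normalized autocorrelation falls below
#' the voicing threshold are marked unvoiced (NA). The summary f0 is the
#' median over voiced frames (NA when no frame is voiced).
#'
#' @param wave numeric mono waveform.
#' @param sr sample rate, Hz.
#' @param fmin,fmax f0 search range, Hz; requires
#'   \code{fmin < fmax < sr/2}.
#' @param frame frame length in samples.
#' @param hop hop size in samples.
#' @param voicingThreshold minimum peak autocorrelation for a voiced
#'   frame.
#' @return list with \code{f0Track} (Hz per frame, NA when unvoiced),
#'   \code{voiced} (logical), \code{f0Median} (Hz or NA).
#' @export
autocorrPitch <- function(wave, sr, fmin = 75, fmax = 500,
                          frame = 2048L, hop = 512L,
                          voicingThreshold = 0.3) {
  stopifnot(fmin > 0, fmin < fmax, fmax < sr / 2)
  n <- length(wave)
  if (n < frame) stop("signal shorter than one frame")
  lagMin <- max(1L, floor(sr / fmax))
  lagMax <- min(frame - 2L, ceiling(sr / fmin))
  starts <- seq(1L, n - frame + 1L, by = hop)
  f0 <- rep(NA_real_, length(starts))
  for (fi in seq_along(starts)) {
    x <- wave[starts[fi]:(starts[fi] + frame - 1L)]
    x <- x - mean(x)
    r0 <- sum(x * x)
    if (r0 == 0) next
    lags <- lagMin:lagMax
    r <- vapply(lags, function(l)
      sum(x[1:(frame - l)] * x[(l + 1):frame]) / r0, numeric(1))
    pk <- which.max(r)
    if (r[pk] < voicingThreshold) next
    lag <- lags[pk]
    # parabolic refinement around the peak
    if (pk > 1 && pk < length(r)) {
      y1 <- r[pk - 1]; y2 <- r[pk]; y3 <- r[pk + 1]
      denom <- y1 - 2 * y2 + y3
      if (abs(denom) > .Machine$double.eps)
        lag <- lag + 0.5 * (y1 - y3) / denom
    }
    f0[fi] <- sr / lag
  }
  voiced <- !is.na(f0)
  list(f0Track = f0, voiced = voiced,
       f0Median = if (any(voiced)) stats::median(f0[voiced]) else NA_real_)
}

#' Assemble a pitch feature table from waveforms
#'
#' Extracts each stimulus's f0 track with \code{\link{autocorrPitch}} and
#' resamples the voiced portion to a fixed number of points by linear
#' interpolation, yielding one fixed-length pitch vector per stimulus.
#' This makes per-emotion Pearson distances well-defined where a single
#' scalar f0 per stimulus would not be.
#'
#' @param waves named list of numeric waveforms; names carry the emotion
#'   label of each stimulus (e.g. \code{"happy.3"}; the part before the
#'   first dot is used).
#' @param sr sample rate, Hz.
#' @param nPoints length of the resampled pitch vector.
#' @param ... passed to \code{\link{autocorrPitch}}.
#' @return data.frame with an \code{emotion} column and \code{nPoints}
#'   feature columns.
#' @export
pitchFeatureTable <- function(waves, sr, nPoints = 20L, ...) {
  stopifnot(length(waves) > 0, !is.null(names(waves)))
  rows <- lapply(names(waves), function(nm) {
    tr <- autocorrPitch(waves[[nm]], sr, ...)
    v <- tr$f0Track[tr$voiced]
    if (length(v) < 2) stop("stimulus '", nm, "' has fewer than 2 voiced frames")
    f <- stats::approx(seq_along(v), v, n = nPoints)$y
    c(list(emotion = sub("\\..*$", "", nm)),
      as.list(stats::setNames(f, paste0("p", seq_len(nPoints)))))
  })
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Pearson-distance RDM from a stimulus feature table
#'
#' Averages the feature vectors of each emotion's stimuli into one vector
#' per emotion (or, with \code{average = FALSE}, averages pairwise
#' stimulus-level distances) and returns the matrix of Pearson correlation
#' distances \eqn{1 - r} between emotions.
#'
#' @param features data.frame with an \code{emotion} column and numeric
#'   feature columns, no missing values.
#' @param average average features within emotion before the distance
#'   (default); otherwise average stimulus-pair distances.
#' @return a \linkS4class{DissimilarityMatrix} (correlation type).
#' @export
featureRdm <- function(features, average = TRUE) {
  stopifnot("emotion" %in% names(features))
  F <- as.matrix(features[setdiff(names(features), "emotion")])
  if (anyNA(F)) stop("feature table contains missing values")
  if (ncol(F) < 2) stop("need at least 2 feature columns for Pearson")
  emo <- as.character(features$emotion)
  labels <- unique(emo)
  if (average) {
    M <- t(vapply(labels, function(e)
      colMeans(F[emo == e, , drop = FALSE]), numeric(ncol(F))))
    if (any(apply(M, 1, stats::sd) == 0))
      stop("constant feature vector for emotion(s): ",
           paste(labels[apply(M, 1, stats::sd) == 0], collapse = ", "))
    d <- 1 - stats::cor(t(M))
  } else {
    if (any(apply(F, 1, stats::sd) == 0))
      stop("constant stimulus feature vector")
    ds <- 1 - stats::cor(t(F))
    d <- matrix(0, length(labels), length(labels))
    for (i in seq_along(labels))
      for (j in seq_along(labels))
        if (i != j)
          d[i, j] <- mean(ds[emo == labels[i], emo == labels[j]])
  }
  d <- pmin(pmax((d + t(d)) / 2, 0), 2)
  d[abs(d) < 1e-12] <- 0               # snap numerically-zero distances
  diag(d) <- 0
  DissimilarityMatrix(d, labels = labels, type = "correlation")
}
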