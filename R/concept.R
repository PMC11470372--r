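#' Conceptual dissimilarity from an emotion-word rating matrix
#'
#' The conceptual dissimilarity between two emotion categories is the
#' Pearson correlation distance between their rating vectors over the
#' feature words: \eqn{d(i, j) = 1 - r(\mathrm{row}_i, \mathrm{row}_j)}.
#' A value of 0 means perfect conceptual similarity; 2 means perfectly
#' anticorrelated rating profiles.
#'
#' @param ratings numeric matrix, emotions x words (e.g. from
#'   \code{\link{genSubjectRatings}}); row names are the emotion labels.
#' @return a \linkS4class{DissimilarityMatrix} (correlation type).
#' @export
rdmFromRatings <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings contain missing entries")
  labels <- rownames(ratings)
  if (is.null(labels)) labels <- paste0("e", seq_len(nrow(ratings)))
  sds <- apply(ratings, 1, stats::sd)
  if (any(sds == 0))
    stop("constant rating row(s): ",
         paste(labels[sds == 0], collapse = ", "),
         " (Pearson correlation undefined)")
  d <- 1 - stats::cor(t(ratings))
  d <- pmin(pmax((d + t(d)) / 2, 0), 2)
  d[abs(d) < 1e-12] <- 0               # snap numerically-zero distances
  diag(d) <- 0
  DissimilarityMatrix(d, labels = labels, type = "correlation")
}

#' Elementwise average of dissimilarity matrices
#'
#' @param rdms non-empty list of \linkS4class{DissimilarityMatrix} objects
#'   with identical labels.
#' @return their elementwise mean as a \linkS4class{DissimilarityMatrix}.
#' @export
averageRdm <- function(rdms) {
  if (!length(rdms)) stop("'rdms' must be non-empty")
  labs <- rdmLabels(rdms[[1]])
  for (r in rdms)
    if (!identical(rdmLabels(r), labs))
      stop("all matrices must share one label set")
  m <- Reduce(`+`, lapply(rdms, rdmValues)) / length(rdms)
  DissimilarityMatrix(m, labels = labs, type = rdms[[1]]@type)
}

# Kruskal stress-1 with primary tie handling: disparities are the isotonic
# fit of configuration distances taken in dissimilarity order, ties broken
# by current distance (so tied dissimilarities impose no order constraint).
.kruskalStress <- function(dvec, deltaOrder) {
  dOrd <- dvec[deltaOrder]
  fit <- stats::isoreg(dOrd)$yf
  dhat <- numeric(length(dvec))
  dhat[deltaOrder] <- fit
  list(stress = sqrt(sum((dvec - dhat)^2) / sum(dvec^2)), dhat = dhat)
}

#' Kruskal nonmetric multidimensional scaling
#'
#' Embeds a dissimilarity matrix in \code{dims} dimensions by minimizing
#' Kruskal stress-1 with Guttman-transform majorization and isotonic
#' regression on the dissimilarity ranks (primary tie treatment). The
#' starting configuration is the classical (Torgerson) metric MDS
#' solution. Iteration stops when the stress improvement falls below
#' \code{tol} or after \code{maxIter} iterations.
#'
#' @param rdm a \linkS4class{DissimilarityMatrix}.
#' @param dims embedding dimensionality (must be < number of items).
#' @param maxIter iteration cap.
#' @param tol stop when the per-iteration stress improvement is below this.
#' @return an \linkS4class{MdsSolution}.
#' @export
nonmetricMds <- function(rdm, dims = 2L, maxIter = 300L, tol = 1e-6) {
  delta <- rdmValues(rdm)
  n <- nrow(delta)
  if (dims >= n) stop("'dims' must be smaller than the number of items")
  X <- stats::cmdscale(stats::as.dist(delta), k = dims)
  if (ncol(X) < dims)                   # degenerate input, pad with zeros
    X <- cbind(X, matrix(0, n, dims - ncol(X)))
  dvecOf <- function(X) as.vector(stats::dist(X))
  deltaVec <- as.vector(stats::as.dist(delta))
  dvec <- dvecOf(X)
  # primary ties: order by dissimilarity, then by current distance
  orderNow <- function(dvec) order(deltaVec, dvec)
  st <- .kruskalStress(dvec, orderNow(dvec))
  trace <- st$stress
  iter <- 0L
  while (iter < maxIter && st$stress > 1e-12) {
    iter <- iter + 1L
    # Guttman transform with current disparities
    Dm <- symmetricFromLower(dvec, n)
    Dhat <- symmetricFromLower(st$dhat, n)
    ratio <- ifelse(Dm > 0, Dhat / Dm, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    Xnew <- B %*% X / n
    dvecNew <- dvecOf(Xnew)
    stNew <- .kruskalStress(dvecNew, orderNow(dvecNew))
    improvement <- st$stress - stNew$stress
    X <- Xnew; dvec <- dvecNew; st <- stNew
    trace <- c(trace, st$stress)
    if (improvement < tol) break
  }
  rownames(X) <- rdmLabels(rdm)
  new("MdsSolution", coordinates = X, stress = st$stress,
      nIterations = iter, stressTrace = trace)
}

#' Ward hierarchical clustering of emotion categories
#'
#' Agglomerative clustering of the dissimilarity matrix under Ward's
#' criterion in the Murtagh-Legendre "Ward2" convention: the
#' Lance-Williams recurrence runs on squared dissimilarities and merge
#' heights are reported on the original (square-rooted) scale, as
#' implemented by \code{\link[stats]{hclust}} with
#' \code{method = "ward.D2"}.
#'
#' @param rdm a \linkS4class{DissimilarityMatrix}.
#' @return an \code{hclust} object with an added \code{"convention"}
#'   attribute recording the Ward2 choice.
#' @export
wardClustering <- function(rdm) {
  hc <- stats::hclust(stats::as.dist(rdmValues(rdm)), method = "ward.D2")
  attr(hc, "convention") <- "Ward2 (Lance-Williams on squared dissimilarities, square-rooted heights)"
  hc
}
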