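#' Build an emotion-categorization confusion matrix
#'
#' Tabulates response records into a square count matrix with rows for the
#' presented (true) category and columns for the chosen response.
#'
#' @param responses data.frame with columns \code{true} and
#'   \code{response} (labels drawn from \code{labels}).
#' @param labels category label set; defaults to the seven emotions of
#'   the default \code{\link{designSpec}}.
#' @return a \linkS4class{ConfusionMatrix}.
#' @export
buildConfusion <- function(responses, labels = designSpec()$emotions) {
  stopifnot(all(c("true", "response") %in% names(responses)))
  bad <- setdiff(unique(c(responses$true, responses$response)), labels)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(responses$true, levels = labels),
                  factor(responses$response, levels = labels))
  ConfusionMatrix(matrix(as.integer(counts), length(labels),
                         dimnames = list(labels, labels)))
}

#' Transform confusion counts to a dissimilarity matrix
#'
#' Each off-diagonal count is subtracted from the largest off-diagonal
#' count: \eqn{d(i, j) = \max_{k \ne l} c(k, l) - c(i, j)}. The diagonal is
#' set to zero and excluded from downstream use, and the matrix is left
#' asymmetric (only the upper triangle is used downstream). Note the
#' direction this transform implies: pairs confused \emph{often} receive
#' \emph{small} values, i.e. behave as similar, which is what makes a
#' positive correlation with conceptual dissimilarity the expected sign.
#' An averaged symmetrization is available but off by default.
#'
#' @param cm a \linkS4class{ConfusionMatrix}.
#' @param symmetrize average counts with their transpose first.
#' @return a \linkS4class{DissimilarityMatrix} of type \code{"confusion"}.
#' @export
confusionToDissimilarity <- function(cm, symmetrize = FALSE) {
  counts <- confusionCounts(cm)
  counts <- counts * 1.0
  if (symmetrize) counts <- (counts + t(counts)) / 2
  off <- counts
  diag(off) <- NA
  mx <- suppressWarnings(max(off, na.rm = TRUE))
  if (!is.finite(mx)) mx <- 0           # 1 x 1 or all-NA corner case
  d <- mx - counts
  diag(d) <- 0
  DissimilarityMatrix(d, labels = rownames(counts), type = "confusion")
}

#' Correlate the upper triangles of two dissimilarity matrices
#'
#' Z-scores the strict upper-triangle values of each matrix and computes
#' their Pearson correlation (invariant to the z-scoring, which is kept
#' for scale comparability of the reported values), with the two-sided p
#' value from the t transform of r on \code{nPairs - 2} degrees of
#' freedom. For 7 emotion categories this is r on 19 df.
#'
#' @param a,b \linkS4class{DissimilarityMatrix} objects with matching
#'   labels.
#' @return list with \code{r}, \code{df}, \code{p}, \code{n} (number of
#'   pairs).
#' @export
correlateUpperTriangles <- function(a, b) {
  if (!identical(rdmLabels(a), rdmLabels(b)))
    stop("label sets must match")
  x <- upperTriangle(a)
  y <- upperTriangle(b)
  if (length(x) < 3) stop("need at least 3 upper-triangle entries")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance upper triangle")
  zx <- as.vector(scale(x))
  zy <- as.vector(scale(y))
  r <- stats::cor(zx, zy)
  df <- length(x) - 2L
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  list(r = r, df = df, p = p, n = length(x))
}
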