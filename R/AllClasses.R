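#' @import methods
NULL

.STAT_KINDS <- c("t", "z", "F", "tfce", "p_corrected", "fisher_z", "beta")

#' DissimilarityMatrix: pairwise dissimilarities between emotion categories
#'
#' A small square matrix of pairwise dissimilarities between conditions
#' (here, emotion categories), with labels carried as dimnames.  Three
#' flavours circulate in the pipeline and are recorded in the \code{type}
#' slot: \code{"correlation"} (Pearson correlation distance, \eqn{d = 1 - r},
#' symmetric with entries in [0, 2]), \code{"confusion"} (derived from a
#' categorization confusion matrix by subtracting off-diagonal counts from
#' the largest off-diagonal count; allowed to be asymmetric, only the upper
#' triangle is meaningful downstream), and \code{"general"} (any symmetric
#' non-negative dissimilarity).
#'
#' @slot values numeric matrix, square, zero diagonal, labelled dimnames.
#' @slot type character, one of \code{"correlation"}, \code{"confusion"},
#'   \code{"general"}.
#' @exportClass DissimilarityMatrix
setClass("DissimilarityMatrix",
  representation(values = "matrix", type = "character"),
  prototype(type = "correlation"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v) || nrow(v) != ncol(v))
      return("'values' must be a square numeric matrix")
    if (anyNA(v) || any(!is.finite(v)))
      return("'values' must be finite with no missing entries")
    if (any(abs(diag(v)) > 1e-12))
      return("diagonal must be zero")
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
      return("rows must carry unique labels")
    if (!identical(rownames(v), colnames(v)))
      return("row and column labels must agree")
    if (!object@type %in% c("correlation", "confusion", "general"))
      return("unknown 'type'")
    if (object@type != "confusion" && any(abs(v - t(v)) > 1e-8))
      return("matrix must be symmetric")
    if (object@type == "correlation" &&
        (min(v) < -1e-8 || max(v) > 2 + 1e-8))
      return("correlation-distance entries must lie in [0, 2]")
    TRUE
  }
)

#' Construct a DissimilarityMatrix
#'
#' @param values square numeric matrix with zero diagonal.
#' @param labels optional character labels; defaults to existing dimnames or
#'   \code{e1, e2, ...}.
#' @param type dissimilarity flavour; see \linkS4class{DissimilarityMatrix}.
#' @return a \linkS4class{DissimilarityMatrix}.
#' @export
DissimilarityMatrix <- function(values, labels = NULL,
                                type = c("correlation", "general",
                                         "confusion")) {
  type <- match.arg(type)
  values <- as.matrix(values)
  if (is.null(labels))
    labels <- rownames(values)
  if (is.null(labels))
    labels <- paste0("e", seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  new("DissimilarityMatrix", values = values, type = type)
}

#' @describeIn DissimilarityMatrix-accessors matrix of dissimilarities
#' @export
setGeneric("rdmValues", function(x) standardGeneric("rdmValues"))
#' @describeIn DissimilarityMatrix-accessors condition labels
#' @export
setGeneric("rdmLabels", function(x) standardGeneric("rdmLabels"))

#' Accessors for DissimilarityMatrix
#'
#' @param x a \linkS4class{DissimilarityMatrix}.
#' @name DissimilarityMatrix-accessors
NULL

#' @rdname DissimilarityMatrix-accessors
#' @export
setMethod("rdmValues", "DissimilarityMatrix", function(x) x@values)
#' @rdname DissimilarityMatrix-accessors
#' @export
setMethod("rdmLabels", "DissimilarityMatrix", function(x) rownames(x@values))

setMethod("show", "DissimilarityMatrix", function(object) {
  cat(sprintf("DissimilarityMatrix (%s) with %d conditions: %s\n",
              object@type, nrow(object@values),
              paste(rdmLabels(object), collapse = ", ")))
  print(round(object@values, 3))
})

#' ConfusionMatrix: emotion-categorization response counts
#'
#' Rows index the presented (true) category, columns the chosen response.
#' Row sums equal the number of trials presented per true category.
#'
#' @slot counts non-negative integer matrix with matching row/column labels.
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(counts = "matrix"),
  validity = function(object) {
    cm <- object@counts
    if (nrow(cm) != ncol(cm)) return("'counts' must be square")
    if (anyNA(cm) || any(cm < 0) || any(cm != round(cm)))
      return("'counts' must be non-negative integers")
    if (is.null(rownames(cm)) ||
        !identical(rownames(cm), colnames(cm)))
      return("rows and columns must share one label set")
    TRUE
  }
)

#' Construct a ConfusionMatrix
#' @param counts square non-negative integer matrix.
#' @param labels optional labels (defaults to dimnames).
#' @return a \linkS4class{ConfusionMatrix}.
#' @export
ConfusionMatrix <- function(counts, labels = NULL) {
  counts <- as.matrix(counts)
  if (is.null(labels)) labels <- rownames(counts)
  if (is.null(labels)) labels <- paste0("e", seq_len(nrow(counts)))
  dimnames(counts) <- list(labels, labels)
  new("ConfusionMatrix", counts = counts)
}

#' @describeIn ConfusionMatrix-accessors count matrix
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' Accessors for ConfusionMatrix
#' @param x a \linkS4class{ConfusionMatrix}.
#' @name ConfusionMatrix-accessors
NULL

#' @rdname ConfusionMatrix-accessors
#' @export
setMethod("confusionCounts", "ConfusionMatrix", function(x) x@counts)

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix, %d categories, %d responses\n",
              nrow(object@counts), sum(object@counts)))
  print(object@counts)
})

#' BetaVolumeSet: per-trial coefficient volumes on a shared grid
#'
#' Holds one 3-D coefficient volume per modeled trial, stacked as a 4-D
#' array, together with the binary analysis mask, the voxel-to-world affine
#' and per-trial metadata (at minimum an \code{emotion} column).
#'
#' @slot betas 4-D numeric array (x, y, z, trial).
#' @slot mask 3-D logical array on the same grid.
#' @slot affine 4 x 4 voxel-to-world matrix.
#' @slot trials data.frame of trial metadata, one row per volume.
#' @exportClass BetaVolumeSet
setClass("BetaVolumeSet",
  representation(betas = "array", mask = "array", affine = "matrix",
                 trials = "data.frame"),
  validity = function(object) {
    if (length(dim(object@betas)) != 4L)
      return("'betas' must be a 4-D array")
    if (!identical(dim(object@mask), dim(object@betas)[1:3]))
      return("'mask' grid must match 'betas'")
    if (!identical(dim(object@affine), c(4L, 4L)))
      return("'affine' must be 4 x 4")
    if (nrow(object@trials) != dim(object@betas)[4])
      return("one metadata row per trial volume required")
    TRUE
  }
)

#' Construct a BetaVolumeSet
#' @param betas 4-D array (x, y, z, trial).
#' @param mask 3-D logical/numeric mask.
#' @param affine 4 x 4 voxel-to-world matrix; default scales by 1 mm.
#' @param trials data.frame of per-trial metadata.
#' @return a \linkS4class{BetaVolumeSet}.
#' @export
BetaVolumeSet <- function(betas, mask = NULL, affine = diag(4), trials) {
  if (is.null(mask)) mask <- array(TRUE, dim(betas)[1:3])
  new("BetaVolumeSet", betas = betas, mask = array(as.logical(mask),
      dim(mask)), affine = affine, trials = as.data.frame(trials))
}

#' @describeIn BetaVolumeSet-accessors 4-D beta array
#' @export
setGeneric("betaArray", function(x) standardGeneric("betaArray"))
#' @describeIn BetaVolumeSet-accessors binary analysis mask
#' @export
setGeneric("volumeMask", function(x) standardGeneric("volumeMask"))
#' @describeIn BetaVolumeSet-accessors voxel-to-world affine
#' @export
setGeneric("volumeAffine", function(x) standardGeneric("volumeAffine"))
#' @describeIn BetaVolumeSet-accessors per-trial metadata
#' @export
setGeneric("trialInfo", function(x) standardGeneric("trialInfo"))

#' Accessors for BetaVolumeSet
#' @param x a \linkS4class{BetaVolumeSet}.
#' @name BetaVolumeSet-accessors
NULL

#' @rdname BetaVolumeSet-accessors
#' @export
setMethod("betaArray", "BetaVolumeSet", function(x) x@betas)
#' @rdname BetaVolumeSet-accessors
#' @export
setMethod("volumeMask", "BetaVolumeSet", function(x) x@mask)
#' @rdname BetaVolumeSet-accessors
#' @export
setMethod("volumeAffine", "BetaVolumeSet", function(x) x@affine)
#' @rdname BetaVolumeSet-accessors
#' @export
setMethod("trialInfo", "BetaVolumeSet", function(x) x@trials)

setMethod("show", "BetaVolumeSet", function(object) {
  d <- dim(object@betas)
  cat(sprintf("BetaVolumeSet: %d trials on a %d x %d x %d grid (%d in mask)\n",
              d[4], d[1], d[2], d[3], sum(object@mask)))
  if ("emotion" %in% names(object@trials))
    cat("  emotions:",
        paste(names(table(object@trials$emotion)), collapse = ", "), "\n")
})

#' StatMap: a 3-D statistic map on the mask grid
#'
#' @slot values 3-D numeric array.
#' @slot kind statistic kind: t, z, F, tfce, p_corrected, fisher_z or beta.
#' @slot df degrees of freedom where applicable (length 0, 1 or 2).
#' @exportClass StatMap
setClass("StatMap",
  representation(values = "array", kind = "character", df = "numeric"),
  prototype(df = numeric(0)),
  validity = function(object) {
    if (length(dim(object@values)) != 3L)
      return("'values' must be a 3-D array")
    if (!object@kind %in% .STAT_KINDS)
      return(paste("'kind' must be one of:",
                   paste(.STAT_KINDS, collapse = ", ")))
    if (object@kind == "p_corrected" &&
        (min(object@values, na.rm = TRUE) < 0 ||
         max(object@values, na.rm = TRUE) > 1))
      return("p maps must lie in [0, 1]")
    TRUE
  }
)

#' Construct a StatMap
#' @param values 3-D numeric array.
#' @param kind statistic kind (see \linkS4class{StatMap}).
#' @param df optional degrees of freedom.
#' @return a \linkS4class{StatMap}.
#' @export
StatMap <- function(values, kind, df = numeric(0)) {
  new("StatMap", values = values, kind = kind, df = as.numeric(df))
}

#' @describeIn StatMap-accessors 3-D array of values
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @describeIn StatMap-accessors statistic kind
#' @export
setGeneric("mapKind", function(x) standardGeneric("mapKind"))

#' Accessors for StatMap
#' @param x a \linkS4class{StatMap}.
#' @name StatMap-accessors
NULL

#' @rdname StatMap-accessors
#' @export
setMethod("mapValues", "StatMap", function(x) x@values)
#' @rdname StatMap-accessors
#' @export
setMethod("mapKind", "StatMap", function(x) x@kind)

setMethod("show", "StatMap", function(object) {
  d <- dim(object@values)
  rng <- range(object@values, na.rm = TRUE)
  cat(sprintf("StatMap (%s%s), %d x %d x %d, range [%.3g, %.3g]\n",
              object@kind,
              if (length(object@df))
                paste0(", df = ", paste(object@df, collapse = ", "))
              else "",
              d[1], d[2], d[3], rng[1], rng[2]))
})

#' MdsSolution: a nonmetric multidimensional scaling configuration
#'
#' @slot coordinates items x dims configuration.
#' @slot stress final Kruskal stress-1 value.
#' @slot nIterations number of majorization iterations performed.
#' @slot stressTrace stress value after each iteration.
#' @exportClass MdsSolution
setClass("MdsSolution",
  representation(coordinates = "matrix", stress = "numeric",
                 nIterations = "integer", stressTrace = "numeric"),
  validity = function(object) {
    if (any(!is.finite(object@coordinates)))
      return("coordinates must be finite")
    if (object@stress < 0) return("stress must be non-negative")
    TRUE
  }
)

setMethod("show", "MdsSolution", function(object) {
  cat(sprintf(
    "MdsSolution: %d items in %d dims, stress-1 = %.3g (%d iterations)\n",
    nrow(object@coordinates), ncol(object@coordinates),
    object@stress, object@nIterations))
})

#' RsaResultMap: searchlight RSA coefficient maps
#'
#' One Fisher-transformed standardized coefficient map per model RDM, with
#' a mask of valid searchlight centers. Centers dropped for degeneracy
#' (too few voxels, constant patterns) are absent from \code{centerMask}
#' and recorded in \code{dropped}.
#'
#' @slot coefficients 4-D array (x, y, z, model), model names as dimnames.
#' @slot centerMask 3-D logical array of valid centers.
#' @slot affine 4 x 4 voxel-to-world matrix.
#' @slot dropped integer vector of linear voxel indices of dropped centers.
#' @exportClass RsaResultMap
setClass("RsaResultMap",
  representation(coefficients = "array", centerMask = "array",
                 affine = "matrix", dropped = "integer"),
  validity = function(object) {
    if (length(dim(object@coefficients)) != 4L)
      return("'coefficients' must be 4-D (x, y, z, model)")
    if (!identical(dim(object@centerMask), dim(object@coefficients)[1:3]))
      return("'centerMask' grid must match coefficients")
    TRUE
  }
)

#' @describeIn RsaResultMap-accessors extract one model's coefficient map
#' @export
setGeneric("modelMap", function(x, model) standardGeneric("modelMap"))

#' Accessors for RsaResultMap
#' @param x an \linkS4class{RsaResultMap}.
#' @param model model name or index.
#' @name RsaResultMap-accessors
NULL

#' @rdname RsaResultMap-accessors
#' @export
setMethod("modelMap", "RsaResultMap", function(x, model) {
  StatMap(x@coefficients[, , , model, drop = TRUE], kind = "fisher_z")
})

#' @rdname RsaResultMap-accessors
#' @param ... unused.
#' @export
setGeneric("validCenters", function(x, ...) standardGeneric("validCenters"))
#' @rdname RsaResultMap-accessors
#' @export
setMethod("validCenters", "RsaResultMap", function(x, ...) x@centerMask)

setMethod("show", "RsaResultMap", function(object) {
  d <- dim(object@coefficients)
  cat(sprintf(
    "RsaResultMap: %d model(s) [%s] on %d x %d x %d grid, %d centers (%d dropped)\n",
    d[4], paste(dimnames(object@coefficients)[[4]], collapse = ", "),
    d[1], d[2], d[3], sum(object@centerMask), length(object@dropped)))
})

#' PermutationResult: sign-permutation TFCE inference output
#'
#' @slot tMap observed group t map.
#' @slot observedTfce TFCE-enhanced observed map.
#' @slot nullMax maximum TFCE statistic per permutation.
#' @slot pCorrected FWE-corrected p map (max-statistic correction).
#' @slot zMap corrected p converted to one-sided z scores.
#' @slot significant logical 3-D array, z >= threshold.
#' @slot nPerm number of permutations.
#' @slot seed RNG seed used.
#' @slot zThreshold display/significance threshold on z.
#' @exportClass PermutationResult
setClass("PermutationResult",
  representation(tMap = "StatMap", observedTfce = "StatMap",
                 nullMax = "numeric", pCorrected = "StatMap",
                 zMap = "StatMap", significant = "array",
                 nPerm = "integer", seed = "integer",
                 zThreshold = "numeric"),
  validity = function(object) {
    if (length(object@nullMax) != object@nPerm)
      return("null vector length must equal nPerm")
    pv <- mapValues(object@pCorrected)
    pv <- pv[is.finite(pv)]
    if (length(pv) && min(pv) < 1 / (object@nPerm + 1) - 1e-12)
      return("corrected p cannot undercut 1/(nPerm + 1)")
    TRUE
  }
)

#' @describeIn PermutationResult-accessors FWE-corrected p map
#' @export
setGeneric("correctedP", function(x) standardGeneric("correctedP"))
#' @describeIn PermutationResult-accessors corrected z map
#' @export
setGeneric("zMap", function(x) standardGeneric("zMap"))
#' @describeIn PermutationResult-accessors logical significance mask
#' @export
setGeneric("significantVoxels", function(x) standardGeneric("significantVoxels"))
#' @describeIn PermutationResult-accessors per-permutation max TFCE values
#' @export
setGeneric("nullMaxima", function(x) standardGeneric("nullMaxima"))

#' Accessors for PermutationResult
#' @param x a \linkS4class{PermutationResult}.
#' @name PermutationResult-accessors
NULL

#' @rdname PermutationResult-accessors
#' @export
setMethod("correctedP", "PermutationResult", function(x) x@pCorrected)
#' @rdname PermutationResult-accessors
#' @export
setMethod("zMap", "PermutationResult", function(x) x@zMap)
#' @rdname PermutationResult-accessors
#' @export
setMethod("significantVoxels", "PermutationResult", function(x) x@significant)
#' @rdname PermutationResult-accessors
#' @export
setMethod("nullMaxima", "PermutationResult", function(x) x@nullMax)

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult: %d permutations, %d voxels significant at z >= %.2f\n",
    object@nPerm, sum(object@significant), object@zThreshold))
})
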