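#' Read a long-format rating table
#'
#' Expects a tab-separated file with columns \code{participant},
#' \code{emotion}, \code{word}, \code{rating} and returns one
#' emotions x words rating matrix per participant.
#'
#' @param path TSV file path.
#' @return named list of rating matrices.
#' @export
readRatingsTsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("participant", "emotion", "word", "rating") %in%
                  names(d)))
  lapply(split(d, d$participant), function(p) {
    m <- tapply(p$rating, list(p$emotion, p$word), mean)
    if (anyNA(m)) stop("incomplete rating table")
    m
  })
}

#' Write a rating matrix in long format
#' @param ratings emotions x words matrix.
#' @param participant participant identifier.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writeRatingsTsv <- function(ratings, participant, path) {
  d <- expand.grid(emotion = rownames(ratings), word = colnames(ratings),
                   stringsAsFactors = FALSE)
  d$participant <- participant
  d$rating <- as.vector(ratings)
  utils::write.table(d[, c("participant", "emotion", "word", "rating")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write labeled RDM CSV files
#'
#' @param x a \linkS4class{DissimilarityMatrix} (for writing).
#' @param path CSV path.
#' @param type dissimilarity flavour for reading.
#' @return \code{readRdmCsv}: a \linkS4class{DissimilarityMatrix};
#'   \code{writeRdmCsv}: the path, invisibly.
#' @name rdm-io
NULL

#' @rdname rdm-io
#' @export
writeRdmCsv <- function(x, path) {
  utils::write.csv(rdmValues(x), path, row.names = TRUE)
  invisible(path)
}

#' @rdname rdm-io
#' @export
readRdmCsv <- function(path, type = "correlation") {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  DissimilarityMatrix(m, labels = rownames(m), type = type)
}

#' Read / write BIDS-style event tables
#'
#' Tab-separated with at least \code{onset}, \code{duration},
#' \code{trial_type}.
#'
#' @param events event data.frame (for writing).
#' @param path TSV path.
#' @return \code{readEventsTsv}: a data.frame; \code{writeEventsTsv}: the
#'   path, invisibly.
#' @name events-io
NULL

#' @rdname events-io
#' @export
writeEventsTsv <- function(events, path) {
  stopifnot(all(c("onset", "duration", "trial_type") %in% names(events)))
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname events-io
#' @export
readEventsTsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a 3-D or 4-D volume as NIfTI-1
#'
#' @param x numeric array, \linkS4class{StatMap} or
#'   \linkS4class{BetaVolumeSet}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @param affine 4 x 4 voxel-to-world matrix (taken from the object when
#'   it carries one).
#' @return invisibly, the path.
#' @export
writeVolumeNifti <- function(x, path, affine = diag(4)) {
  if (is(x, "StatMap")) x <- mapValues(x)
  if (is(x, "BetaVolumeSet")) {
    affine <- volumeAffine(x)
    x <- betaArray(x)
  }
  img <- RNifti::asNifti(x)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume with its affine
#'
#' @param path NIfTI file path.
#' @return list with \code{data} (array) and \code{affine} (4 x 4).
#' @export
readVolumeNifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = as.array(img), affine = unclass(RNifti::xform(img)))
}

#' Write a BetaVolumeSet as a 4-D NIfTI stack plus JSON sidecar
#'
#' @param bvs a \linkS4class{BetaVolumeSet}.
#' @param path output NIfTI path; the sidecar replaces the extension with
#'   \code{.json} and stores trial metadata and the mask indices.
#' @return invisibly, the path.
#' @export
writeBetaStack <- function(bvs, path) {
  writeVolumeNifti(bvs, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(trials = trialInfo(bvs),
                            maskIndices = which(volumeMask(bvs))),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
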