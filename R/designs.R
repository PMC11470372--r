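#' Task design specification
#'
#' Bundles the constants of the behavioral rating task and the scanner
#' task: 7 emotion categories rated against 40 feature words on a 1-7
#' scale, and scanner sessions of 4 blocks x 7 emotion trials, each trial
#' presenting 4 actors for 3 s after a 4.5-s fixation, a 3-s post-stimulus
#' fixation, 12-s rests between blocks, and 2 catch trials per session.
#'
#' @param nEmotions number of emotion categories.
#' @param nWords number of feature words rated against each emotion.
#' @param ratingScale integer range of the rating scale.
#' @param sessions scanner sessions per participant.
#' @param blocksPerSession blocks in each session.
#' @param trialsPerBlock emotion trials per block (one per emotion).
#' @param actorsPerTrial stimuli (actors) presented within one trial.
#' @param catchPerSession attention catch trials per session.
#' @param timings named list of seconds: \code{preFix}, \code{stim},
#'   \code{postFix}, \code{blockRest}.
#' @param emotions emotion category labels.
#' @return a list of class \code{"DesignSpec"}.
#' @export
designSpec <- function(nEmotions = 7L, nWords = 40L,
                       ratingScale = c(1L, 7L),
                       sessions = 4L, blocksPerSession = 4L,
                       trialsPerBlock = 7L, actorsPerTrial = 4L,
                       catchPerSession = 2L,
                       timings = list(preFix = 4.5, stim = 3.0,
                                      postFix = 3.0, blockRest = 12.0),
                       emotions = NULL) {
  spec <- list(nEmotions = as.integer(nEmotions),
               nWords = as.integer(nWords),
               ratingScale = as.integer(ratingScale),
               sessions = as.integer(sessions),
               blocksPerSession = as.integer(blocksPerSession),
               trialsPerBlock = as.integer(trialsPerBlock),
               actorsPerTrial = as.integer(actorsPerTrial),
               catchPerSession = as.integer(catchPerSession),
               timings = timings,
               emotions = emotions)
  counts <- c(spec$nEmotions, spec$nWords, spec$sessions,
              spec$blocksPerSession, spec$trialsPerBlock,
              spec$actorsPerTrial)
  if (any(counts <= 0)) stop("all design counts must be positive")
  if (spec$catchPerSession < 0) stop("catch count must be non-negative")
  if (spec$ratingScale[1] >= spec$ratingScale[2])
    stop("rating scale bounds must be ordered")
  if (any(unlist(timings) < 0)) stop("timings must be non-negative")
  if (is.null(spec$emotions)) {
    base <- c("angry", "disgusted", "fearful", "happy", "sad",
              "surprised", "neutral")
    spec$emotions <- if (spec$nEmotions <= 7L) base[seq_len(spec$nEmotions)]
                     else c(base, paste0("emotion", 8:spec$nEmotions))
  }
  if (length(spec$emotions) != spec$nEmotions)
    stop("need one label per emotion")
  class(spec) <- "DesignSpec"
  spec
}

#' Generate a rating-task trial list
#'
#' One block per emotion category in random order; within each block the
#' feature words appear in random order. For the default design this yields
#' 280 records (7 emotions x 40 words).
#'
#' @param spec a \code{\link{designSpec}}.
#' @param seed RNG seed; fixes the block and word orders.
#' @return data.frame with columns \code{trial}, \code{block},
#'   \code{emotion}, \code{word}.
#' @export
genRatingDesign <- function(spec = designSpec(), seed = 1L) {
  stopifnot(inherits(spec, "DesignSpec"))
  words <- paste0("word", sprintf("%02d", seq_len(spec$nWords)))
  withSeed(seed, {
    blockOrder <- sample(spec$emotions)
    rows <- do.call(rbind, lapply(seq_along(blockOrder), function(b) {
      data.frame(block = b, emotion = blockOrder[b],
                 word = sample(words), stringsAsFactors = FALSE)
    }))
    rows
  }) -> rows
  rows$trial <- seq_len(nrow(rows))
  rows[, c("trial", "block", "emotion", "word")]
}

#' Generate one scanner-session event table
#'
#' Builds the within-session event sequence: \code{blocksPerSession} blocks
#' each holding one trial per emotion in random order; every emotion trial
#' expands to \code{actorsPerTrial} consecutive 3-s stimulus records after
#' a 4.5-s fixation, followed by a 3-s fixation; blocks are separated by a
#' 12-s rest. Catch trials (single stimulus plus a sex-judgment prompt)
#' are appended after the last trial of randomly chosen blocks; they are
#' flagged so analysis stages can drop them. The default design yields
#' 114 stimulus records per session (4 x 7 x 4 + 2).
#'
#' @param spec a \code{\link{designSpec}}.
#' @param modality \code{"face"} or \code{"voice"}.
#' @param seed RNG seed.
#' @param session session number recorded in the output.
#' @return data.frame with BIDS-style columns \code{onset},
#'   \code{duration}, \code{trial_type} plus \code{emotion}, \code{block},
#'   \code{trial}, \code{actor}, \code{modality}, \code{session},
#'   \code{catch}.
#' @export
genSessionDesign <- function(spec = designSpec(),
                             modality = c("face", "voice"), seed = 1L,
                             session = 1L) {
  stopifnot(inherits(spec, "DesignSpec"))
  modality <- match.arg(modality)
  tm <- spec$timings
  withSeed(seed, {
    catchBlocks <- if (spec$catchPerSession > 0)
      sort(sample(spec$blocksPerSession, spec$catchPerSession,
                  replace = spec$catchPerSession > spec$blocksPerSession))
    else integer(0)
    emoOrders <- lapply(seq_len(spec$blocksPerSession), function(b)
      sample(spec$emotions, spec$trialsPerBlock,
             replace = spec$trialsPerBlock > spec$nEmotions))
    actorPool <- seq_len(4L * spec$actorsPerTrial)
    actorSets <- lapply(seq_len(spec$blocksPerSession *
                                  spec$trialsPerBlock + spec$catchPerSession),
                        function(i) sample(actorPool, spec$actorsPerTrial))
    list(catchBlocks = catchBlocks, emoOrders = emoOrders,
         actorSets = actorSets)
  }) -> plan

  rows <- list()
  t <- 0; trialIdx <- 0; setIdx <- 0
  for (b in seq_len(spec$blocksPerSession)) {
    if (b > 1) t <- t + tm$blockRest
    for (k in seq_len(spec$trialsPerBlock)) {
      trialIdx <- trialIdx + 1; setIdx <- setIdx + 1
      emo <- plan$emoOrders[[b]][k]
      t <- t + tm$preFix
      for (a in seq_len(spec$actorsPerTrial)) {
        rows[[length(rows) + 1]] <- data.frame(
          onset = t, duration = tm$stim,
          trial_type = paste0(modality, "-", emo),
          emotion = emo, block = b, trial = trialIdx,
          actor = plan$actorSets[[setIdx]][a],
          modality = modality, session = session, catch = FALSE,
          stringsAsFactors = FALSE)
        t <- t + tm$stim
      }
      t <- t + tm$postFix
    }
    nCatchHere <- sum(plan$catchBlocks == b)
    for (ci in seq_len(nCatchHere)) {
      trialIdx <- trialIdx + 1; setIdx <- setIdx + 1
      t <- t + tm$preFix
      rows[[length(rows) + 1]] <- data.frame(
        onset = t, duration = tm$stim,
        trial_type = paste0(modality, "-catch"),
        emotion = NA_character_, block = b, trial = trialIdx,
        actor = plan$actorSets[[setIdx]][1],
        modality = modality, session = session, catch = TRUE,
        stringsAsFactors = FALSE)
      t <- t + tm$stim + tm$postFix
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
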