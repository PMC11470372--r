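test_that("rating-task generator enumerates blocks x words and is seeded", {
  d <- genRatingDesign(designSpec(), seed = 11)
  expect_equal(nrow(d), 280L)
  expect_equal(unname(table(d$emotion)), rep(40L, 7), ignore_attr = TRUE)
  expect_equal(nrow(genRatingDesign(designSpec(nEmotions = 1, nWords = 1,
                                               trialsPerBlock = 1))), 1L)
  expect_identical(genRatingDesign(seed = 5), genRatingDesign(seed = 5))
  expect_false(identical(genRatingDesign(seed = 5),
                         genRatingDesign(seed = 6)))
})

test_that("session generator yields the scanner trial structure", {
  s <- genSessionDesign(designSpec(), "face", seed = 2)
  expect_equal(nrow(s), 114L)
  expect_equal(sum(!s$catch), 112L)
  expect_equal(sum(s$catch), 2L)
  # catch-free enumeration
  s0 <- genSessionDesign(designSpec(catchPerSession = 0), "voice", seed = 2)
  expect_equal(nrow(s0), 112L)
  # each emotion appears once per block among real trials
  tab <- table(s$block[!s$catch], s$emotion[!s$catch])
  expect_true(all(tab == 4L))           # 4 actor records per emotion trial
  # onsets non-overlapping and strictly increasing
  expect_true(all(diff(s$onset) >= s$duration[-nrow(s)] - 1e-9))
  expect_true(all(diff(s$onset) > 0))
  expect_identical(genSessionDesign(seed = 9), genSessionDesign(seed = 9))
})

test_that("subject ratings carry the planted RDM and respect the scale", {
  wExact <- plantedWorld(idiosyncrasySd = 0, noiseSd = 0, seed = 4)
  r <- genSubjectRatings(wExact, 1, discretize = FALSE)
  emp <- rdmValues(rdmFromRatings(r))
  expect_lt(max(abs(emp - rdmValues(wExact$targetRdm))), 0.05)
  # discretized ratings stay on the 7-point scale and near the target
  ri <- genSubjectRatings(wExact, 1)
  expect_true(all(ri >= 1 & ri <= 7 & ri == round(ri)))
  expect_lt(max(abs(rdmValues(rdmFromRatings(ri)) -
                      rdmValues(wExact$targetRdm))), 0.35)
  # degenerate prototype: all rows perfectly correlated before rounding
  z <- DissimilarityMatrix(matrix(0, 7, 7),
                           labels = rdmLabels(wExact$targetRdm))
  wz <- plantedWorld(targetRdm = z, idiosyncrasySd = 0, noiseSd = 0)
  rz <- genSubjectRatings(wz, 1, discretize = FALSE)
  expect_lt(max(abs(cor(t(rz)) - 1)), 1e-10)
  # seeded determinism
  expect_identical(genSubjectRatings(plantedWorld(seed = 7), 3),
                   genSubjectRatings(plantedWorld(seed = 7), 3))
})

test_that("subject RDMs are valid correlation distances with jitter", {
  w <- plantedWorld(idiosyncrasySd = 0.25, seed = 12)
  for (s in 1:5) {
    ds <- rdmValues(subjectRdm(w, s))
    expect_true(isSymmetric(ds))
    ev <- eigen(1 - ds, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
    expect_true(all(ds >= 0 & ds <= 2))
  }
  expect_false(identical(rdmValues(subjectRdm(w, 1)),
                         rdmValues(subjectRdm(w, 2))))
})

test_that("non-PSD targets are rejected as planted worlds", {
  bad <- matrix(1.9, 3, 3); diag(bad) <- 0   # 1-d is far from PSD
  expect_error(plantedWorld(targetRdm = DissimilarityMatrix(bad),
                            gridShape = c(4, 4, 4)),
               "positive semidefinite")
})

test_that("confusion generator concentrates mass by dissimilarity", {
  r <- exampleEmotionRdm()
  cm <- genConfusions(r, temperature = 0.3, nTrialsPerEmotion = 50,
                      seed = 3)
  expect_equal(unname(rowSums(confusionCounts(cm))), rep(50, 7))
  # argmax limit: tiny temperature puts everything on the diagonal
  cold <- genConfusions(r, temperature = 1e-3, nTrialsPerEmotion = 50,
                        seed = 3)
  expect_equal(sum(diag(confusionCounts(cold))), 350)
  # constant off-diagonal distance: uniform off-diagonal expectation
  flat <- toyRdm(rep(0.8, 21), 7, type = "general")
  cf <- genConfusions(flat, temperature = 0.5,
                      nTrialsPerEmotion = 20000, seed = 5)
  off <- confusionCounts(cf)[row(confusionCounts(cf)) !=
                               col(confusionCounts(cf))]
  expect_lt(max(abs(off / 20000 - mean(off) / 20000)), 0.01)
  # planted monotone link: transformed confusion correlates positively
  big <- genConfusions(r, temperature = 0.4, nTrialsPerEmotion = 5000,
                       seed = 8)
  ct <- correlateUpperTriangles(
    DissimilarityMatrix(
      (rdmValues(confusionToDissimilarity(big)) +
         t(rdmValues(confusionToDissimilarity(big)))) / 2,
      labels = rdmLabels(r), type = "general"),
    r)
  expect_gt(ct$r, 0)
  expect_error(genConfusions(r, temperature = 0), "temperature")
})

test_that("beta volumes plant the subject RDM in the signal region", {
  w <- plantedWorld(idiosyncrasySd = 0.15, noiseSd = 0,
                    gridShape = c(8, 8, 8), seed = 21)
  rs <- subjectRdm(w, 4)
  bvs <- genBetaVolumes(w, rs, trialsPerEmotion = 3)
  flat <- matrix(betaArray(bvs), nrow = prod(w$gridShape))
  emo <- trialInfo(bvs)$emotion
  means <- sapply(rdmLabels(rs), function(e)
    rowMeans(flat[w$signalRegion, emo == e, drop = FALSE]))
  expect_lt(max(abs((1 - cor(means)) - rdmValues(rs))), 0.05)
  # outside the region: zero signal at zero noise
  expect_equal(max(abs(flat[-w$signalRegion, ])), 0)
  # whole-grid region with all-zero RDM: all emotion means identical
  z <- DissimilarityMatrix(matrix(0, 7, 7), labels = rdmLabels(rs))
  wz <- plantedWorld(targetRdm = z, idiosyncrasySd = 0, noiseSd = 0,
                     gridShape = c(4, 4, 4),
                     signalRegion = seq_len(64), seed = 2)
  bz <- genBetaVolumes(wz, z, 2)
  fz <- matrix(betaArray(bz), nrow = 64)
  mz <- sapply(rdmLabels(z), function(e)
    rowMeans(fz[, trialInfo(bz)$emotion == e, drop = FALSE]))
  expect_lt(max(abs(mz - mz[, 1])), 1e-10)
  # determinism and the tiny-region guard
  expect_identical(betaArray(genBetaVolumes(w, rs, 2, seed = 99)),
                   betaArray(genBetaVolumes(w, rs, 2, seed = 99)))
  wtiny <- plantedWorld(gridShape = c(4, 4, 4), signalRegion = 1:2)
  expect_error(genBetaVolumes(wtiny, rs, 2), "3 voxels")
})

test_that("forward BOLD model matches its building blocks", {
  ev <- data.frame(onset = c(5, 40), duration = 3)
  # zero amplitudes, zero noise: flat series
  b0 <- genBold(ev, c(0, 0), TR = 2, noiseSd = 0, dims = c(2, 1, 1))
  expect_equal(max(abs(b0)), 0)
  # a single unit trial equals the convolved boxcar for every voxel
  ev1 <- data.frame(onset = 5, duration = 3)
  b1 <- genBold(ev1, 1, TR = 2, noiseSd = 0, dims = c(2, 2, 1))
  series <- matrix(b1, 4, dim(b1)[4], byrow = FALSE)
  expect_equal(series[1, ], series[4, ])
  expect_gt(max(series[1, ]), 0)
  expect_equal(sum(abs(series[1, 1:2])), 0)  # nothing before onset
  expect_identical(genBold(ev, c(1, 2), TR = 2, seed = 3, noiseSd = 1),
                   genBold(ev, c(1, 2), TR = 2, seed = 3, noiseSd = 1))
  expect_error(genBold(ev, c(1, 2), TR = 0), "TR")
})

test_that("tone generator respects frequency and Nyquist", {
  w <- genTone(220, sr = 22050, duration = 1)
  expect_length(w, 22050)
  crossings <- sum(diff(sign(w)) != 0)
  expect_lt(abs(crossings - 2 * 220), 3)
  expect_error(genTone(22050 / 2, sr = 22050), "Nyquist")
})

test_that("noise calibration hits the requested recovery level", {
  w <- plantedWorld(idiosyncrasySd = 0.1, gridShape = c(6, 6, 6),
                    seed = 31)
  sd05 <- calibrateBetaNoise(w, trialsPerEmotion = 4, target = 0.5,
                             unit = "region", nRep = 8, seed = 2)
  w$noiseSd <- sd05
  rs <- vapply(1:12, function(s) {
    rdmS <- subjectRdm(w, s)
    bvs <- genBetaVolumes(w, rdmS, 4, seed = 1000 + s)
    flat <- matrix(betaArray(bvs), nrow = prod(w$gridShape))
    emo <- trialInfo(bvs)$emotion
    means <- sapply(rdmLabels(rdmS), function(e)
      rowMeans(flat[w$signalRegion, emo == e, drop = FALSE]))
    cor(upperTriangle(1 - cor(means)), upperTriangle(rdmValues(rdmS)))
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.5), 0.12)
})
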