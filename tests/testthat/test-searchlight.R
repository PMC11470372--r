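# exhaustive offset-enumeration oracle for sphere membership
sphereOracle <- function(center, dims, voxmm, radius) {
  g <- as.matrix(expand.grid(1:dims[1], 1:dims[2], 1:dims[3]))
  w <- sweep(g, 2, center) %*% diag(voxmm)
  g[sqrt(rowSums(w^2)) <= radius + 1e-9, , drop = FALSE]
}

test_that("searchlight membership matches exhaustive world-distance enumeration", {
  dims <- c(5, 5, 5)
  aff <- diag(c(3, 3, 3, 1))
  sl <- buildSearchlights(array(TRUE, dims), aff, radiusMm = 4)
  byCenter <- setNames(sl$searchlights,
                       sapply(sl$searchlights, function(s)
                         paste(s$center, collapse = ",")))
  # interior center: 7 members (face neighbors at 3 mm; diagonals excluded)
  int <- byCenter[["3,3,3"]]
  expect_equal(length(int$members), 7L)
  oracleIdx <- sort((sphereOracle(c(3, 3, 3), dims, c(3, 3, 3), 4) %*%
                       c(1, 5, 25) - 30)[, 1])
  expect_equal(int$members, oracleIdx)
  # corner is clipped
  expect_equal(length(byCenter[["1,1,1"]]$members), 4L)
  # anisotropic voxels honor world distance (3.3 x 3.3 x 3 mm)
  affA <- diag(c(3.3, 3.3, 3, 1))
  slA <- buildSearchlights(array(TRUE, dims), affA, radiusMm = 4)
  intA <- Filter(function(s) all(s$center == c(3, 3, 3)),
                 slA$searchlights)[[1]]
  oracleA <- sphereOracle(c(3, 3, 3), dims, c(3.3, 3.3, 3), 4)
  expect_equal(length(intA$members), nrow(oracleA))
  # tiny radius with minVoxels 1: singletons
  slT <- buildSearchlights(array(TRUE, dims), aff, radiusMm = 1,
                           minVoxels = 1)
  expect_true(all(sapply(slT$searchlights, function(s)
    length(s$members)) == 1L))
  # membership symmetry on the full cube
  memberSets <- lapply(sl$searchlights, `[[`, "members")
  names(memberSets) <- sapply(sl$searchlights, `[[`, "centerIndex")
  for (s in sl$searchlights[seq(1, 125, by = 17)])
    for (v in s$members)
      expect_true(s$centerIndex %in% memberSets[[as.character(v)]])
  expect_error(buildSearchlights(array(TRUE, dims), aff, radiusMm = 0),
               "radius")
})

test_that("centers below the member floor are dropped and recorded", {
  dims <- c(3, 3, 3)
  mask <- array(FALSE, dims); mask[2, 2, 2] <- TRUE; mask[1, 1, 1] <- TRUE
  sl <- buildSearchlights(mask, diag(c(3, 3, 3, 1)), radiusMm = 4,
                          minVoxels = 2)
  expect_equal(length(sl$searchlights), 0L)
  expect_setequal(sl$dropped, which(mask))
})

test_that("neural RDMs recover planted pattern geometry", {
  w <- plantedWorld(idiosyncrasySd = 0.12, noiseSd = 0,
                    gridShape = c(8, 8, 8), seed = 17)
  rs <- subjectRdm(w, 1)
  bvs <- genBetaVolumes(w, rs, trialsPerEmotion = 3)
  regionSl <- list(center = linearToVoxelTest(w$signalRegion[14],
                                              w$gridShape),
                   centerIndex = w$signalRegion[14],
                   members = w$signalRegion)
  nr <- neuralRdm(bvs, regionSl)
  expect_lt(max(abs(rdmValues(nr)[rdmLabels(rs), rdmLabels(rs)] -
                      rdmValues(rs))), 0.05)
  # identical mean patterns give distance 0
  flat <- matrix(betaArray(bvs), nrow = prod(w$gridShape))
  flat[, trialInfo(bvs)$emotion == "happy"] <-
    flat[, trialInfo(bvs)$emotion == "sad"][, 1]
  bvs2 <- BetaVolumeSet(array(flat, dim(betaArray(bvs))),
                        mask = volumeMask(bvs),
                        affine = volumeAffine(bvs),
                        trials = trialInfo(bvs))
  nr2 <- neuralRdm(bvs2, regionSl)
  expect_lt(abs(rdmValues(nr2)["happy", "sad"]), 1e-10)
})

test_that("RSA regression equals atanh of Pearson r for a single model", {
  set.seed(23)
  for (i in 1:8) {
    neural <- toyRdm(runif(21), 7)
    model <- toyRdm(runif(21), 7)
    b <- rsaRegress(neural, list(conceptual = model))
    r <- pearsonDirect(lowerTriangle(neural), lowerTriangle(model))
    expect_equal(unname(b), atanh(r), tolerance = 1e-10)
  }
  # identity regression clips at 1 - 1e-7 before atanh
  m <- toyRdm(runif(21), 7)
  expect_equal(unname(rsaRegress(m, list(m))), atanh(1 - 1e-7))
  # orthogonalized two-model case: coefficient of the inert model ~ 0
  set.seed(24)
  m1v <- scale(runif(21)); m2v <- scale(runif(21))
  m2v <- scale(resid(lm(m2v ~ m1v)))
  neural <- toyRdm(as.vector(m2v) - min(m2v) + 0.1, 7)
  b2 <- rsaRegress(neural, list(a = toyRdm(as.vector(m1v) - min(m1v) + 0.1, 7),
                                b = toyRdm(as.vector(m2v) - min(m2v) + 0.1, 7)))
  expect_lt(abs(b2[["a"]]), 1e-8)
  expect_gt(b2[["b"]], 3)
  expect_error(rsaRegress(toyRdm(rep(1, 21), 7), list(m)), "variance")
  expect_error(rsaRegress(m, list(m, m)), "collinear")
})

test_that("searchlight maps localize the planted region", {
  w <- plantedWorld(idiosyncrasySd = 0.1, noiseSd = 1.2,
                    gridShape = c(7, 7, 7), seed = 27)
  rs <- subjectRdm(w, 1)
  bvs <- genBetaVolumes(w, rs, trialsPerEmotion = 4)
  res <- runSearchlight(bvs, list(conceptual = rs), radiusMm = 4)
  co <- mapValues(modelMap(res, "conceptual"))
  inRegion <- mean(co[w$signalRegion], na.rm = TRUE)
  outRegion <- mean(co[-w$signalRegion], na.rm = TRUE)
  expect_gt(inRegion, outRegion + 0.2)
  # output grid matches input; centers defined everywhere on a full mask
  expect_equal(dim(co), w$gridShape)
  expect_true(all(validCenters(res)))
  # pure noise: map mean within 3 SE of zero
  wN <- plantedWorld(idiosyncrasySd = 0.1, noiseSd = 1,
                     gridShape = c(6, 6, 6), seed = 5)
  bN <- genBetaVolumes(wN, subjectRdm(wN, 2), 4, seed = 1234)
  zero <- array(0, dim(betaArray(bN)))
  zero[] <- withr::with_seed(7, rnorm(length(zero)))
  bNoise <- BetaVolumeSet(zero, mask = volumeMask(bN),
                          affine = volumeAffine(bN),
                          trials = trialInfo(bN))
  resN <- runSearchlight(bNoise, list(conceptual = subjectRdm(wN, 2)))
  cN <- mapValues(modelMap(resN, "conceptual"))
  se <- sd(cN, na.rm = TRUE) / sqrt(sum(!is.na(cN)))
  expect_lt(abs(mean(cN, na.rm = TRUE)), 3 * se + 0.02)
})

test_that("searchlight output is invariant to trial order and label permutation", {
  w <- plantedWorld(idiosyncrasySd = 0.1, noiseSd = 0.8,
                    gridShape = c(5, 5, 5), seed = 33)
  rs <- subjectRdm(w, 3)
  bvs <- genBetaVolumes(w, rs, 3)
  res1 <- runSearchlight(bvs, list(conceptual = rs))
  perm <- withr::with_seed(1, sample(dim(betaArray(bvs))[4]))
  bvsP <- BetaVolumeSet(betaArray(bvs)[, , , perm, drop = FALSE],
                        mask = volumeMask(bvs),
                        affine = volumeAffine(bvs),
                        trials = trialInfo(bvs)[perm, ])
  res2 <- runSearchlight(bvsP, list(conceptual = rs))
  expect_equal(res1@coefficients, res2@coefficients, tolerance = 1e-10)
  # permuting emotion labels consistently in RDM leaves maps unchanged
  lp <- withr::with_seed(2, sample(7))
  rsP <- DissimilarityMatrix(rdmValues(rs)[lp, lp],
                             labels = rdmLabels(rs)[lp])
  res3 <- runSearchlight(bvs, list(conceptual = rsP))
  expect_equal(res1@coefficients, res3@coefficients, tolerance = 1e-10)
})
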