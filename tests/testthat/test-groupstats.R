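test_that("group t map matches the hand-computed one-sample t", {
  # n = 4 values (1, 2, 3, 4): t = 2.5 / (1.29099/2)
  maps <- lapply(1:4, function(i) array(i, c(1, 1, 1)))
  tm <- groupTmap(maps)
  expect_equal(mapValues(tm)[1, 1, 1], 2.5 / (sd(1:4) / 2),
               tolerance = 1e-10)
  expect_equal(tm@df, 3)
  # zero-variance convention: identical maps give t = 0
  same <- lapply(1:4, function(i) array(5, c(2, 1, 1)))
  expect_equal(max(abs(mapValues(groupTmap(same)))), 0)
  # odd symmetry
  set.seed(3)
  rnd <- lapply(1:6, function(i) array(rnorm(8), c(2, 2, 2)))
  neg <- lapply(rnd, function(m) -m)
  expect_equal(mapValues(groupTmap(neg)), -mapValues(groupTmap(rnd)),
               tolerance = 1e-12)
  expect_error(groupTmap(rnd[1:2]), "3 subjects")
})

test_that("TFCE matches the analytic isolated-voxel integral", {
  v <- array(0, c(7, 7, 7))
  h <- 3.2
  v[4, 4, 4] <- h
  dh <- h / 100
  tf <- mapValues(tfce(v, dh = dh))
  # extent 1 at every threshold: sum h_k^2 dh approximates h^3/3
  expect_lt(abs(tf[4, 4, 4] - h^3 / 3), h^2 * dh * 2)
  riemann <- sum(((1:100) * dh)^2 * dh)
  expect_equal(tf[4, 4, 4], riemann, tolerance = 1e-10)
  expect_equal(sum(tf != 0), 1L)
  # all-zero map passes through as zeros
  expect_equal(max(abs(mapValues(tfce(array(0, c(3, 3, 3)))))), 0)
  expect_error(tfce(v, E = 0), "positive")
})

test_that("TFCE respects extent weighting and monotonicity", {
  # two equal-height voxels: connected pair doubles extent, e^0.5 scaling
  va <- array(0, c(5, 5, 5)); va[2, 2, 2] <- 1; va[4, 4, 4] <- 1
  vb <- array(0, c(5, 5, 5)); vb[2, 2, 2] <- 1; vb[2, 2, 3] <- 1
  dh <- 1 / 100
  ta <- mapValues(tfce(va, dh = dh))[2, 2, 2]
  tb <- mapValues(tfce(vb, dh = dh))[2, 2, 2]
  expect_equal(tb / ta, sqrt(2), tolerance = 1e-10)
  # scaling the map raises every positive output
  v <- array(0, c(4, 4, 4)); v[2, 2, 2] <- 1; v[3, 3, 3] <- 0.5
  t1 <- mapValues(tfce(v))
  t2 <- mapValues(tfce(2 * v))
  expect_true(all(t2[v > 0] > t1[v > 0]))
  # with E -> 0 and H = 1 the enhancement approaches the analytic
  # integral of h over [0, x], i.e. x^2 / 2 at every positive voxel
  vr <- array(runif(27), c(3, 3, 3))
  tl <- mapValues(tfce(vr, E = 1e-9, H = 1, dh = max(vr) / 4000))
  expect_lt(max(abs(tl - vr^2 / 2)), max(vr) / 1000)
  # connectivity: 6 vs 26 for a diagonal pair
  vd <- array(0, c(3, 3, 3)); vd[1, 1, 1] <- 1; vd[2, 2, 2] <- 1
  t6 <- mapValues(tfce(vd, connectivity = 6))[1, 1, 1]
  t26 <- mapValues(tfce(vd, connectivity = 26))[1, 1, 1]
  expect_gt(t26, t6)
})

test_that("sign permutation control: p floor, monotonicity, one-sidedness", {
  set.seed(11)
  maps <- lapply(1:8, function(i) {
    m <- array(rnorm(64), c(4, 4, 4))
    m[2, 2, 2] <- m[2, 2, 2] + 4      # strong planted voxel
    m
  })
  pr <- signPermutationTest(maps, nPerm = 256, seed = 4)  # enumerated
  expect_equal(pr@nPerm, 256L)
  p <- mapValues(correctedP(pr))
  expect_gte(min(p), 1 / 257)
  # corrected p monotone non-increasing in the observed TFCE statistic
  o <- order(mapValues(pr@observedTfce))
  expect_true(all(diff(p[o]) <= 1e-12))
  # z cap at the permutation resolution
  expect_lte(max(mapValues(zMap(pr))), qnorm(1 - 1 / 257) + 1e-12)
  # planted voxel found, flipped signs kill it
  expect_true(significantVoxels(pr)[2, 2, 2])
  prNeg <- signPermutationTest(lapply(maps, function(m) -m),
                               nPerm = 256, seed = 4)
  expect_gt(mapValues(correctedP(prNeg))[2, 2, 2], 0.5)
  expect_false(any(significantVoxels(prNeg)))
  expect_error(signPermutationTest(maps[1:3]), "5 subjects")
  expect_warning(signPermutationTest(maps, nPerm = 50, seed = 1),
                 "100 permutations")
})

test_that("full enumeration triggers when 2^n fits in nPerm", {
  set.seed(12)
  maps <- lapply(1:6, function(i) array(rnorm(27), c(3, 3, 3)))
  pr1 <- suppressWarnings(signPermutationTest(maps, nPerm = 64, seed = 1))
  pr2 <- suppressWarnings(signPermutationTest(maps, nPerm = 64, seed = 99))
  # seed-independent when enumerated
  expect_equal(nullMaxima(pr1), nullMaxima(pr2))
  expect_equal(pr1@nPerm, 64L)
})

test_that("sign permutation is deterministic under a seed and honors masks", {
  set.seed(13)
  maps <- lapply(1:9, function(i) array(rnorm(64), c(4, 4, 4)))
  pr1 <- signPermutationTest(maps, nPerm = 200, seed = 7)
  pr2 <- signPermutationTest(maps, nPerm = 200, seed = 7)
  expect_equal(nullMaxima(pr1), nullMaxima(pr2))
  mask <- array(FALSE, c(4, 4, 4)); mask[1:2, , ] <- TRUE
  prM <- signPermutationTest(maps, nPerm = 200, seed = 7, mask = mask)
  expect_equal(max(mapValues(prM@observedTfce)[!mask]), 0)
  expect_true(all(mapValues(correctedP(prM))[!mask] == 1))
})

test_that("voxelwise repeated-measures F matches aov and its null moment", {
  set.seed(17)
  n <- 6; cc <- 7; V <- 4
  arr <- array(rnorm(n * cc * V), c(n, cc, V))
  fm <- voxelwiseEmotionF(arr)
  expect_equal(fm@df, c(6, 30))
  # oracle: aov with subject blocking factor
  for (v in 1:V) {
    d <- data.frame(y = as.vector(arr[, , v]),
                    subj = factor(rep(1:n, cc)),
                    cond = factor(rep(1:cc, each = n)))
    ref <- summary(aov(y ~ cond + Error(subj), d))
    Fref <- ref[["Error: Within"]][[1]]["cond", "F value"]
    expect_equal(mapValues(fm)[v, 1, 1], Fref, tolerance = 1e-10)
  }
  # null mean of F is df2/(df2 - 2)
  set.seed(18)
  nullF <- replicate(400, {
    a <- array(rnorm(4 * 7), c(4, 7, 1))
    mapValues(voxelwiseEmotionF(a))[1, 1, 1]
  })
  df2 <- 6 * 3
  expect_lt(abs(mean(nullF) - df2 / (df2 - 2)),
            4 * sd(nullF) / sqrt(400))
  # planted condition offset dominates
  arr2 <- arr
  arr2[, 3, ] <- arr2[, 3, ] + 10
  expect_gt(min(mapValues(voxelwiseEmotionF(arr2))),
            qf(0.999, 6, 30))
  # null F distribution invariant to a shared condition relabeling
  perm <- sample(7)
  expect_equal(mapValues(voxelwiseEmotionF(arr[, perm, , drop = FALSE])),
               mapValues(voxelwiseEmotionF(arr)), tolerance = 1e-10)
})

test_that("minimum-statistic conjunction intersects significance", {
  a <- StatMap(array(c(3.1, 0.2, 2.0, 5.0), c(4, 1, 1)), "z")
  b <- StatMap(array(c(2.4, 4.0, 1.0, 5.5), c(4, 1, 1)), "z")
  cj <- conjunctionMin(a, b, threshold = 1.65)
  expect_equal(as.vector(mapValues(cj$min)), c(2.4, 0.2, 1.0, 5.0))
  expect_equal(as.vector(cj$mask), c(TRUE, FALSE, FALSE, TRUE))
  # idempotence
  cj2 <- conjunctionMin(a, a, threshold = 1.65)
  expect_equal(mapValues(cj2$min), mapValues(a))
  expect_equal(as.vector(cj2$mask), as.vector(mapValues(a) >= 1.65))
  # disjoint significant sets conjoin to nothing
  hi <- StatMap(array(c(9, 0, 9, 0), c(4, 1, 1)), "z")
  lo <- StatMap(array(c(0, 9, 0, 9), c(4, 1, 1)), "z")
  expect_false(any(conjunctionMin(hi, lo, 1.65)$mask))
  f <- StatMap(array(1, c(4, 1, 1)), "F")
  expect_error(conjunctionMin(a, f, 1.65), "kind")
})
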