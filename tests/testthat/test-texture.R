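test_that("direction encoding maps jet-relative angle linearly to gray", {
  dom <- cubeDomain(c(5, 5, 5))
  mk <- function(vec) {
    f <- array(0, c(5, 5, 5, 3))
    for (k in 1:3) f[, , , k] <- vec[k]
    flowFromFrames(list(f, f), dom)
  }
  jet <- c(0, 0, 1)
  expect_true(all(encodeDirection(mk(c(0, 0, 40)), jet)@gray == 0))
  expect_true(all(encodeDirection(mk(c(0, 0, -40)), jet)@gray == 255))
  gvPerp <- encodeDirection(mk(c(30, 0, 0)), jet)
  expect_true(all(gvPerp@gray == 128))           # round-half-up of 127.5
  expect_error(encodeDirection(mk(c(0, 0, 1e-9)), jet), "stagnant")
})

test_that("jet estimation recovers the inflow direction", {
  dom <- makeDomain(3, 1.5, 0.3)
  fs <- makeFlowSeries(dom, nFrames = 3, noiseSd = 0, seed = 1,
                       vortices = list(),
                       jet = list(direction = c(0, 0, 1), peakSpeed = 100))
  expect_equal(estimateJetDirection(fs), c(0, 0, 1), tolerance = 1e-9)
  rev <- flowFromFrames(lapply(fs@frames, function(f) -f), dom)
  expect_equal(estimateJetDirection(rev), c(0, 0, -1), tolerance = 1e-9)
  fsN <- makeFlowSeries(dom, nFrames = 3, noiseSd = 3, seed = 5,
                        vortices = list(),
                        jet = list(direction = c(0, 0, 1), peakSpeed = 100))
  ang <- acos(sum(estimateJetDirection(fsN) * c(0, 0, 1)))
  expect_lt(ang, 5 * pi / 180)
  zero <- flowFromFrames(list(array(0, c(dim(sacMask(dom)), 3)),
                              array(0, c(dim(sacMask(dom)), 3))), dom)
  expect_error(estimateJetDirection(zero), "zero-velocity")
})

test_that("quantization bins the gray range into labelled levels", {
  d <- c(4, 4, 4)
  gray <- array(0L, d); gray[1] <- 255L; gray[2] <- 127L
  gv <- new("GrayVolume", gray = gray, mask = array(TRUE, d),
            levels = array(0L, d), nLevels = 0L)
  q <- quantizeGray(gv, 16)
  expect_equal(q@levels[1], 16L)
  expect_equal(q@levels[3], 1L)       # gray 0 -> level 1
  q256 <- quantizeGray(gv, 256)
  expect_true(all(q256@levels[q256@mask] == q256@gray[q256@mask] + 1L))
  expect_error(quantizeGray(gv, 1), "nLevels")
  expect_error(quantizeGray(gv, 300), "nLevels")
  # near-uniform levels for uniform random grays
  set.seed(2)
  gray2 <- array(sample(0:255, 4096, replace = TRUE), c(16, 16, 16))
  gv2 <- quantizeGray(new("GrayVolume", gray = gray2,
                          mask = array(TRUE, c(16, 16, 16)),
                          levels = array(0L, c(16, 16, 16)), nLevels = 0L), 8)
  cnt <- tabulate(gv2@levels, 8)
  expect_gt(suppressWarnings(chisq.test(cnt)$p.value), 0.001)
})

test_that("first-order features handle constant and symmetric volumes", {
  gv <- constantGrayVolume(57)
  expect_message(f <- firstOrderFeatures(gv), "constant")
  expect_equal(unname(f["FirstOrder.Mean"]), 57)
  expect_equal(unname(f["FirstOrder.Range"]), 0)
  expect_equal(unname(f["FirstOrder.Entropy"]), 0)
  expect_equal(unname(f["FirstOrder.Uniformity"]), 1)
  expect_equal(unname(f["FirstOrder.Skewness"]), 0)
  d <- c(4, 5, 1)
  gray <- array(c(rep(0L, 10), rep(255L, 10)), d)
  gv2 <- new("GrayVolume", gray = gray, mask = array(TRUE, d),
             levels = array(0L, d), nLevels = 0L)
  f2 <- firstOrderFeatures(gv2)
  expect_equal(unname(f2["FirstOrder.Mean"]), 127.5)
  expect_equal(unname(f2["FirstOrder.Skewness"]), 0)
  expect_error(firstOrderFeatures(constantGrayVolume(1, d = c(2, 2, 2))),
               "at least 10")
})

test_that("GLCM features: constant volume and hand-enumerated checkerboard", {
  f <- suppressMessages(glcmFeatures(constantGrayVolume(200)))
  expect_equal(unname(f["GLCM.JointEnergy"]), 1)
  expect_equal(unname(f["GLCM.JointEntropy"]), 0)
  expect_equal(unname(f["GLCM.DifferenceAverage"]), 0)
  expect_equal(length(f), 24)
  # 2x2x1 checkerboard of levels {1, 2}
  d <- c(2, 2, 1)
  gray <- array(c(0L, 255L, 255L, 0L), d)
  gv <- quantizeGray(new("GrayVolume", gray = gray, mask = array(TRUE, d),
                         levels = array(0L, d), nLevels = 0L), 2)
  got <- glcmFeatures(gv)
  want <- oracleGlcm(gv@levels, 2)
  expect_equal(got, want[names(got)], tolerance = 1e-12)
  # hand check: x and y directions see only (1,2) pairs; diagonals see equal
  # pairs; Contrast is the direction average of 1, 1, 0, 0 over 4 directions
  expect_equal(unname(got["GLCM.Contrast"]), mean(c(1, 1, 0, 0)))
})

test_that("GLRLM features: single runs and alternating levels", {
  L <- 6
  lev <- array(3L, c(L, 1, 1))
  R <- sacflow:::glrlmCounts(lev, c(1, 0, 0), 4)
  f <- sacflow:::glrlmFromMatrix(R, L)
  expect_equal(unname(f["GLRLM.LongRunEmphasis"]), L^2)
  expect_equal(sum(R), 1)
  levAlt <- array(rep(c(1L, 2L), 3), c(L, 1, 1))
  fAlt <- sacflow:::glrlmFromMatrix(
    sacflow:::glrlmCounts(levAlt, c(1, 0, 0), 2), L)
  expect_equal(unname(fAlt["GLRLM.ShortRunEmphasis"]), 1)
  expect_equal(unname(fAlt["GLRLM.RunPercentage"]), 1)
})

test_that("GLSZM features: zone counts of constant and two-blob volumes", {
  d <- c(3, 4, 3)
  f <- suppressMessages(glszmFeatures(constantGrayVolume(100, d = d)))
  expect_equal(unname(f["GLSZM.ZonePercentage"]), 1 / prod(d))
  # two disjoint equal-level blobs -> 2 zones
  gray <- array(0L, c(5, 5, 1))
  gray[1:2, 1:2, 1] <- 200L
  gray[4:5, 4:5, 1] <- 200L
  mask <- gray > 0
  mask[3, 3, 1] <- TRUE; gray[3, 3, 1] <- 0L  # lone background voxel
  gv <- quantizeGray(new("GrayVolume", gray = gray, mask = mask,
                         levels = array(0L, dim(gray)), nLevels = 0L), 4)
  f2 <- glszmFeatures(gv)
  expect_equal(unname(f2["GLSZM.ZonePercentage"]), 3 / 9)  # 2 blobs + 1 voxel
})

test_that("matrix features match brute-force oracles on random volumes", {
  for (seed in 1:12) {
    gv <- randomGrayVolume(seed)
    lev <- gv@levels; ng <- gv@nLevels; np <- sum(gv@mask)
    expect_equal(glcmFeatures(gv), oracleGlcm(lev, ng)[names(glcmFeatures(gv))],
                 tolerance = 1e-10)
    expect_equal(glrlmFeatures(gv), oracleGlrlm(lev, ng, np),
                 tolerance = 1e-10)
    expect_equal(glszmFeatures(gv), oracleGlszm(lev, ng, np),
                 tolerance = 1e-10)
    expect_equal(firstOrderFeatures(gv),
                 oracleFirstOrder(as.numeric(gv@gray[gv@mask])),
                 tolerance = 1e-10)
  }
})

test_that("directional matrices are normalized and symmetric", {
  gv <- randomGrayVolume(99)
  for (k in 1:13) {
    C <- sacflow:::glcmCounts(gv@levels, sacflow:::.directions13[k, ],
                              gv@nLevels)
    if (sum(C) == 0) next
    P <- C / sum(C)
    expect_equal(sum(P), 1)
    expect_equal(P, t(P))
  }
})

test_that("matrix features are invariant under 90-degree lattice rotation", {
  gv <- randomGrayVolume(7)
  rot <- function(a) aperm(a[, dim(a)[2]:1, , drop = FALSE], c(2, 1, 3))
  gvR <- new("GrayVolume", gray = rot(gv@gray), mask = rot(gv@mask),
             levels = rot(gv@levels), nLevels = gv@nLevels)
  expect_equal(glcmFeatures(gv), glcmFeatures(gvR), tolerance = 1e-12)
  expect_equal(glrlmFeatures(gv), glrlmFeatures(gvR), tolerance = 1e-12)
  expect_equal(glszmFeatures(gv), glszmFeatures(gvR), tolerance = 1e-12)
})

test_that("the full extractor yields 74 deterministic named features", {
  dom <- makeDomain(3, 1.5, 0.4)
  fs <- makeFlowSeries(dom, nFrames = 4, noiseSd = 8, seed = 6,
                       jet = list(direction = c(0, 0, 1), peakSpeed = 60))
  fv <- velocityFeatures(fs, nLevels = 8)
  expect_identical(names(fv), velocityFeatureNames())
  expect_equal(length(fv), 74L)
  expect_true(all(is.finite(fv)))
  expect_identical(fv, velocityFeatures(fs, nLevels = 8))
  fvAvg <- velocityFeatures(fs, nLevels = 8, frameMode = "per_frame")
  expect_identical(names(fvAvg), velocityFeatureNames())
})
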