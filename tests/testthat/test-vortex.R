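rigidRotationFrame <- function(d, sp, omega) {
  xs <- (seq_len(d[1]) - (d[1] + 1) / 2) * sp
  v <- array(0, c(d, 3))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    v[i, j, , 1] <- -omega * xs[j]
    v[i, j, , 2] <- omega * xs[i]
  }
  v
}

test_that("lambda2 closed forms: rigid rotation and simple shear", {
  d <- c(9, 9, 9); sp <- 0.4
  v <- rigidRotationFrame(d, sp, omega = 2.5)
  l2 <- lambda2Field(v, sp)
  expect_equal(l2[2:8, 2:8, 2:8], array(-2.5^2, c(7, 7, 7)), tolerance = 1e-6)
  xs <- (1:9 - 5) * sp
  shear <- array(0, c(d, 3))
  for (j in 1:9) shear[, j, , 1] <- 1.7 * xs[j]
  expect_equal(lambda2Field(shear, sp)[2:8, 2:8, 2:8],
               array(0, c(7, 7, 7)), tolerance = 1e-6)
  expect_error(lambda2Field(array(NaN, c(d, 3)), sp), "finite")
})

test_that("a Lamb-Oseen core has negative lambda2 inside its radius", {
  dom <- makeDomain(3, 1.5, 0.3)
  fs <- makeFlowSeries(dom, nFrames = 2, noiseSd = 0, seed = 1)
  l2 <- lambda2Field(fs@frames[[1]], dom@spacing)
  ctr <- sacCentroid(dom)
  co <- sacflow:::domainCoords(dom)
  ci <- c(which.min(abs(co$x - ctr[1])), which.min(abs(co$y - ctr[2])),
          which.min(abs(co$z - ctr[3])))
  # voxels near the core axis all swirl
  for (dx in -2:2) for (dy in -2:2)
    expect_lt(l2[ci[1] + dx, ci[2] + dy, ci[3]], 0)
})

test_that("lambda2 and vortex masks are Galilean invariant", {
  d <- c(8, 8, 8); sp <- 0.5
  set.seed(4)
  v <- array(rnorm(prod(d) * 3, sd = 10), c(d, 3))
  l2 <- lambda2Field(v, sp)
  vShift <- v
  vShift[, , , 1] <- vShift[, , , 1] + 37
  vShift[, , , 3] <- vShift[, , , 3] - 12
  expect_equal(lambda2Field(vShift, sp), l2, tolerance = 1e-9)
})

test_that("vortex masks: jets give none, rotation fills the sac interior", {
  dom <- makeDomain(3, 1.5, 0.3)
  d <- dim(sacMask(dom))
  uniform <- array(0, c(d, 3)); uniform[, , , 3] <- 100
  fs <- flowFromFrames(list(uniform, uniform), dom)
  vs <- extractVortexMask(fs)
  expect_true(all(!vapply(vs@masks, any, logical(1))))
  # rigid rotation over the whole grid: nearly every sac voxel swirls
  rot <- rigidRotationFrame(d, dom@spacing, 3)
  fsR <- flowFromFrames(list(rot, rot), dom)
  vsR <- extractVortexMask(fsR)
  expect_gt(mean(vsR@masks[[1]][sacMask(dom)]), 0.95)
})

test_that("two separated cores survive as two components", {
  dom <- makeDomain(4, 2, 0.4)
  fs <- makeFlowSeries(dom, nFrames = 2, noiseSd = 0, seed = 1,
                       vortices = list(
                         list(center = c(-1.8, 0, 1.5), coreRadius = 0.9,
                              circulation = 1500),
                         list(center = c(1.8, 0, 1.5), coreRadius = 0.9,
                              circulation = 1500)))
  vs <- extractVortexMask(fs, minVoxels = 8)
  labs <- sacflow:::labelComponents3d(vs@masks[[1]], 26)
  expect_gte(max(labs), 2)
})

test_that("DVO trivial values and conventions", {
  d <- c(4, 4, 4)
  m1 <- array(FALSE, d); m1[1:2, 1:2, 1:2] <- TRUE
  m2 <- array(FALSE, d); m2[3:4, 3:4, 3:4] <- TRUE
  mk <- function(masks) new("VortexSeries", masks = masks,
                            lambda2 = lapply(masks, function(m) array(0, d)),
                            threshold = 0)
  expect_equal(dvo(mk(list(m1, m1, m1))), 1)
  expect_equal(dvo(mk(list(m1, m2))), 0)
  # |A| = |B| = 8, |A n B| = 4 every cyclic pair
  m3 <- array(FALSE, d); m3[1:2, 1:2, 2:3] <- TRUE  # shifted by 1 in z
  expect_equal(sum(m1), 8); expect_equal(sum(m3), 8)
  expect_equal(sum(m1 & m3), 4)
  expect_equal(dvo(mk(list(m1, m3))), 0.5)
  # empty conventions
  e <- array(FALSE, d)
  expect_equal(dvo(mk(list(e, e))), 1)
  expect_equal(dvo(mk(list(m1, e))), 0)
  # translation applied to every frame leaves DVO unchanged
  t1 <- array(FALSE, d); t1[2:3, 2:3, 2:3] <- TRUE
  t2 <- array(FALSE, d); t2[2:3, 2:3, 3:4] <- TRUE
  s1 <- array(FALSE, d); s1[1:2, 2:3, 2:3] <- TRUE
  s2 <- array(FALSE, d); s2[1:2, 2:3, 3:4] <- TRUE
  expect_equal(dvo(mk(list(t1, t2))), dvo(mk(list(s1, s2))))
  # reference mode compares against the union
  expect_equal(dvo(mk(list(m1, m1)), mode = "reference"), 1)
})

test_that("vortex volume fraction is the time-averaged mask share", {
  dom <- makeDomain(3, 1.5, 0.4)
  sac <- sacMask(dom)
  full <- sac
  empty <- array(FALSE, dim(sac))
  mk <- function(masks) new("VortexSeries", masks = masks,
                            lambda2 = lapply(masks, function(m) array(0, dim(sac))),
                            threshold = 0)
  expect_equal(vortexVolumeFraction(mk(list(full, full)), dom), 1)
  expect_equal(vortexVolumeFraction(mk(list(empty, empty)), dom), 0)
  expect_equal(vortexVolumeFraction(mk(list(full, empty)), dom), 0.5)
})

test_that("DVO and Vt/V stay within [0, 1] on random masks", {
  d <- c(5, 5, 5)
  for (seed in 1:20) {
    set.seed(seed)
    masks <- lapply(1:4, function(i) array(runif(prod(d)) < 0.3, d))
    vs <- new("VortexSeries", masks = masks,
              lambda2 = lapply(masks, function(m) array(0, d)), threshold = 0)
    x <- dvo(vs)
    expect_true(x >= 0 && x <= 1)
  }
})
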