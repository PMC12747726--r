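test_that("TAWSS of constant and direction-flipping fields", {
  # constant |tau| = 2 Pa along x
  tau <- array(0, c(4, 3, 6)); tau[, 1, ] <- 2
  expect_equal(tawssField(wsFromTau(tau)), rep(2, 4))
  # alternating +/- x with |tau| = 1: magnitude average ignores direction
  tau2 <- array(0, c(4, 3, 6))
  tau2[, 1, ] <- matrix(rep(c(1, -1), 3), 4, 6, byrow = TRUE)
  expect_equal(tawssField(wsFromTau(tau2)), rep(1, 4))
})

test_that("scalar WSS summary matches hand values", {
  tau <- array(0, c(2, 3, 4))
  tau[1, 1, ] <- 1; tau[2, 1, ] <- 3
  s <- wssSummary(wsFromTau(tau))
  expect_equal(s$staWss, 2)
  expect_equal(s$wssMax, 3)
  expect_equal(s$wssMin, 1)
  # uniform 2 Pa
  tauU <- array(0, c(3, 3, 4)); tauU[, 2, ] <- 2
  sU <- wssSummary(wsFromTau(tauU))
  expect_equal(c(sU$staWss, sU$wssMax, sU$wssMin), c(2, 2, 2))
  # global-min strategy option
  tauG <- tau; tauG[2, 1, 3] <- 0.5
  expect_equal(wssSummary(wsFromTau(tauG), minMode = "global_min")$wssMin, 0.5)
})

test_that("OSI identities: steady, reversing, and orthogonal rotation", {
  tau <- array(0, c(3, 3, 5)); tau[, 1, ] <- 2
  expect_equal(osiField(wsFromTau(tau)), rep(0, 3))
  # balanced exact reversal
  tau2 <- array(0, c(2, 3, 4))
  tau2[, 1, ] <- matrix(c(1, 1, -1, -1), 2, 4, byrow = TRUE)
  expect_equal(osiField(wsFromTau(tau2)), rep(0.5, 2))
  # two equal-duration frames (1,0,0) then (0,1,0): 0.5 (1 - sqrt(2)/2)
  tau3 <- array(0, c(1, 3, 2))
  tau3[1, 1, 1] <- 1; tau3[1, 2, 2] <- 1
  expect_equal(osiField(wsFromTau(tau3)), 0.5 * (1 - sqrt(2) / 2))
  # all-zero node defined as 0
  tau4 <- array(0, c(2, 3, 3)); tau4[1, 1, ] <- 1
  expect_equal(osiField(wsFromTau(tau4))[2], 0)
})

test_that("RRT closed forms and consistency with OSI and TAWSS", {
  tau <- array(0, c(2, 3, 4)); tau[, 1, ] <- 2
  expect_equal(rrtField(wsFromTau(tau)), rep(0.5, 2))
  ws <- randomWallShear(21)
  expect_equal(rrtField(ws),
               1 / ((1 - 2 * osiField(ws)) * tawssField(ws)))
})

test_that("LSA uses a strict 2 Pa boundary and area weights", {
  tau <- array(0, c(2, 3, 3)); tau[, 1, ] <- 1
  expect_equal(lsa(wsFromTau(tau)), 100)
  tau2 <- array(0, c(2, 3, 3)); tau2[1, 1, ] <- 1; tau2[2, 1, ] <- 3
  expect_equal(lsa(wsFromTau(tau2)), 50)
  tauB <- array(0, c(1, 3, 3)); tauB[1, 1, ] <- 2
  expect_equal(lsa(wsFromTau(tauB)), 0)        # exactly 2 Pa is excluded
  # area weighting
  tau3 <- array(0, c(2, 3, 3)); tau3[1, 1, ] <- 1; tau3[2, 1, ] <- 3
  expect_equal(lsa(wsFromTau(tau3, areas = c(3, 1))), 75)
  expect_error(lsa(wsFromTau(tau3), threshold = 0), "positive")
})

test_that("random series match the loop-based trapezoid oracle", {
  for (seed in c(5, 17, 33)) {
    ws <- randomWallShear(seed)
    mags <- sqrt(ws@tau[, 1, ]^2 + ws@tau[, 2, ]^2 + ws@tau[, 3, ]^2)
    n <- dim(ws@tau)[1]
    tawssOracle <- vapply(seq_len(n), function(i)
      trapCyclic(mags[i, ], ws@times, ws@period) / ws@period, numeric(1))
    expect_equal(tawssField(ws), tawssOracle)
    osiOracle <- vapply(seq_len(n), function(i) {
      num <- sqrt(sum(vapply(1:3, function(cc)
        trapCyclic(ws@tau[i, cc, ], ws@times, ws@period), numeric(1))^2))
      den <- trapCyclic(mags[i, ], ws@times, ws@period)
      0.5 * (1 - num / den)
    }, numeric(1))
    expect_equal(osiField(ws), osiOracle)
    aw <- ws@areas / sum(ws@areas)
    expect_equal(wssSummary(ws)$staWss, sum(tawssOracle * aw))
  }
})

test_that("OSI stays in [0, 0.5] and metrics scale as expected", {
  for (seed in 1:50) {
    ws <- randomWallShear(seed, nNodes = 6, nFrames = 5)
    osi <- osiField(ws)
    expect_true(all(osi >= 0 & osi <= 0.5))
  }
  ws <- randomWallShear(77)
  c <- 3.7
  wsScaled <- wsFromTau(ws@tau * c, areas = ws@areas)
  expect_equal(osiField(wsScaled), osiField(ws))
  expect_equal(tawssField(wsScaled), c * tawssField(ws))
  expect_equal(rrtField(wsScaled), rrtField(ws) / c)
  tw <- tawssField(ws)
  expect_equal(lsa(wsScaled, threshold = 2 * c), lsa(ws, threshold = 2))
})

test_that("shape mismatches are rejected", {
  expect_error(new("WallShearSeries", tau = array(0, c(2, 3, 3)),
                   areas = c(1, 1, 1), times = c(0, 0.5, 1) / 1.5,
                   period = 1))
  expect_error(wsFromTau(array(NA_real_, c(2, 3, 3))))
})
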