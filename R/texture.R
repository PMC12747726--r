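# Directional velocity informatics: encode the angle between local velocity
# and the inflow-jet direction as a gray-level volume, then extract the 74
# texture features (18 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM). Feature
# formulas follow the IBSI reference definitions; matrix features use
# symmetric distance-1 matrices over the 13 unique 3-D directions, averaged.

.firstOrderNames <- paste0("FirstOrder.", c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
  "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
  "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
  "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity"))

.glcmNames <- paste0("GLCM.", c(
  "Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
  "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
  "DifferenceEntropy", "DifferenceVariance", "JointEnergy", "JointEntropy",
  "IMC1", "IMC2", "Idm", "Idmn", "Id", "Idn", "InverseVariance",
  "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares", "MCC"))

.glrlmNames <- paste0("GLRLM.", c(
  "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LongRunHighGrayLevelEmphasis"))

.glszmNames <- paste0("GLSZM.", c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LargeAreaHighGrayLevelEmphasis"))

# the 13 unique 3-D lattice directions at distance 1
.directions13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

#' Names of the 74 velocity-informatics features
#'
#' Stable column order: 18 `FirstOrder.*`, 24 `GLCM.*`, 16 `GLRLM.*`,
#' 16 `GLSZM.*`.
#'
#' @return character vector of length 74.
#' @export
velocityFeatureNames <- function() {
  c(.firstOrderNames, .glcmNames, .glrlmNames, .glszmNames)
}

#' Estimate the inflow-jet direction
#'
#' Averages the velocity over sac voxels adjacent to the ostium plane
#' (within one voxel of the plane) at the peak-speed frame and normalizes
#' it. If the net flux through the ostium neighbourhood is (near) zero, the
#' mean velocity direction over the whole sac is used instead.
#'
#' @param series a [FlowSeries-class].
#' @param domain the domain (defaults to the series' own).
#' @return unit 3-vector.
#' @export
estimateJetDirection <- function(series, domain = flowDomain(series)) {
  sac <- domain@sacMask
  speeds <- vapply(series@frames, function(f) {
    mean(sqrt(f[, , , 1]^2 + f[, , , 2]^2 + f[, , , 3]^2)[sac])
  }, numeric(1))
  if (max(speeds) <= 0) stop("zero-velocity series: no jet direction")
  fr <- series@frames[[which.max(speeds)]]
  coords <- domainCoords(domain)
  d <- dim(sac)
  gx <- array(coords$x, d)
  gy <- aperm(array(coords$y, d[c(2, 1, 3)]), c(2, 1, 3))
  gz <- aperm(array(coords$z, d[c(3, 1, 2)]), c(2, 3, 1))
  dist <- (gx - domain@ostiumPoint[1]) * domain@ostiumNormal[1] +
          (gy - domain@ostiumPoint[2]) * domain@ostiumNormal[2] +
          (gz - domain@ostiumPoint[3]) * domain@ostiumNormal[3]
  near <- sac & abs(dist) <= domain@spacing
  pick <- if (any(near)) near else sac
  v <- c(mean(array(fr[, , , 1], d)[pick]),
         mean(array(fr[, , , 2], d)[pick]),
         mean(array(fr[, , , 3], d)[pick]))
  if (sqrt(sum(v^2)) < 1e-9) {
    v <- c(mean(array(fr[, , , 1], d)[sac]),
           mean(array(fr[, , , 2], d)[sac]),
           mean(array(fr[, , , 3], d)[sac]))
    if (sqrt(sum(v^2)) < 1e-9) stop("no net flow direction in sac")
  }
  v / sqrt(sum(v^2))
}

#' Encode velocity direction relative to the jet as gray levels
#'
#' Per voxel, the angle theta between the voxel velocity and the jet
#' direction (in `[0, pi]`) is mapped linearly to gray =
#' `round(255 * theta / pi)` with half-up rounding: velocity parallel to the
#' jet gives gray 0, anti-parallel 255, perpendicular 128. Voxels whose
#' speed falls below `vFloor` are excluded from the mask.
#'
#' @param series a [FlowSeries-class].
#' @param jet unit 3-vector (see [estimateJetDirection()]).
#' @param frame frame index; defaults to the peak-speed frame.
#' @param vFloor minimum speed, mm/s (default 1e-6).
#' @return A [GrayVolume-class] (unquantized).
#' @export
encodeDirection <- function(series, jet, frame = NULL, vFloor = 1e-6) {
  if (abs(sqrt(sum(jet^2)) - 1) > 1e-6) stop("jet must be a unit vector")
  sac <- series@domain@sacMask
  if (is.null(frame)) {
    speeds <- vapply(series@frames, function(f) {
      mean(sqrt(f[, , , 1]^2 + f[, , , 2]^2 + f[, , , 3]^2)[sac])
    }, numeric(1))
    frame <- which.max(speeds)
  }
  fr <- series@frames[[frame]]
  d <- dim(sac)
  vx <- array(fr[, , , 1], d); vy <- array(fr[, , , 2], d)
  vz <- array(fr[, , , 3], d)
  speed <- sqrt(vx^2 + vy^2 + vz^2)
  mask <- sac & speed >= vFloor
  if (!any(mask)) stop("stagnant field: all voxels below the speed floor")
  costh <- (vx * jet[1] + vy * jet[2] + vz * jet[3]) / pmax(speed, 1e-300)
  theta <- acos(pmin(pmax(costh, -1), 1))
  gray <- array(0L, d)
  gray[mask] <- as.integer(floor(255 * theta[mask] / pi + 0.5))  # half-up
  new("GrayVolume", gray = gray, mask = mask,
      levels = array(0L, d), nLevels = 0L)
}

#' Quantize a gray volume for matrix features
#'
#' Equal-width binning of the 0-255 gray range into `nLevels` levels
#' labelled 1..`nLevels`. First-order features always use the unquantized
#' gray; the matrix (GLCM/GLRLM/GLSZM) features use these levels.
#'
#' @param gv a [GrayVolume-class].
#' @param nLevels level count in `[2, 256]` (default 16).
#' @return the volume with its `levels` slot filled.
#' @export
quantizeGray <- function(gv, nLevels = 16) {
  if (nLevels < 2 || nLevels > 256) stop("nLevels must lie in [2, 256]")
  lev <- array(0L, dim(gv@gray))
  lev[gv@mask] <- pmin(as.integer(nLevels),
                       as.integer(floor(gv@gray[gv@mask] * nLevels / 256)) + 1L)
  gv@levels <- lev
  gv@nLevels <- as.integer(nLevels)
  gv
}

#' First-order statistics of a gray volume
#'
#' The 18 standard first-order features over the masked, unquantized 0-255
#' gray values. `TotalEnergy` scales `Energy` by the voxel volume
#' (`spacing^3`). For a constant volume, skewness and kurtosis are
#' degenerate and defined as 0 (a message is emitted).
#'
#' @param gv a [GrayVolume-class].
#' @param spacing voxel size, mm (default 1), used by `TotalEnergy` only.
#' @return named numeric vector of length 18.
#' @export
firstOrderFeatures <- function(gv, spacing = 1) {
  x <- as.numeric(gv@gray[gv@mask])
  n <- length(x)
  if (n < 10) stop("need at least 10 masked voxels")
  p <- as.numeric(table(x)) / n
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 == 0) {
    message("constant volume: skewness and kurtosis defined as 0")
    skew <- 0; kurt <- 0
  } else {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2
  }
  q <- quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  rob <- x[x >= q[1] & x <= q[5]]
  setNames(c(
    sum(x^2),                      # Energy
    spacing^3 * sum(x^2),          # TotalEnergy
    -sum(p * log2(p)),             # Entropy
    min(x), q[1], q[5], max(x),
    mu, q[3], q[4] - q[2],
    max(x) - min(x),
    mean(abs(x - mu)),             # MeanAbsoluteDeviation
    mean(abs(rob - mean(rob))),    # RobustMeanAbsoluteDeviation
    sqrt(mean(x^2)),               # RootMeanSquared
    skew, kurt, m2,
    sum(p^2)                       # Uniformity
  ), .firstOrderNames)
}

# pairs of co-occurring levels for one lattice offset; returns the symmetric
# count matrix (Ng x Ng)
glcmCounts <- function(lev, off, ng) {
  d <- dim(lev)
  rng <- function(n, s) {
    lo <- max(1, 1 - s); hi <- min(n, n - s)
    if (lo > hi) integer(0) else lo:hi
  }
  xs <- rng(d[1], off[1]); ys <- rng(d[2], off[2]); zs <- rng(d[3], off[3])
  a <- lev[xs, ys, zs, drop = FALSE]
  b <- lev[xs + off[1], ys + off[2], zs + off[3], drop = FALSE]
  ok <- a > 0L & b > 0L
  if (!any(ok)) return(matrix(0, ng, ng))
  cnt <- tabulate((a[ok] - 1L) * ng + b[ok], nbins = ng * ng)
  m <- matrix(cnt, ng, ng, byrow = TRUE)
  m + t(m)
}

# the 24 GLCM features from one normalized symmetric matrix P
glcmFromMatrix <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)                      # = py by symmetry
  mux <- sum(seq_len(ng) * px)
  sigx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  kd <- 0:(ng - 1)                      # |i-j| values
  pd <- vapply(kd, function(k) sum(P[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * ng)                      # i+j values
  ps <- vapply(ks, function(k) sum(P[(i + j) == k]), numeric(1))
  da <- sum(kd * pd)
  hxy <- -sum(P[P > 0] * log2(P[P > 0]))
  pxpy <- px[i] * px[j]
  hxy1 <- -sum(P[P > 0] * log2(pxpy[P > 0]))
  hxy2 <- -sum(pxpy[pxpy > 0] * log2(pxpy[pxpy > 0]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  corr <- if (sigx == 0) 1 else (sum(i * j * P) - mux^2) / sigx^2
  imc1 <- if (hx == 0) 0 else (hxy - hxy1) / hx
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  present <- which(px > 0)
  mcc <- if (length(present) < 2) 1 else {
    Psub <- P[present, present, drop = FALSE]
    pxs <- px[present]
    m <- length(present)
    Q <- matrix(0, m, m)
    for (a in seq_len(m)) for (b in seq_len(m))
      Q[a, b] <- sum(Psub[a, ] * Psub[b, ] / (pxs[a] * pxs))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(ev[2], 0))
  }
  offdiag <- abs(i - j) > 0
  setNames(c(
    sum(i * j * P),                                   # Autocorrelation
    mux,                                              # JointAverage
    sum((i + j - 2 * mux)^4 * P),                     # ClusterProminence
    sum((i + j - 2 * mux)^3 * P),                     # ClusterShade
    sum((i + j - 2 * mux)^2 * P),                     # ClusterTendency
    sum((i - j)^2 * P),                               # Contrast
    corr,
    da,                                               # DifferenceAverage
    -sum(pd[pd > 0] * log2(pd[pd > 0])),              # DifferenceEntropy
    sum((kd - da)^2 * pd),                            # DifferenceVariance
    sum(P^2),                                         # JointEnergy
    hxy,                                              # JointEntropy
    imc1, imc2,
    sum(P / (1 + (i - j)^2)),                         # Idm
    sum(P / (1 + ((i - j) / ng)^2)),                  # Idmn
    sum(P / (1 + abs(i - j))),                        # Id
    sum(P / (1 + abs(i - j) / ng)),                   # Idn
    sum(P[offdiag] / (i - j)[offdiag]^2),             # InverseVariance
    max(P),                                           # MaximumProbability
    sum(ks * ps),                                     # SumAverage
    -sum(ps[ps > 0] * log2(ps[ps > 0])),              # SumEntropy
    sum((i - mux)^2 * P),                             # SumSquares
    mcc), .glcmNames)
}

#' Gray-level co-occurrence features
#'
#' Symmetric distance-1 co-occurrence matrices for the 13 unique 3-D
#' directions, each normalized; the 24 standard features are computed per
#' direction and averaged. Degenerate conventions: `Correlation` and `MCC`
#' are 1 and `IMC1` is 0 when the volume has a single occupied gray level.
#'
#' @param gv a quantized [GrayVolume-class] (see [quantizeGray()]).
#' @return named numeric vector of length 24.
#' @export
glcmFeatures <- function(gv) {
  lev <- quantizedLevels(gv)
  ng <- gv@nLevels
  feats <- NULL
  nDir <- 0L
  for (k in seq_len(nrow(.directions13))) {
    cnt <- glcmCounts(lev, .directions13[k, ], ng)
    tot <- sum(cnt)
    if (tot == 0) next
    f <- glcmFromMatrix(cnt / tot)
    feats <- if (is.null(feats)) f else feats + f
    nDir <- nDir + 1L
  }
  if (is.null(feats)) stop("mask too small for co-occurrence analysis")
  feats / nDir
}

quantizedLevels <- function(gv) {
  if (gv@nLevels < 2L) stop("volume must be quantized first (quantizeGray)")
  if (sum(gv@mask) < 2) stop("mask too small for matrix features")
  gv@levels
}

# run-length matrix (Ng x maxLen) for one direction
glrlmCounts <- function(lev, dir, ng) {
  idx <- which(lev > 0L, arr.ind = TRUE)
  v <- lev[lev > 0L]
  # parameterise each lattice line by t along the direction's first nonzero
  # axis; the other coordinates minus t*dir identify the line
  axis <- which(dir != 0)[1]
  t <- idx[, axis]               # dir[axis] == 1 for all 13 directions
  k1 <- idx[, 1] - t * dir[1]
  k2 <- idx[, 2] - t * dir[2]
  k3 <- idx[, 3] - t * dir[3]
  ord <- order(k1, k2, k3, t)
  v <- v[ord]; t <- t[ord]
  k1 <- k1[ord]; k2 <- k2[ord]; k3 <- k3[ord]
  n <- length(v)
  newRun <- c(TRUE, k1[-1] != k1[-n] | k2[-1] != k2[-n] | k3[-1] != k3[-n] |
                t[-1] != t[-n] + 1L | v[-1] != v[-n])
  runId <- cumsum(newRun)
  lens <- tabulate(runId)
  glev <- v[newRun]
  maxLen <- max(lens)
  cnt <- tabulate((glev - 1L) * maxLen + lens, nbins = ng * maxLen)
  matrix(cnt, ng, maxLen, byrow = TRUE)
}

# 16 run-length features from matrix R (Ng x L), Np = voxel count
glrlmFromMatrix <- function(R, np) {
  nr <- sum(R)
  g <- row(R); l <- col(R)
  p <- R / nr
  rg <- rowSums(R); rl <- colSums(R)
  mug <- sum(g * p); mul <- sum(l * p)
  setNames(c(
    sum(R / l^2) / nr,               # ShortRunEmphasis
    sum(R * l^2) / nr,               # LongRunEmphasis
    sum(rg^2) / nr,                  # GrayLevelNonUniformity
    sum(rg^2) / nr^2,                # GrayLevelNonUniformityNormalized
    sum(rl^2) / nr,                  # RunLengthNonUniformity
    sum(rl^2) / nr^2,                # RunLengthNonUniformityNormalized
    nr / np,                         # RunPercentage
    sum((g - mug)^2 * p),            # GrayLevelVariance
    sum((l - mul)^2 * p),            # RunVariance
    -sum(p[p > 0] * log2(p[p > 0])), # RunEntropy
    sum(R / g^2) / nr,               # LowGrayLevelRunEmphasis
    sum(R * g^2) / nr,               # HighGrayLevelRunEmphasis
    sum(R / (g^2 * l^2)) / nr,       # ShortRunLowGrayLevelEmphasis
    sum(R * g^2 / l^2) / nr,         # ShortRunHighGrayLevelEmphasis
    sum(R * l^2 / g^2) / nr,         # LongRunLowGrayLevelEmphasis
    sum(R * g^2 * l^2) / nr          # LongRunHighGrayLevelEmphasis
  ), .glrlmNames)
}

#' Gray-level run-length features
#'
#' Run-length matrices over the 13 directions (runs confined to the mask);
#' the 16 standard features computed per direction and averaged.
#'
#' @param gv a quantized [GrayVolume-class].
#' @return named numeric vector of length 16.
#' @export
glrlmFeatures <- function(gv) {
  lev <- quantizedLevels(gv)
  np <- sum(gv@mask)
  acc <- 0
  for (k in seq_len(nrow(.directions13))) {
    R <- glrlmCounts(lev, .directions13[k, ], gv@nLevels)
    acc <- acc + glrlmFromMatrix(R, np)
  }
  acc / nrow(.directions13)
}

#' Gray-level size-zone features
#'
#' Zones are 26-connected components of equal level within the mask; the 16
#' standard size-zone features are computed from the single (direction-free)
#' size-zone matrix.
#'
#' @param gv a quantized [GrayVolume-class].
#' @return named numeric vector of length 16.
#' @export
glszmFeatures <- function(gv) {
  lev <- quantizedLevels(gv)
  np <- sum(gv@mask)
  zones <- list()
  for (g in sort(unique(lev[lev > 0L]))) {
    labs <- labelComponents3d(lev == g, connectivity = 26)
    if (max(labs) > 0)
      zones[[length(zones) + 1L]] <- cbind(g, tabulate(labs[labs > 0]))
  }
  Z <- do.call(rbind, zones)           # rows: (level, size)
  maxS <- max(Z[, 2])
  M <- matrix(0, gv@nLevels, maxS)
  for (r in seq_len(nrow(Z))) M[Z[r, 1], Z[r, 2]] <- M[Z[r, 1], Z[r, 2]] + 1
  nz <- sum(M)
  g <- row(M); s <- col(M)
  p <- M / nz
  mg <- rowSums(M); ms <- colSums(M)
  mug <- sum(g * p); mus <- sum(s * p)
  setNames(c(
    sum(M / s^2) / nz,               # SmallAreaEmphasis
    sum(M * s^2) / nz,               # LargeAreaEmphasis
    sum(mg^2) / nz,                  # GrayLevelNonUniformity
    sum(mg^2) / nz^2,                # GrayLevelNonUniformityNormalized
    sum(ms^2) / nz,                  # SizeZoneNonUniformity
    sum(ms^2) / nz^2,                # SizeZoneNonUniformityNormalized
    nz / np,                         # ZonePercentage
    sum((g - mug)^2 * p),            # GrayLevelVariance
    sum((s - mus)^2 * p),            # ZoneVariance
    -sum(p[p > 0] * log2(p[p > 0])), # ZoneEntropy
    sum(M / g^2) / nz,               # LowGrayLevelZoneEmphasis
    sum(M * g^2) / nz,               # HighGrayLevelZoneEmphasis
    sum(M / (g^2 * s^2)) / nz,       # SmallAreaLowGrayLevelEmphasis
    sum(M * g^2 / s^2) / nz,         # SmallAreaHighGrayLevelEmphasis
    sum(M * s^2 / g^2) / nz,         # LargeAreaLowGrayLevelEmphasis
    sum(M * g^2 * s^2) / nz          # LargeAreaHighGrayLevelEmphasis
  ), .glszmNames)
}

#' Extract the full 74-feature velocity-informatics vector
#'
#' Pipeline: jet estimation, direction encoding, quantization, then the four
#' feature families. With `frameMode = "peak"` (default) the peak-speed
#' frame is encoded; with `"per_frame"` every frame is encoded and the
#' feature vectors averaged.
#'
#' @param series a [FlowSeries-class].
#' @param domain defaults to the series' own domain.
#' @param nLevels quantization levels for the matrix features (default 16).
#' @param frameMode `"peak"` or `"per_frame"`.
#' @param jet optional jet unit vector (estimated when `NULL`).
#' @return named numeric vector of length 74 (18 + 24 + 16 + 16).
#' @examples
#' dom <- makeDomain(3, 1.5, 0.5)
#' fs <- makeFlowSeries(dom, nFrames = 4, jet = list(direction = c(0, 0, 1),
#'                      peakSpeed = 50), seed = 1)
#' head(velocityFeatures(fs, nLevels = 8))
#' @export
velocityFeatures <- function(series, domain = flowDomain(series),
                             nLevels = 16, frameMode = c("peak", "per_frame"),
                             jet = NULL) {
  frameMode <- match.arg(frameMode)
  if (is.null(jet)) jet <- estimateJetDirection(series, domain)
  oneFrame <- function(frame) {
    gv <- encodeDirection(series, jet, frame = frame)
    gv <- quantizeGray(gv, nLevels)
    c(firstOrderFeatures(gv, spacing = domain@spacing),
      glcmFeatures(gv), glrlmFeatures(gv), glszmFeatures(gv))
  }
  if (frameMode == "peak") {
    out <- oneFrame(NULL)
  } else {
    mats <- lapply(seq_along(series@frames), oneFrame)
    out <- Reduce(`+`, mats) / length(mats)
  }
  stopifnot(length(out) == 74L, all(is.finite(out)))
  out
}
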