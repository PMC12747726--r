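# Independent brute-force oracles for the texture features, written as
# plain per-voxel / per-entry loops so they share no code path with the
# package implementations.

oracleDirections <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

# ---- first order ----
oracleFirstOrder <- function(x, spacing = 1) {
  n <- length(x)
  counts <- table(x)
  p <- as.numeric(counts) / n
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  qs <- quantile(x, c(.1, .25, .5, .75, .9), names = FALSE)
  rob <- x[x >= qs[1] & x <= qs[5]]
  c(FirstOrder.Energy = sum(x^2),
    FirstOrder.TotalEnergy = spacing^3 * sum(x^2),
    FirstOrder.Entropy = -sum(p * log2(p)),
    FirstOrder.Minimum = min(x),
    `FirstOrder.10Percentile` = qs[1],
    `FirstOrder.90Percentile` = qs[5],
    FirstOrder.Maximum = max(x),
    FirstOrder.Mean = mu,
    FirstOrder.Median = qs[3],
    FirstOrder.InterquartileRange = qs[4] - qs[2],
    FirstOrder.Range = max(x) - min(x),
    FirstOrder.MeanAbsoluteDeviation = sum(abs(x - mu)) / n,
    FirstOrder.RobustMeanAbsoluteDeviation =
      sum(abs(rob - mean(rob))) / length(rob),
    FirstOrder.RootMeanSquared = sqrt(sum(x^2) / n),
    FirstOrder.Skewness = if (m2 == 0) 0 else m3 / m2^1.5,
    FirstOrder.Kurtosis = if (m2 == 0) 0 else m4 / m2^2,
    FirstOrder.Variance = m2,
    FirstOrder.Uniformity = sum(p^2))
}

# ---- GLCM ----
# brute-force symmetric co-occurrence matrix for one offset
oracleGlcmMatrix <- function(lev, off, ng) {
  d <- dim(lev)
  C <- matrix(0, ng, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (a == 0) next
    for (s in c(1, -1)) {
      xx <- x + s * off[1]; yy <- y + s * off[2]; zz <- z + s * off[3]
      if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3]) next
      b <- lev[xx, yy, zz]
      if (b == 0) next
      C[a, b] <- C[a, b] + 1
    }
  }
  C
}

oracleGlcmFromP <- function(P) {
  ng <- nrow(P)
  px <- numeric(ng)
  for (i in 1:ng) px[i] <- sum(P[i, ])
  mux <- 0
  for (i in 1:ng) mux <- mux + i * px[i]
  sig2 <- 0
  for (i in 1:ng) sig2 <- sig2 + (i - mux)^2 * px[i]
  autoc <- prom <- shade <- tend <- contrast <- energy <- entropy <- 0
  idm <- idmn <- idv <- idn <- invvar <- sumsq <- corrnum <- 0
  for (i in 1:ng) for (j in 1:ng) {
    pij <- P[i, j]
    autoc <- autoc + i * j * pij
    prom <- prom + (i + j - 2 * mux)^4 * pij
    shade <- shade + (i + j - 2 * mux)^3 * pij
    tend <- tend + (i + j - 2 * mux)^2 * pij
    contrast <- contrast + (i - j)^2 * pij
    energy <- energy + pij^2
    if (pij > 0) entropy <- entropy - pij * log2(pij)
    idm <- idm + pij / (1 + (i - j)^2)
    idmn <- idmn + pij / (1 + ((i - j) / ng)^2)
    idv <- idv + pij / (1 + abs(i - j))
    idn <- idn + pij / (1 + abs(i - j) / ng)
    if (i != j) invvar <- invvar + pij / (i - j)^2
    sumsq <- sumsq + (i - mux)^2 * pij
    corrnum <- corrnum + i * j * pij
  }
  pd <- numeric(ng)           # |i-j| = k-1
  ps <- numeric(2 * ng - 1)   # i+j = k+1
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + P[i, j]
  }
  da <- 0
  for (k in 1:ng) da <- da + (k - 1) * pd[k]
  de <- 0
  for (k in 1:ng) if (pd[k] > 0) de <- de - pd[k] * log2(pd[k])
  dv <- 0
  for (k in 1:ng) dv <- dv + (k - 1 - da)^2 * pd[k]
  sa <- 0
  for (k in seq_along(ps)) sa <- sa + (k + 1) * ps[k]
  se <- 0
  for (k in seq_along(ps)) if (ps[k] > 0) se <- se - ps[k] * log2(ps[k])
  hx <- 0
  for (i in 1:ng) if (px[i] > 0) hx <- hx - px[i] * log2(px[i])
  hxy1 <- hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    q <- px[i] * px[j]
    if (q > 0) {
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log2(q)
      hxy2 <- hxy2 - q * log2(q)
    }
  }
  corr <- if (sig2 == 0) 1 else (corrnum - mux^2) / sig2
  imc1 <- if (hx == 0) 0 else (entropy - hxy1) / hx
  imc2 <- sqrt(max(1 - exp(-2 * (hxy2 - entropy)), 0))
  pres <- which(px > 0)
  mcc <- if (length(pres) < 2) 1 else {
    m <- length(pres)
    Q <- matrix(0, m, m)
    for (a in 1:m) for (b in 1:m) {
      acc <- 0
      for (k in 1:m)
        acc <- acc + P[pres[a], pres[k]] * P[pres[b], pres[k]] /
          (px[pres[a]] * px[pres[k]])
      Q[a, b] <- acc
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(ev[2], 0))
  }
  c(GLCM.Autocorrelation = autoc, GLCM.JointAverage = mux,
    GLCM.ClusterProminence = prom, GLCM.ClusterShade = shade,
    GLCM.ClusterTendency = tend, GLCM.Contrast = contrast,
    GLCM.Correlation = corr, GLCM.DifferenceAverage = da,
    GLCM.DifferenceEntropy = de, GLCM.DifferenceVariance = dv,
    GLCM.JointEnergy = energy, GLCM.JointEntropy = entropy,
    GLCM.IMC1 = imc1, GLCM.IMC2 = imc2, GLCM.Idm = idm, GLCM.Idmn = idmn,
    GLCM.Id = idv, GLCM.Idn = idn, GLCM.InverseVariance = invvar,
    GLCM.MaximumProbability = max(P), GLCM.SumAverage = sa,
    GLCM.SumEntropy = se, GLCM.SumSquares = sumsq, GLCM.MCC = mcc)
}

oracleGlcm <- function(lev, ng) {
  acc <- NULL; nd <- 0
  for (k in seq_len(nrow(oracleDirections))) {
    C <- oracleGlcmMatrix(lev, oracleDirections[k, ], ng)
    if (sum(C) == 0) next
    f <- oracleGlcmFromP(C / sum(C))
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  acc / nd
}

# ---- GLRLM ----
# walk every lattice line voxel by voxel and record runs
oracleGlrlmMatrix <- function(lev, dir, ng) {
  d <- dim(lev)
  runs <- list()
  inGrid <- function(p) all(p >= 1) && all(p <= d)
  starts <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    prev <- c(x, y, z) - dir
    if (!inGrid(prev)) starts[[length(starts) + 1]] <- c(x, y, z)
  }
  maxLen <- max(d)
  R <- matrix(0, ng, sum(d))
  for (s in starts) {
    p <- s
    curLev <- 0L; curLen <- 0L
    while (inGrid(p)) {
      v <- lev[p[1], p[2], p[3]]
      if (v == curLev && v != 0L) {
        curLen <- curLen + 1L
      } else {
        if (curLev != 0L) R[curLev, curLen] <- R[curLev, curLen] + 1
        curLev <- v; curLen <- if (v != 0L) 1L else 0L
      }
      p <- p + dir
    }
    if (curLev != 0L) R[curLev, curLen] <- R[curLev, curLen] + 1
  }
  R
}

oracleRunFeatures <- function(R, np, prefix) {
  nr <- sum(R)
  ng <- nrow(R); nl <- ncol(R)
  sre <- lre <- gln <- rln <- lgl <- hgl <- srl <- srh <- lrl <- lrh <- 0
  mug <- mul <- 0
  for (g in 1:ng) for (l in 1:nl) {
    r <- R[g, l]
    if (r == 0) next
    sre <- sre + r / l^2; lre <- lre + r * l^2
    lgl <- lgl + r / g^2; hgl <- hgl + r * g^2
    srl <- srl + r / (g^2 * l^2); srh <- srh + r * g^2 / l^2
    lrl <- lrl + r * l^2 / g^2; lrh <- lrh + r * g^2 * l^2
    mug <- mug + g * r / nr; mul <- mul + l * r / nr
  }
  for (g in 1:ng) gln <- gln + sum(R[g, ])^2
  for (l in 1:nl) rln <- rln + sum(R[, l])^2
  gv <- rv <- ent <- 0
  for (g in 1:ng) for (l in 1:nl) {
    pr <- R[g, l] / nr
    if (pr > 0) {
      gv <- gv + (g - mug)^2 * pr
      rv <- rv + (l - mul)^2 * pr
      ent <- ent - pr * log2(pr)
    }
  }
  out <- c(sre / nr, lre / nr, gln / nr, gln / nr^2, rln / nr, rln / nr^2,
           nr / np, gv, rv, ent, lgl / nr, hgl / nr, srl / nr, srh / nr,
           lrl / nr, lrh / nr)
  names(out) <- paste0(prefix, c(
    "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
    "RunLengthNonUniformityNormalized", "RunPercentage",
    "GrayLevelVariance", "RunVariance", "RunEntropy",
    "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
    "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
    "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"))
  out
}

oracleGlrlm <- function(lev, ng, np) {
  acc <- 0
  for (k in seq_len(nrow(oracleDirections)))
    acc <- acc + oracleRunFeatures(
      oracleGlrlmMatrix(lev, oracleDirections[k, ], ng), np, "GLRLM.")
  acc / nrow(oracleDirections)
}

# ---- GLSZM ----
# recursive (stack-based) 26-connected flood fill per level
oracleGlszmMatrix <- function(lev, ng) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  zones <- list()
  nbrs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbrs <- nbrs[rowSums(abs(nbrs)) > 0, ]
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (lev[x, y, z] == 0L || seen[x, y, z]) next
    g <- lev[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (r in seq_len(nrow(nbrs))) {
        q <- p + nbrs[r, ]
        if (any(q < 1) || any(q > d)) next
        if (seen[q[1], q[2], q[3]] || lev[q[1], q[2], q[3]] != g) next
        seen[q[1], q[2], q[3]] <- TRUE
        stack[[length(stack) + 1]] <- q
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  Z <- do.call(rbind, zones)
  M <- matrix(0, ng, max(Z[, 2]))
  for (r in seq_len(nrow(Z))) M[Z[r, 1], Z[r, 2]] <- M[Z[r, 1], Z[r, 2]] + 1
  M
}

oracleGlszm <- function(lev, ng, np) {
  f <- oracleRunFeatures(oracleGlszmMatrix(lev, ng), np, "GLSZM.")
  names(f) <- paste0("GLSZM.", c(
    "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
    "SizeZoneNonUniformityNormalized", "ZonePercentage",
    "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
    "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
    "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
    "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis"))
  f
}

# ---- fixtures ----
# random small gray volume (<= 5x5x5), quantized
randomGrayVolume <- function(seed, dmax = 5, nLevels = 4) {
  set.seed(seed)
  d <- sample(3:dmax, 3, replace = TRUE)
  mask <- array(runif(prod(d)) < 0.8, d)
  while (sum(mask) < 12) mask <- array(runif(prod(d)) < 0.8, d)
  gray <- array(sample(0:255, prod(d), replace = TRUE), d)
  gray[!mask] <- 0L
  gv <- new("GrayVolume", gray = gray, mask = mask,
            levels = array(0L, d), nLevels = 0L)
  quantizeGray(gv, nLevels)
}

# constant-gray volume helper
constantGrayVolume <- function(value, d = c(3, 4, 3), nLevels = 4) {
  gray <- array(as.integer(value), d)
  gv <- new("GrayVolume", gray = gray, mask = array(TRUE, d),
            levels = array(0L, d), nLevels = 0L)
  quantizeGray(gv, nLevels)
}
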