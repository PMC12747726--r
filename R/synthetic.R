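# Seeded synthetic aneurysm domains, pulsatile flow series, wall shear
# series, and case cohorts. These stand in for patient imaging and CFD and
# give the downstream metrics controllable ground truth.

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build an idealised aneurysm-sac domain
#'
#' Constructs a spherical sac truncated by the ostium plane where a
#' cylindrical parent-vessel neck of radius `neckRadius` would attach. The
#' sac mask contains the voxels of the sphere above the ostium plane; wall
#' nodes tile the spherical part of the sac surface with near-equal areas
#' (Fibonacci sampling) and outward radial normals.
#'
#' @param sacRadius sac radius, mm.
#' @param neckRadius neck (ostium) radius, mm; must be smaller than
#'   `sacRadius`.
#' @param spacing isotropic voxel size, mm; must resolve at least 10 voxels
#'   across the sac diameter.
#' @return An [AneurysmDomain-class].
#' @examples
#' dom <- makeDomain(sacRadius = 4, neckRadius = 2, spacing = 0.4)
#' dom
#' @export
makeDomain <- function(sacRadius, neckRadius, spacing) {
  if (!(neckRadius > 0 && neckRadius < sacRadius))
    stop("need 0 < neckRadius < sacRadius")
  if (2 * sacRadius / spacing < 10)
    stop("spacing too coarse: fewer than 10 voxels across the sac")
  zOst <- -sqrt(sacRadius^2 - neckRadius^2)  # ostium plane below centre
  margin <- 2 * spacing
  xs <- seq(-sacRadius - margin, sacRadius + margin, by = spacing)
  zs <- seq(zOst - margin, sacRadius + margin, by = spacing)
  nx <- length(xs); nz <- length(zs)
  gx <- array(xs, c(nx, nx, nz))
  gy <- aperm(array(xs, c(nx, nx, nz)), c(2, 1, 3))
  gz <- aperm(array(zs, c(nz, nx, nx)), c(2, 3, 1))
  mask <- (gx^2 + gy^2 + gz^2 <= sacRadius^2) & (gz > zOst)

  capH <- sacRadius - zOst
  capArea <- 2 * pi * sacRadius * capH          # spherical zone area, mm^2
  nWant <- min(5000L, max(64L, round(capArea / spacing^2)))
  # Fibonacci sphere, keep the points above the ostium plane
  nFull <- ceiling(nWant * (4 * pi * sacRadius^2) / capArea)
  k <- seq_len(nFull) - 0.5
  zu <- 1 - 2 * k / nFull
  phi <- pi * (1 + sqrt(5)) * k
  pts <- cbind(sqrt(1 - zu^2) * cos(phi), sqrt(1 - zu^2) * sin(phi), zu)
  keep <- pts[, 3] * sacRadius > zOst
  normals <- pts[keep, , drop = FALSE]
  points <- normals * sacRadius
  areas <- rep(capArea / nrow(points), nrow(points))

  new("AneurysmDomain",
      sacMask = mask, spacing = spacing,
      ostiumPoint = c(0, 0, zOst), ostiumNormal = c(0, 0, 1),
      wallPoints = points, wallNormals = normals, wallAreas = areas)
}

# grid coordinates (mm) of every voxel centre of a domain's grid
domainCoords <- function(domain) {
  d <- dim(domain@sacMask)
  sp <- domain@spacing
  # makeDomain grids are centred on x = y = 0 with z starting below the ostium
  xs <- (seq_len(d[1]) - (d[1] + 1) / 2) * sp
  ys <- (seq_len(d[2]) - (d[2] + 1) / 2) * sp
  zOst <- domain@ostiumPoint[3]
  zs <- zOst - 2 * sp + (seq_len(d[3]) - 1) * sp
  list(x = xs, y = ys, z = zs)
}

# default single-period raised-cosine waveform with its systolic peak at 30%
# of the cycle; strictly positive
defaultWaveform <- function(times, period) {
  0.3 + 0.7 * 0.5 * (1 + cos(2 * pi * (times / period - 0.3)))
}

# Lamb-Oseen swirl velocity (mm/s) of one core at the given voxel coords
lambOseenField <- function(coords, center, axis, coreRadius, circulation) {
  axis <- axis / sqrt(sum(axis^2))
  nx <- length(coords$x); ny <- length(coords$y); nz <- length(coords$z)
  gx <- array(coords$x, c(nx, ny, nz)) - center[1]
  gy <- aperm(array(coords$y, c(ny, nx, nz)), c(2, 1, 3)) - center[2]
  gz <- aperm(array(coords$z, c(nz, nx, ny)), c(2, 3, 1)) - center[3]
  ax <- gx * axis[1] + gy * axis[2] + gz * axis[3]
  px <- gx - ax * axis[1]; py <- gy - ax * axis[2]; pz <- gz - ax * axis[3]
  r <- sqrt(px^2 + py^2 + pz^2)
  rSafe <- pmax(r, 1e-9)
  vth <- circulation / (2 * pi * rSafe) * (1 - exp(-(rSafe / coreRadius)^2))
  vth[r < 1e-9] <- 0
  # tangential direction = axis x radial
  tx <- axis[2] * pz - axis[3] * py
  ty <- axis[3] * px - axis[1] * pz
  tz <- axis[1] * py - axis[2] * px
  tn <- pmax(sqrt(tx^2 + ty^2 + tz^2), 1e-12)
  out <- array(0, c(nx, ny, nz, 3))
  out[, , , 1] <- vth * tx / tn
  out[, , , 2] <- vth * ty / tn
  out[, , , 3] <- vth * tz / tn
  out
}

#' Generate a pulsatile synthetic flow series
#'
#' Each frame is `waveform(t)` times the sum of Lamb-Oseen swirling cores and
#' a uniform inflow jet, plus seeded Gaussian noise, zeroed outside the sac
#' mask. Core centres may follow a per-frame path so the downstream degree of
#' vortex overlap has controllable ground truth. The Lamb-Oseen tangential
#' profile `v_theta(r) = Gamma/(2 pi r) * (1 - exp(-r^2/rc^2))` is used for
#' its smoothness and known lambda2 sign structure.
#'
#' The composite field is not divergence-free in general (the individual
#' cores are solenoidal, the uniform jet is, the noise is not); no downstream
#' operation assumes incompressibility.
#'
#' @param domain an [AneurysmDomain-class].
#' @param nFrames number of frames over one cycle (default 20).
#' @param waveform positive amplitude samples (length `nFrames`) or a
#'   function of time; default a raised-cosine pulse peaking at 30% of the
#'   cycle.
#' @param vortices list of core specs, each a list with `center` (3-vector,
#'   mm, or an `nFrames` x 3 path matrix), `coreRadius` (mm, at least twice
#'   the voxel spacing), `circulation` (mm^2/s) and optional `axis`
#'   (default z). `NULL` gives a single static core at the sac centre.
#' @param jet list with `direction` (3-vector) and `peakSpeed` (mm/s), or
#'   `NULL` for no jet.
#' @param noiseSd standard deviation of added Gaussian velocity noise, mm/s.
#' @param period cycle length, s (default 1).
#' @param seed integer seed for the noise.
#' @return A [FlowSeries-class].
#' @examples
#' dom <- makeDomain(3, 1.5, 0.4)
#' fs <- makeFlowSeries(dom, nFrames = 5, seed = 1)
#' fs
#' @export
makeFlowSeries <- function(domain, nFrames = 20, waveform = NULL,
                           vortices = NULL, jet = NULL, noiseSd = 0,
                           period = 1, seed = 1) {
  if (nFrames < 2) stop("need at least 2 frames")
  times <- (seq_len(nFrames) - 1) * period / nFrames
  if (is.null(waveform)) {
    w <- defaultWaveform(times, period)
  } else if (is.function(waveform)) {
    w <- waveform(times)
  } else {
    if (length(waveform) != nFrames) stop("waveform length must equal nFrames")
    w <- as.numeric(waveform)
  }
  if (any(!is.finite(w)) || any(w <= 0)) stop("waveform must be positive")

  coords <- domainCoords(domain)
  if (is.null(vortices)) {
    ctr <- sacCentroid(domain)
    vortices <- list(list(center = ctr, coreRadius = maxSacRadius(domain) / 2,
                          circulation = 2000))
  }
  for (v in vortices) {
    if (v$coreRadius < 2 * domain@spacing)
      stop("vortex core radius below 2 x spacing is unresolvable")
  }
  d <- dim(domain@sacMask)
  maskIdx <- which(rep(domain@sacMask, 3) == FALSE)

  base <- function(frameIdx) {
    f <- array(0, c(d, 3))
    for (v in vortices) {
      ctr <- if (is.matrix(v$center)) v$center[frameIdx, ] else v$center
      axis <- if (is.null(v$axis)) c(0, 0, 1) else v$axis
      f <- f + lambOseenField(coords, ctr, axis, v$coreRadius, v$circulation)
    }
    if (!is.null(jet)) {
      dir <- jet$direction / sqrt(sum(jet$direction^2))
      f[, , , 1] <- f[, , , 1] + dir[1] * jet$peakSpeed
      f[, , , 2] <- f[, , , 2] + dir[2] * jet$peakSpeed
      f[, , , 3] <- f[, , , 3] + dir[3] * jet$peakSpeed
    }
    f
  }

  static <- all(vapply(vortices, function(v) !is.matrix(v$center), logical(1)))
  if (static) base0 <- base(1L)
  frames <- withSeed(seed, lapply(seq_len(nFrames), function(i) {
    f <- if (static) base0 else base(i)
    f <- f * w[i]
    if (noiseSd > 0)
      f <- f + array(rnorm(length(f), sd = noiseSd), dim(f))
    f[maskIdx] <- 0
    f
  }))
  new("FlowSeries", frames = frames, times = times, period = period,
      domain = domain)
}

#' Centroid of the sac lumen
#'
#' Mean position (mm) of the sac-mask voxels; a convenient anchor for
#' vortex-core paths.
#'
#' @param domain an [AneurysmDomain-class].
#' @return numeric 3-vector, mm.
#' @export
sacCentroid <- function(domain) {
  coords <- domainCoords(domain)
  idx <- which(domain@sacMask, arr.ind = TRUE)
  c(mean(coords$x[idx[, 1]]), mean(coords$y[idx[, 2]]), mean(coords$z[idx[, 3]]))
}

maxSacRadius <- function(domain) {
  coords <- domainCoords(domain)
  idx <- which(domain@sacMask, arr.ind = TRUE)
  ctr <- sacCentroid(domain)
  max(sqrt((coords$x[idx[, 1]] - ctr[1])^2 +
           (coords$y[idx[, 2]] - ctr[2])^2 +
           (coords$z[idx[, 3]] - ctr[3])^2))
}

#' Generate a wall shear series with target summary metrics
#'
#' Builds per-node shear-vector time series whose recomputed spatial-mean
#' TAWSS, OSI and low-shear area fraction match the requested targets. Each
#' node carries a constant-magnitude vector rotating between two fixed
#' orthogonal directions: `tau(t) = m (cos(theta) d + sin(theta) s(t) e)`
#' with `s(t)` a balanced square wave, which yields OSI
#' `= (1 - cos(theta)) / 2` exactly under the cyclic trapezoidal integrals
#' used by the metrics. Node magnitudes are drawn so that the area fraction
#' below 2 Pa equals `targetLsa` and the area-weighted mean equals
#' `targetTawss`.
#'
#' @param domain an [AneurysmDomain-class]; supplies the wall nodes.
#' @param targetTawss target spatial-mean time-averaged WSS, Pa.
#' @param targetOsi target spatial-mean OSI in `[0, 0.5]`.
#' @param targetLsa target low-shear (< 2 Pa) area fraction in `[0, 1]`.
#' @param nFrames frames per cycle (even; default 20).
#' @param period cycle length, s.
#' @param seed integer seed.
#' @return A [WallShearSeries-class].
#' @examples
#' dom <- makeDomain(3, 1.5, 0.4)
#' ws <- makeWallShear(dom, targetTawss = 3, targetOsi = 0.1,
#'                     targetLsa = 0.3, seed = 2)
#' @export
makeWallShear <- function(domain, targetTawss, targetOsi, targetLsa,
                          nFrames = 20, period = 1, seed = 1) {
  if (targetOsi < 0 || targetOsi > 0.5) stop("targetOsi must lie in [0, 0.5]")
  if (targetLsa < 0 || targetLsa > 1) stop("targetLsa must lie in [0, 1]")
  if (targetTawss <= 0) stop("targetTawss must be positive")
  if (nFrames %% 2 != 0) stop("nFrames must be even")
  nNodes <- length(domain@wallAreas)

  # node magnitudes: a 'low' block spread below 2 Pa and a 'high' block at h
  lowMean <- 1
  if (targetLsa >= 1 - 1e-12) {
    if (targetTawss >= 2)
      stop("infeasible targets: all-low wall cannot average >= 2 Pa")
    h <- NA
  } else {
    h <- (targetTawss - targetLsa * lowMean) / (1 - targetLsa)
    if (h < 2 - 1e-9)
      stop("infeasible targets: high-shear block would fall below 2 Pa")
  }

  withSeed(seed, {
    nLow <- round(targetLsa * nNodes)
    lowIdx <- sample.int(nNodes, nLow)
    m <- numeric(nNodes)
    if (nLow == nNodes) {
      # all-low wall: spread below 2 Pa around the target mean
      w <- max(0, min(targetTawss - 0.05, 1.95 - targetTawss))
      lows <- runif(nLow, targetTawss - w, targetTawss + w)
      m[] <- pmin(pmax(lows - mean(lows) + targetTawss, 0.02), 1.99)
    } else {
      if (nLow > 0) {
        lows <- runif(nLow, 0.25, 1.75)
        lows <- lows - mean(lows) + lowMean    # exact low-block mean
        m[lowIdx] <- pmin(pmax(lows, 0.05), 1.95)
      }
      w <- max(0, min(0.2 * h, h - 2))
      highs <- runif(nNodes - nLow, h - w, h + w)
      highs <- pmax(highs - mean(highs) + h, 2 + 1e-9)
      m[setdiff(seq_len(nNodes), lowIdx)] <- highs
    }

    theta <- acos(1 - 2 * targetOsi)
    # random orthonormal pair (d, e) per node
    d1 <- matrix(rnorm(3 * nNodes), nNodes, 3)
    d1 <- d1 / sqrt(rowSums(d1^2))
    tmp <- matrix(rnorm(3 * nNodes), nNodes, 3)
    e1 <- tmp - d1 * rowSums(tmp * d1)
    e1 <- e1 / sqrt(rowSums(e1^2))

    s <- rep(c(1, -1), each = nFrames / 2)     # balanced square wave
    tau <- array(0, c(nNodes, 3, nFrames))
    for (f in seq_len(nFrames)) {
      dirs <- cos(theta) * d1 + sin(theta) * s[f] * e1
      tau[, , f] <- m * dirs
    }
    times <- (seq_len(nFrames) - 1) * period / nFrames
    new("WallShearSeries", tau = tau, areas = domain@wallAreas,
        times = times, period = period)
  })
}

#' Generate a synthetic case cohort
#'
#' Emits a per-case table of morphological features (aneurysm location,
#' parent vessel diameter, ostium minimum, NRV2 — a Voronoi-diagram-derived
#' shape index, treated here as an input feature) and the 74 named
#' velocity-informatics features, with rupture labels. Velocity features are
#' standardized Gaussians whose ruptured-group means are shifted by
#' `effectSizes` (standardized mean differences); morphological effects are
#' set analogously via `morphEffects`.
#'
#' Defaults mirror the cohort structure the package emulates: 112 cases,
#' 44 ruptured, locations ICA/MCA/ACA in 39/52/21 proportion.
#'
#' @param nCases,nRuptured cohort size and ruptured count.
#' @param locations named integer counts over ICA/MCA/ACA summing to
#'   `nCases`.
#' @param effectSizes named standardized mean shifts (ruptured minus
#'   unruptured) for any subset of the 74 velocity features; unnamed
#'   features get 0. A single unnamed number is recycled to all features.
#' @param morphEffects named shifts for `VesselDiameter`, `OstiumMin`,
#'   `NRV2`.
#' @param seed integer seed.
#' @return A `data.frame` with columns `caseId`, `location`, `label`,
#'   the morphology columns, and the 74 feature columns.
#' @examples
#' coh <- makeCohort(nCases = 40, nRuptured = 16, seed = 1)
#' table(coh$label)
#' @export
makeCohort <- function(nCases = 112, nRuptured = 44,
                       locations = c(ICA = 39, MCA = 52, ACA = 21),
                       effectSizes = NULL,
                       morphEffects = c(VesselDiameter = 0.6, OstiumMin = 0.2,
                                        NRV2 = 0.8),
                       seed = 1) {
  if (nRuptured > nCases) stop("nRuptured must not exceed nCases")
  if (is.null(names(locations)) || length(locations) != 3L)
    stop("locations must be a named 3-vector of counts")
  if (sum(locations) != nCases) {
    # rescale counts proportionally when a non-default nCases is requested
    locations <- round(locations / sum(locations) * nCases)
    locations[1] <- nCases - sum(locations[-1])
  }
  fnames <- velocityFeatureNames()
  es <- setNames(numeric(length(fnames)), fnames)
  if (!is.null(effectSizes)) {
    if (is.null(names(effectSizes)) && length(effectSizes) == 1L) {
      es[] <- effectSizes
    } else {
      bad <- setdiff(names(effectSizes), fnames)
      if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
      es[names(effectSizes)] <- effectSizes
    }
  }
  me <- c(VesselDiameter = 0, OstiumMin = 0, NRV2 = 0)
  me[names(morphEffects)] <- morphEffects

  out <- withSeed(seed, {
    label <- factor(rep(c("ruptured", "unruptured"),
                        c(nRuptured, nCases - nRuptured)),
                    levels = c("unruptured", "ruptured"))
    location <- factor(sample(rep(names(locations), locations)),
                       levels = c("ICA", "MCA", "ACA"))
    shift <- as.numeric(label == "ruptured")
    morph <- data.frame(
      VesselDiameter = rnorm(nCases, 3.5, 0.8) + 0.8 * me["VesselDiameter"] * shift,
      OstiumMin = rnorm(nCases, 2.5, 0.7) + 0.7 * me["OstiumMin"] * shift,
      NRV2 = rnorm(nCases, 0.60, 0.15) + 0.15 * me["NRV2"] * shift
    )
    feat <- matrix(rnorm(nCases * length(fnames)), nCases,
                   dimnames = list(NULL, fnames))
    feat <- feat + outer(shift, es)
    tab <- data.frame(caseId = sprintf("case%03d", seq_len(nCases)),
                      location = location, label = label, morph,
                      feat, check.names = FALSE)
    tab[sample.int(nCases), , drop = FALSE]
  })
  rownames(out) <- NULL
  out
}
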