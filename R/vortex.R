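# lambda2 vortex identification and the temporal vortex summaries (degree of
# vortex overlap, vortex volume fraction).

#' lambda2 field of a velocity frame
#'
#' For each voxel, builds the velocity-gradient tensor J by central
#' differences (one-sided at the grid faces), splits it into its symmetric
#' part S and antisymmetric part Omega, and returns the middle eigenvalue of
#' `S^2 + Omega^2` (eigenvalues sorted ascending; index 2 of 3). Swirling
#' regions are where this eigenvalue is negative. The symmetric 3x3
#' eigensolve uses the closed-form trigonometric method, vectorized over the
#' volume.
#'
#' @param velocity 4-D numeric array `(nx, ny, nz, 3)`, mm/s.
#' @param spacing voxel size, mm.
#' @return 3-D numeric array of lambda2 values, s^-2.
#' @export
lambda2Field <- function(velocity, spacing) {
  J <- velocityGradient(velocity, spacing)
  # A = S^2 + Omega^2 where S=(J+J')/2, W=(J-J')/2. Using index notation,
  # A_ij = sum_k (S_ik S_kj + W_ik W_kj); A is symmetric.
  S <- list(); W <- list()
  for (i in 1:3) {
    S[[i]] <- list(); W[[i]] <- list()
    for (j in 1:3) {
      S[[i]][[j]] <- (J[[i]][[j]] + J[[j]][[i]]) / 2
      W[[i]][[j]] <- (J[[i]][[j]] - J[[j]][[i]]) / 2
    }
  }
  A <- list()
  for (i in 1:3) {
    A[[i]] <- list()
    for (j in i:3) {
      acc <- 0
      for (k in 1:3)
        acc <- acc + S[[i]][[k]] * S[[k]][[j]] + W[[i]][[k]] * W[[k]][[j]]
      A[[i]][[j]] <- acc
    }
  }
  middleEigSym3(A[[1]][[1]], A[[2]][[2]], A[[3]][[3]],
                A[[1]][[2]], A[[1]][[3]], A[[2]][[3]])
}

# middle eigenvalue of symmetric 3x3 matrices given componentwise as arrays
middleEigSym3 <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(p2 / 6)
  pSafe <- pmax(p, .Machine$double.xmin)
  b11 <- (a11 - q) / pSafe; b22 <- (a22 - q) / pSafe; b33 <- (a33 - q) / pSafe
  b12 <- a12 / pSafe; b13 <- a13 / pSafe; b23 <- a23 / pSafe
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)                 # largest
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)    # smallest
  mid <- 3 * q - e1 - e3
  mid[p == 0] <- q[p == 0]
  mid
}

#' Q-criterion field of a velocity frame
#'
#' `Q = (|Omega|^2 - |S|^2) / 2`; vortices are where Q is positive. Offered
#' as a sensitivity alternative to [lambda2Field()].
#'
#' @inheritParams lambda2Field
#' @return 3-D numeric array of Q values, s^-2.
#' @export
qCriterionField <- function(velocity, spacing) {
  J <- velocityGradient(velocity, spacing)
  s2 <- 0; w2 <- 0
  for (i in 1:3) for (j in 1:3) {
    s <- (J[[i]][[j]] + J[[j]][[i]]) / 2
    w <- (J[[i]][[j]] - J[[j]][[i]]) / 2
    s2 <- s2 + s * s
    w2 <- w2 + w * w
  }
  (w2 - s2) / 2
}

# Label connected components of a 3-D logical mask (26- or 6-connectivity).
# Vectorized wavefront flood fill on a zero-padded linear index space.
labelComponents3d <- function(mask, connectivity = 26) {
  d <- dim(mask)
  pd <- d + 2L
  pm <- array(FALSE, pd)
  pm[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  steps <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  steps <- steps[!(steps$dx == 0 & steps$dy == 0 & steps$dz == 0), ]
  if (connectivity == 6)
    steps <- steps[abs(steps$dx) + abs(steps$dy) + abs(steps$dz) == 1, ]
  else if (connectivity != 26)
    stop("connectivity must be 6 or 26")
  off <- steps$dx + steps$dy * pd[1] + steps$dz * pd[1] * pd[2]
  labels <- integer(prod(pd))
  todo <- which(pm)
  lab <- 0L
  pending <- rep(TRUE, length(labels))
  pending[-todo] <- FALSE
  for (seed in todo) {
    if (!pending[seed]) next
    lab <- lab + 1L
    frontier <- seed
    pending[seed] <- FALSE
    labels[seed] <- lab
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, off, `+`)))
      nb <- nb[nb >= 1L & nb <= length(labels)]
      nb <- nb[pending[nb]]
      if (!length(nb)) break
      labels[nb] <- lab
      pending[nb] <- FALSE
      frontier <- nb
    }
  }
  out <- array(labels, pd)[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  array(out, d)
}

#' Extract per-frame vortex-region masks
#'
#' Computes the vortex criterion field on every frame and thresholds it
#' (lambda2 below `threshold`, or Q above it for `criterion = "q"`),
#' intersects with the sac mask, and removes connected components smaller
#' than `minVoxels` (26-connectivity).
#'
#' @param series a [FlowSeries-class].
#' @param threshold criterion cutoff, s^-2 (default 0).
#' @param minVoxels smallest retained component size (default 8).
#' @param criterion `"lambda2"` (default) or `"q"`.
#' @return A [VortexSeries-class].
#' @export
extractVortexMask <- function(series, threshold = 0, minVoxels = 8,
                              criterion = c("lambda2", "q")) {
  criterion <- match.arg(criterion)
  sp <- series@domain@spacing
  sac <- series@domain@sacMask
  fields <- lapply(series@frames, function(f) {
    if (criterion == "lambda2") lambda2Field(f, sp) else qCriterionField(f, sp)
  })
  masks <- lapply(fields, function(l2) {
    m <- if (criterion == "lambda2") l2 < threshold else l2 > threshold
    m <- m & sac
    if (any(m) && minVoxels > 1) {
      labs <- labelComponents3d(m, connectivity = 26)
      sizes <- tabulate(labs[labs > 0])
      keep <- which(sizes >= minVoxels)
      m <- array(labs %in% keep, dim(m))
    }
    m
  })
  new("VortexSeries", masks = masks, lambda2 = fields, threshold = threshold)
}

#' Temporally averaged degree of vortex overlap
#'
#' Averages the Dice coefficient `2|A n B| / (|A| + |B|)` over consecutive
#' frame pairs (cyclic: the last-to-first pair is included). A pair where
#' both masks are empty contributes 1 (no vortex, no movement); a pair with
#' exactly one empty mask contributes 0. A temporally stable vortex scores
#' 1; the score decreases as the vortex moves. With `mode = "reference"`
#' each frame is instead compared against the union of all frames' masks.
#'
#' @param series a [VortexSeries-class].
#' @param mode `"consecutive"` (default) or `"reference"`.
#' @return dimensionless DVO in `[0, 1]`.
#' @export
dvo <- function(series, mode = c("consecutive", "reference")) {
  mode <- match.arg(mode)
  n <- length(series@masks)
  if (n < 2) stop("need at least 2 frames")
  dice <- function(a, b) {
    sa <- sum(a); sb <- sum(b)
    if (sa == 0 && sb == 0) return(1)
    if (sa == 0 || sb == 0) return(0)
    2 * sum(a & b) / (sa + sb)
  }
  if (mode == "consecutive") {
    pairs <- vapply(seq_len(n), function(i) {
      dice(series@masks[[i]], series@masks[[if (i == n) 1L else i + 1L]])
    }, numeric(1))
    mean(pairs)
  } else {
    ref <- Reduce(`|`, series@masks)
    mean(vapply(series@masks, function(m) dice(m, ref), numeric(1)))
  }
}

#' Time-averaged vortex volume fraction
#'
#' Mean over frames of the vortex-mask volume divided by the sac volume
#' (Vt/V).
#'
#' @param series a [VortexSeries-class].
#' @param domain the [AneurysmDomain-class] providing the sac mask.
#' @return dimensionless fraction in `[0, 1]`.
#' @export
vortexVolumeFraction <- function(series, domain) {
  nSac <- sum(domain@sacMask)
  if (nSac == 0) stop("empty sac mask")
  mean(vapply(series@masks, sum, numeric(1))) / nSac
}
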