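# Wall shear derived from a flow field under a chosen viscosity law. This is
# the package's mechanistic link between rheology and the WSS metrics: one
# velocity field, evaluated under different laws, yields different wall
# shear series.

# trilinear interpolation of a (nx,ny,nz) array at points given in grid
# coordinates (mm); pts is an (n x 3) matrix
trilinear <- function(field, coords, pts) {
  sp <- c(coords$x[2] - coords$x[1], coords$y[2] - coords$y[1],
          coords$z[2] - coords$z[1])
  d <- dim(field)
  fx <- (pts[, 1] - coords$x[1]) / sp[1] + 1
  fy <- (pts[, 2] - coords$y[1]) / sp[2] + 1
  fz <- (pts[, 3] - coords$z[1]) / sp[3] + 1
  i0 <- pmin(pmax(floor(fx), 1), d[1] - 1); tx <- fx - i0
  j0 <- pmin(pmax(floor(fy), 1), d[2] - 1); ty <- fy - j0
  k0 <- pmin(pmax(floor(fz), 1), d[3] - 1); tz <- fz - k0
  tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1); tz <- pmin(pmax(tz, 0), 1)
  lin <- function(i, j, k) field[cbind(i, j, k)]
  v000 <- lin(i0, j0, k0);     v100 <- lin(i0 + 1, j0, k0)
  v010 <- lin(i0, j0 + 1, k0); v110 <- lin(i0 + 1, j0 + 1, k0)
  v001 <- lin(i0, j0, k0 + 1); v101 <- lin(i0 + 1, j0, k0 + 1)
  v011 <- lin(i0, j0 + 1, k0 + 1); v111 <- lin(i0 + 1, j0 + 1, k0 + 1)
  (v000 * (1 - tx) + v100 * tx) * (1 - ty) * (1 - tz) +
    (v010 * (1 - tx) + v110 * tx) * ty * (1 - tz) +
    (v001 * (1 - tx) + v101 * tx) * (1 - ty) * tz +
    (v011 * (1 - tx) + v111 * tx) * ty * tz
}

#' Wall shear series from a flow series under a viscosity law
#'
#' Estimates the wall shear-stress vector at each wall node as
#' `tau = eta(gammaDot) * gammaDot * t_hat`, where the near-wall shear rate
#' `gammaDot = |v_t| / h` comes from the tangential velocity `v_t`
#' interpolated at distance `h` (one voxel) inside the wall along the inward
#' normal, and `t_hat` is the tangential unit direction. Pa from mm/s over
#' mm times Pa s. A first-order wall model: coarse compared to a resolved
#' boundary layer, but it responds to the viscosity law exactly where
#' shear-thinning matters (low-shear regions).
#'
#' @param flow a [FlowSeries-class].
#' @param params a [RheologyParams-class] viscosity law.
#' @param wallOffset sampling distance inside the wall, in voxels
#'   (default 1).
#' @return A [WallShearSeries-class] on the domain's wall nodes.
#' @export
wallShearFromFlow <- function(flow, params, wallOffset = 1) {
  dom <- flow@domain
  coords <- domainCoords(dom)
  h <- wallOffset * dom@spacing
  pts <- dom@wallPoints - dom@wallNormals * h
  n <- nrow(pts)
  nf <- length(flow@frames)
  tau <- array(0, c(n, 3, nf))
  for (f in seq_len(nf)) {
    fr <- flow@frames[[f]]
    v <- cbind(trilinear(array(fr[, , , 1], dim(fr)[1:3]), coords, pts),
               trilinear(array(fr[, , , 2], dim(fr)[1:3]), coords, pts),
               trilinear(array(fr[, , , 3], dim(fr)[1:3]), coords, pts))
    vn <- rowSums(v * dom@wallNormals)
    vt <- v - vn * dom@wallNormals
    speed <- sqrt(rowSums(vt^2))
    gdot <- speed / h                      # mm/s over mm -> s^-1
    eta <- viscosity(params, gdot)
    mag <- eta * gdot                      # Pa
    dirs <- vt / pmax(speed, 1e-12)
    dirs[speed < 1e-12, ] <- 0
    tau[, , f] <- mag * dirs
  }
  new("WallShearSeries", tau = tau, areas = dom@wallAreas,
      times = flow@times, period = flow@period)
}
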