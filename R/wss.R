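# Wall-shear-stress-derived hemodynamic metrics. Time integrals use the
# trapezoidal rule over the sampled frames with periodic closure (the
# last-to-first segment of the cardiac cycle is included).

# cyclic trapezoid weights: integral over one period = sum(w * f(t_i))
cyclicWeights <- function(times, period) {
  n <- length(times)
  dt <- c(diff(times), times[1] + period - times[n])
  if (any(dt <= 0)) stop("times must fit strictly within one period")
  (dt + c(dt[n], dt[-n])) / 2
}

tauMagnitudes <- function(ws) {
  # (nodes x frames) matrix of |tau|
  sqrt(ws@tau[, 1, ]^2 + ws@tau[, 2, ]^2 + ws@tau[, 3, ]^2)
}

#' Per-node time-averaged wall shear stress
#'
#' Trapezoidal time average of `|tau(t)|` over the cardiac cycle, per node.
#'
#' @param ws a [WallShearSeries-class].
#' @return numeric vector of per-node TAWSS, Pa.
#' @export
tawssField <- function(ws) {
  w <- cyclicWeights(ws@times, ws@period)
  as.numeric(tauMagnitudes(ws) %*% w) / ws@period
}

#' Per-node oscillatory shear index
#'
#' `OSI = 0.5 (1 - |int tau dt| / int |tau| dt)` per node, both integrals
#' cyclic trapezoidal over the cardiac cycle. A node whose shear vanishes at
#' every frame has no oscillation and is assigned OSI 0.
#'
#' @param ws a [WallShearSeries-class].
#' @return numeric vector of per-node OSI in `[0, 0.5]`.
#' @export
osiField <- function(ws) {
  w <- cyclicWeights(ws@times, ws@period)
  num <- sqrt((ws@tau[, 1, ] %*% w)^2 + (ws@tau[, 2, ] %*% w)^2 +
              (ws@tau[, 3, ] %*% w)^2)
  den <- tauMagnitudes(ws) %*% w
  osi <- 0.5 * (1 - as.numeric(num) / as.numeric(den))
  osi[as.numeric(den) == 0] <- 0
  pmin(pmax(osi, 0), 0.5)
}

#' Per-node relative residence time
#'
#' `RRT = 1 / ((1 - 2 OSI) TAWSS)`, a proxy for how long blood resides near
#' the wall. The denominator is clamped below at `eps` so fully oscillatory
#' nodes (OSI near 0.5) stay finite; a message reports how many nodes were
#' clamped.
#'
#' @param ws a [WallShearSeries-class].
#' @param eps denominator floor, Pa (default 1e-6).
#' @return numeric vector of per-node RRT, Pa^-1.
#' @export
rrtField <- function(ws, eps = 1e-6) {
  den <- (1 - 2 * osiField(ws)) * tawssField(ws)
  nClamp <- sum(den < eps)
  if (nClamp > 0)
    message(nClamp, " node(s) clamped at the RRT denominator floor")
  1 / pmax(den, eps)
}

#' Low-shear area percentage
#'
#' Percentage of wall area whose time-averaged WSS falls strictly below the
#' threshold (2 Pa by convention).
#'
#' @param ws a [WallShearSeries-class].
#' @param threshold TAWSS cutoff, Pa; must be positive.
#' @return percent of total wall area in `[0, 100]`.
#' @export
lsa <- function(ws, threshold = 2) {
  if (threshold <= 0) stop("threshold must be positive")
  tw <- tawssField(ws)
  100 * sum(ws@areas[tw < threshold]) / sum(ws@areas)
}

#' Scalar wall-shear summary metrics
#'
#' Computes the scalar WSS metrics of a wall shear series:
#' \describe{
#'   \item{staWss}{area-weighted spatial mean of per-node TAWSS.}
#'   \item{wssMax}{maximum `|tau|` over all nodes and frames.}
#'   \item{wssMin}{by default the time average of the per-frame spatial
#'     minimum of `|tau|` (`minMode = "time_avg_of_spatial_min"`); set
#'     `minMode = "global_min"` for the minimum over all nodes and frames.}
#'   \item{lsa}{low-shear area percent (threshold 2 Pa).}
#'   \item{osi}{spatial mean of per-node OSI, area-weighted by default.}
#'   \item{rrt}{area-weighted spatial mean of per-node RRT.}
#' }
#'
#' @param ws a [WallShearSeries-class].
#' @param minMode `"time_avg_of_spatial_min"` (default) or `"global_min"`.
#' @param osiWeighting `"area"` (default) or `"count"` spatial weighting for
#'   the scalar OSI.
#' @return named list with `staWss`, `wssMax`, `wssMin`, `lsa`, `osi`, `rrt`.
#' @examples
#' dom <- makeDomain(3, 1.5, 0.4)
#' ws <- makeWallShear(dom, 3, 0.1, 0.3, seed = 1)
#' unlist(wssSummary(ws))
#' @export
wssSummary <- function(ws, minMode = c("time_avg_of_spatial_min", "global_min"),
                       osiWeighting = c("area", "count")) {
  minMode <- match.arg(minMode)
  osiWeighting <- match.arg(osiWeighting)
  aw <- ws@areas / sum(ws@areas)
  mags <- tauMagnitudes(ws)
  w <- cyclicWeights(ws@times, ws@period)
  wssMin <- if (minMode == "global_min") min(mags)
            else sum(apply(mags, 2, min) * w) / ws@period
  osi <- osiField(ws)
  list(
    staWss = sum(tawssField(ws) * aw),
    wssMax = max(mags),
    wssMin = wssMin,
    lsa = lsa(ws),
    osi = if (osiWeighting == "area") sum(osi * aw) else mean(osi),
    rrt = sum(rrtField(ws) * aw)
  )
}
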