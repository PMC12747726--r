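#' Construct blood rheology parameters
#'
#' @param model `"newtonian"`, `"carreau_yasuda"`, `"casson"` or
#'   `"herschel_bulkley"` (abbreviations `"cy"` and `"hb"` are accepted).
#' @param ... named overrides of any [RheologyParams-class] slot.
#'
#' @return A [RheologyParams-class] object with field-standard defaults.
#' @examples
#' cy <- rheologyParams("carreau_yasuda")
#' viscosity(cy, c(1e-6, 1, 1e6))
#' @export
rheologyParams <- function(model = "newtonian", ...) {
  model <- switch(model, cy = "carreau_yasuda", hb = "herschel_bulkley", model)
  args <- list(...)
  bad <- setdiff(names(args), slotNames("RheologyParams"))
  if (length(bad))
    stop("unknown rheology parameter(s): ", paste(bad, collapse = ", "))
  do.call(new, c(list("RheologyParams", model = model), args))
}

#' @rdname viscosity
#' @export
setGeneric("viscosity", function(params, gammaDot) standardGeneric("viscosity"))

#' Dynamic viscosity under a blood rheology law
#'
#' Evaluates the selected viscosity law at shear rate `gammaDot` (s^-1),
#' vectorized. The laws are:
#' \describe{
#'   \item{newtonian}{constant `mu`.}
#'   \item{carreau_yasuda}{`etaInf + (eta0 - etaInf) * (1 + (lambda*g)^a)^((n-1)/a)`,
#'     a shear-thinning law bounded between `eta0` (zero shear) and `etaInf`
#'     (infinite shear).}
#'   \item{casson}{Merrill hematocrit closure: yield stress
#'     `tau0c = 0.1 * (0.625 * H)^3` Pa and asymptotic viscosity
#'     `etac = plasmaViscosity * (1 - H)^(-2.5)`, with
#'     `eta(g) = (sqrt(tau0c / g) + sqrt(etac))^2`.}
#'   \item{herschel_bulkley}{`tau0 / g + k * (g / gammac)^(n - 1)`, a yield-stress
#'     power law.}
#' }
#' The Casson and Herschel-Bulkley laws diverge as the shear rate tends to
#' zero; shear rates are clamped from below at `params@gammaFloor`
#' (default 1e-6 s^-1) so evaluated fields stay finite.
#'
#' @param params a [RheologyParams-class] object.
#' @param gammaDot shear rate(s), s^-1, non-negative and finite.
#' @return Dynamic viscosity in Pa s, same shape as `gammaDot`.
#' @examples
#' viscosity(rheologyParams("newtonian"), 0:5)
#' @export
setMethod("viscosity", "RheologyParams", function(params, gammaDot) {
  if (any(!is.finite(gammaDot)))
    stop("gammaDot must be finite")
  if (any(gammaDot < 0))
    stop("gammaDot must be non-negative")
  g <- gammaDot
  out <- switch(params@model,
    newtonian = rep_len(params@mu, length(g)),
    carreau_yasuda = {
      params@etaInf + (params@eta0 - params@etaInf) *
        (1 + (params@lambda * g)^params@a)^((params@n - 1) / params@a)
    },
    casson = {
      g <- pmax(g, params@gammaFloor)
      h <- params@hematocrit
      tau0c <- 0.1 * (0.625 * h)^3
      etac <- params@plasmaViscosity * (1 - h)^(-2.5)
      (sqrt(tau0c / g) + sqrt(etac))^2
    },
    herschel_bulkley = {
      g <- pmax(g, params@gammaFloor)
      params@tau0 / g + params@k * (g / params@gammac)^(params@n - 1)
    },
    stop("unknown model")
  )
  if (!is.null(dim(gammaDot))) dim(out) <- dim(gammaDot)
  out
})

#' Shear-rate magnitude of a velocity field
#'
#' Computes the scalar shear rate `sqrt(2 S:S)` (s^-1) from the symmetric
#' part S of the velocity-gradient tensor, using central differences in the
#' interior and one-sided differences at the grid boundary. Velocities are in
#' mm/s and spacing in mm, so the mm cancels and the result is in s^-1.
#'
#' @param velocity 4-D numeric array `(nx, ny, nz, 3)`, mm/s.
#' @param spacing voxel edge length, mm.
#' @return 3-D numeric array of shear-rate magnitudes, s^-1.
#' @export
strainRateMagnitude <- function(velocity, spacing) {
  J <- velocityGradient(velocity, spacing)
  # S_ij = (J_ij + J_ji)/2 ; gamma = sqrt(2 * sum S_ij^2)
  ss <- 0
  for (i in 1:3) for (j in 1:3) {
    sij <- (J[[i]][[j]] + J[[j]][[i]]) / 2
    ss <- ss + sij * sij
  }
  sqrt(2 * ss)
}

# Velocity-gradient components d(v_i)/d(x_j) as a nested list J[[i]][[j]] of
# 3-D arrays. Central differences in the interior, one-sided at the faces.
velocityGradient <- function(velocity, spacing) {
  d <- dim(velocity)
  if (length(d) != 4L || d[4] != 3L)
    stop("velocity must be a (nx, ny, nz, 3) array")
  if (any(d[1:3] < 3L))
    stop("need at least 3 voxels per axis")
  if (any(!is.finite(velocity)))
    stop("velocity must be finite")
  lapply(1:3, function(i) {
    comp <- array(velocity[, , , i], d[1:3])
    lapply(1:3, function(j) axisDerivative(comp, j, spacing))
  })
}

# d(f)/d(axis) with central differences inside, one-sided at the two faces
axisDerivative <- function(f, axis, spacing) {
  d <- dim(f)
  n <- d[axis]
  idx <- function(k) {
    a <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    a[[axis]] <- k
    f[a[[1]], a[[2]], a[[3]], drop = FALSE]
  }
  fwd <- idx(c(2:n, n))      # f[k+1], clamped
  bwd <- idx(c(1, 1:(n - 1)))  # f[k-1], clamped
  den <- array(2 * spacing, d)
  edge <- function(k, val) {
    a <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    a[[axis]] <- k
    den[a[[1]], a[[2]], a[[3]]] <<- val
  }
  edge(1, spacing)
  edge(n, spacing)
  out <- (fwd - bwd) / den
  array(out, d)
}

#' Reynolds number of a pipe flow
#'
#' `Re = 4 rho Q / (pi mu D)` for volumetric flow rate `Q` (m^3/s) through a
#' circular vessel of diameter `D` (m).
#'
#' @param params a [RheologyParams-class] (supplies the density `rho`).
#' @param flowRate volumetric flow rate, m^3/s.
#' @param diameter vessel diameter, m.
#' @param mu dynamic viscosity, Pa s; defaults to the Newtonian `params@mu`.
#' @return dimensionless Reynolds number.
#' @export
reynoldsNumber <- function(params, flowRate, diameter, mu = params@mu) {
  if (diameter <= 0) stop("diameter must be positive")
  if (mu <= 0) stop("viscosity must be positive")
  if (flowRate < 0) stop("flowRate must be non-negative")
  4 * params@rho * flowRate / (pi * mu * diameter)
}
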