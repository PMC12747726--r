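#' @import methods
#' @importFrom stats aov ave coef cor lm median model.matrix quantile rnorm
#'   runif sd t.test var wilcox.test setNames predict
#' @importFrom utils combn read.csv write.csv head
NULL

#' Aneurysm sac domain on a voxel grid
#'
#' An idealised isolated aneurysm: a boolean sac mask on an isotropic voxel
#' grid, the ostium plane separating the sac from the parent-vessel stub, and
#' a triangulation-free wall-node sampling of the sac surface (points with
#' outward unit normals and area weights).
#'
#' @slot sacMask logical 3-D array; `TRUE` inside the sac lumen.
#' @slot spacing isotropic voxel edge length, mm.
#' @slot ostiumPoint,ostiumNormal a point on, and the unit normal of, the
#'   ostium plane (grid coordinates, mm). The normal points into the sac.
#' @slot wallPoints numeric matrix (nodes x 3), mm.
#' @slot wallNormals numeric matrix (nodes x 3), outward unit normals.
#' @slot wallAreas numeric vector of per-node areas, mm^2.
#'
#' @seealso [makeDomain()]
#' @export
setClass("AneurysmDomain",
  representation(
    sacMask = "array",
    spacing = "numeric",
    ostiumPoint = "numeric",
    ostiumNormal = "numeric",
    wallPoints = "matrix",
    wallNormals = "matrix",
    wallAreas = "numeric"
  )
)

setValidity("AneurysmDomain", function(object) {
  msg <- character()
  if (length(dim(object@sacMask)) != 3L)
    msg <- c(msg, "sacMask must be a 3-D array")
  if (!any(object@sacMask))
    msg <- c(msg, "sacMask must contain at least one voxel")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    msg <- c(msg, "spacing must be a single positive number")
  if (abs(sqrt(sum(object@ostiumNormal^2)) - 1) > 1e-8)
    msg <- c(msg, "ostiumNormal must have unit length")
  n <- nrow(object@wallPoints)
  if (nrow(object@wallNormals) != n || length(object@wallAreas) != n)
    msg <- c(msg, "wall node slots must have matching lengths")
  if (length(object@wallAreas) && any(object@wallAreas <= 0))
    msg <- c(msg, "wall node areas must be positive")
  if (length(msg)) msg else TRUE
})

#' Time-resolved velocity field series in a sac
#'
#' Velocity vector fields (mm/s) sampled on the domain grid at strictly
#' increasing times covering one cardiac cycle. Each frame is a 4-D array
#' `(nx, ny, nz, 3)`.
#'
#' @slot frames list of 4-D numeric arrays, velocity in mm/s.
#' @slot times frame timestamps, s.
#' @slot period cardiac cycle length, s (used for the periodic closure of
#'   time integrals).
#' @slot domain the [AneurysmDomain-class] the fields live on.
#'
#' @seealso [makeFlowSeries()]
#' @export
setClass("FlowSeries",
  representation(
    frames = "list",
    times = "numeric",
    period = "numeric",
    domain = "AneurysmDomain"
  )
)

setValidity("FlowSeries", function(object) {
  msg <- character()
  if (length(object@frames) < 2L)
    msg <- c(msg, "need at least 2 frames")
  if (length(object@times) != length(object@frames))
    msg <- c(msg, "times and frames lengths differ")
  if (any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  dm <- dim(object@domain@sacMask)
  ok <- vapply(object@frames, function(f)
    length(dim(f)) == 4L && all(dim(f)[1:3] == dm) && dim(f)[4] == 3L,
    logical(1))
  if (!all(ok))
    msg <- c(msg, "every frame must have shape (nx, ny, nz, 3) matching sacMask")
  if (object@period <= 0 || object@period < max(object@times) - min(object@times))
    msg <- c(msg, "period must be positive and cover the sampled times")
  if (length(msg)) msg else TRUE
})

#' Wall shear-stress vector time series
#'
#' Per-wall-node shear-stress vectors (Pa) over one cardiac cycle, with
#' per-node area weights. `tau` is an array `(nodes, 3, frames)`.
#'
#' @slot tau numeric array (nodes x 3 x frames), Pa.
#' @slot areas per-node area weights, mm^2.
#' @slot times frame timestamps, s.
#' @slot period cycle length, s.
#'
#' @seealso [makeWallShear()], [wallShearFromFlow()]
#' @export
setClass("WallShearSeries",
  representation(
    tau = "array",
    areas = "numeric",
    times = "numeric",
    period = "numeric"
  )
)

setValidity("WallShearSeries", function(object) {
  msg <- character()
  d <- dim(object@tau)
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "tau must be a (nodes x 3 x frames) array")
  else {
    if (d[1] != length(object@areas))
      msg <- c(msg, "areas length must match node count")
    if (d[3] != length(object@times))
      msg <- c(msg, "times length must match frame count")
    if (d[3] < 2L)
      msg <- c(msg, "need at least 2 frames")
  }
  if (!all(is.finite(object@tau)))
    msg <- c(msg, "tau must be finite")
  if (sum(object@areas) <= 0)
    msg <- c(msg, "areas must sum to a positive total")
  if (any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Vortex-region mask series
#'
#' Per-frame boolean vortex masks obtained by thresholding the lambda2 field,
#' together with the lambda2 fields themselves and the threshold used.
#'
#' @slot masks list of logical 3-D arrays.
#' @slot lambda2 list of numeric 3-D arrays, s^-2.
#' @slot threshold lambda2 cutoff used (vortex where lambda2 < threshold).
#'
#' @seealso [extractVortexMask()], [dvo()], [vortexVolumeFraction()]
#' @export
setClass("VortexSeries",
  representation(
    masks = "list",
    lambda2 = "list",
    threshold = "numeric"
  )
)

setValidity("VortexSeries", function(object) {
  msg <- character()
  if (length(object@masks) < 1L)
    msg <- c(msg, "need at least one frame")
  if (length(object@lambda2) != length(object@masks))
    msg <- c(msg, "lambda2 and masks lengths differ")
  if (length(msg)) msg else TRUE
})

#' Gray-level direction-encoded volume
#'
#' The directional velocity-informatics encoding: per-voxel angle between the
#' local velocity and the inflow-jet direction, mapped linearly to gray
#' levels 0-255. After [quantizeGray()], `levels` carries the 1..nLevels
#' labels used by the matrix (GLCM/GLRLM/GLSZM) features; first-order
#' features always use the raw 0-255 gray.
#'
#' @slot gray integer 3-D array with values in 0..255.
#' @slot mask logical 3-D array of valid voxels.
#' @slot levels integer 3-D array of quantized levels (0 where unquantized).
#' @slot nLevels quantization level count (0 before quantization).
#'
#' @seealso [encodeDirection()], [quantizeGray()]
#' @export
setClass("GrayVolume",
  representation(
    gray = "array",
    mask = "array",
    levels = "array",
    nLevels = "integer"
  )
)

setValidity("GrayVolume", function(object) {
  msg <- character()
  g <- object@gray[object@mask]
  if (length(g) == 0L)
    msg <- c(msg, "mask must select at least one voxel")
  else if (min(g) < 0 || max(g) > 255)
    msg <- c(msg, "gray values must lie in [0, 255]")
  if (!identical(dim(object@gray), dim(object@mask)))
    msg <- c(msg, "gray and mask dimensions differ")
  if (length(msg)) msg else TRUE
})

#' Blood rheology parameters
#'
#' Parameters of one viscosity law. Defaults are the standard arterial blood
#' values: Newtonian mu = 0.004 Pa s; Carreau-Yasuda eta0 = 0.16 Pa s,
#' etaInf = 0.004 Pa s, lambda = 8.2 s, a = 0.64, n = 0.2128;
#' Herschel-Bulkley tau0 = 0.01 Pa, k = 0.04, n = 0.7, gammac = 0.001 s^-1;
#' Casson closure from hematocrit 0.40 and plasma viscosity 1.4 mPa s
#' (Merrill parameterisation, see [viscosity()]).
#'
#' @slot model one of `"newtonian"`, `"carreau_yasuda"`, `"casson"`,
#'   `"herschel_bulkley"`.
#' @slot mu Newtonian dynamic viscosity, Pa s.
#' @slot eta0,etaInf zero- and infinite-shear viscosities, Pa s.
#' @slot lambda Carreau-Yasuda time constant, s.
#' @slot a Yasuda exponent.
#' @slot n power-law index (Carreau-Yasuda or Herschel-Bulkley, by model).
#' @slot tau0 yield stress, Pa.
#' @slot k consistency index, kg s^(n-2) m^-1.
#' @slot gammac critical shear rate, s^-1.
#' @slot hematocrit red-cell volume fraction.
#' @slot plasmaViscosity plasma viscosity, Pa s.
#' @slot rho blood density, kg m^-3.
#' @slot gammaFloor shear-rate floor applied to the diverging Casson and
#'   Herschel-Bulkley laws as the shear rate tends to zero, s^-1.
#'
#' @seealso [rheologyParams()], [viscosity()]
#' @export
setClass("RheologyParams",
  representation(
    model = "character",
    mu = "numeric",
    eta0 = "numeric",
    etaInf = "numeric",
    lambda = "numeric",
    a = "numeric",
    n = "numeric",
    tau0 = "numeric",
    k = "numeric",
    gammac = "numeric",
    hematocrit = "numeric",
    plasmaViscosity = "numeric",
    rho = "numeric",
    gammaFloor = "numeric"
  ),
  prototype(
    model = "newtonian",
    mu = 0.004,
    eta0 = 0.16,
    etaInf = 0.004,
    lambda = 8.2,
    a = 0.64,
    n = 0.2128,
    tau0 = 0.01,
    k = 0.04,
    gammac = 0.001,
    hematocrit = 0.40,
    plasmaViscosity = 0.0014,
    rho = 1050,
    gammaFloor = 1e-6
  )
)

setValidity("RheologyParams", function(object) {
  msg <- character()
  if (!object@model %in% c("newtonian", "carreau_yasuda", "casson", "herschel_bulkley"))
    msg <- c(msg, "unknown model")
  pos <- c(mu = object@mu, eta0 = object@eta0, etaInf = object@etaInf,
           lambda = object@lambda, a = object@a, gammac = object@gammac,
           plasmaViscosity = object@plasmaViscosity, rho = object@rho,
           gammaFloor = object@gammaFloor)
  if (any(pos <= 0))
    msg <- c(msg, paste("must be positive:", paste(names(pos)[pos <= 0], collapse = ", ")))
  if (object@hematocrit <= 0 || object@hematocrit >= 1)
    msg <- c(msg, "hematocrit must lie in (0, 1)")
  if (object@eta0 < object@etaInf)
    msg <- c(msg, "eta0 must be >= etaInf")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AneurysmDomain", function(object) {
  d <- dim(object@sacMask)
  cat(sprintf("AneurysmDomain: %d x %d x %d grid @ %.3g mm, %d sac voxels, %d wall nodes\n",
              d[1], d[2], d[3], object@spacing, sum(object@sacMask),
              nrow(object@wallPoints)))
})

setMethod("show", "FlowSeries", function(object) {
  cat(sprintf("FlowSeries: %d frames over %.3g s on a %s grid\n",
              length(object@frames), object@period,
              paste(dim(object@domain@sacMask), collapse = " x ")))
})

setMethod("show", "WallShearSeries", function(object) {
  d <- dim(object@tau)
  cat(sprintf("WallShearSeries: %d nodes x %d frames over %.3g s\n",
              d[1], d[3], object@period))
})

setMethod("show", "VortexSeries", function(object) {
  vol <- vapply(object@masks, sum, numeric(1))
  cat(sprintf("VortexSeries: %d frames, vortex voxels %d-%d (lambda2 < %g)\n",
              length(object@masks), min(vol), max(vol), object@threshold))
})

setMethod("show", "GrayVolume", function(object) {
  cat(sprintf("GrayVolume: %s grid, %d masked voxels%s\n",
              paste(dim(object@gray), collapse = " x "), sum(object@mask),
              if (object@nLevels > 0L)
                sprintf(", quantized to %d levels", object@nLevels) else ""))
})

setMethod("show", "RheologyParams", function(object) {
  cat(sprintf("RheologyParams: %s (rho = %g kg/m^3)\n", object@model, object@rho))
})

# ---- accessors ----

#' @rdname AneurysmDomain-class
#' @param domain an `AneurysmDomain`.
#' @export
sacMask <- function(domain) domain@sacMask

#' @rdname AneurysmDomain-class
#' @export
voxelSpacing <- function(domain) domain@spacing

#' @rdname AneurysmDomain-class
#' @export
wallAreas <- function(domain) domain@wallAreas

#' @rdname FlowSeries-class
#' @param x a `FlowSeries` or `WallShearSeries`.
#' @export
frameTimes <- function(x) x@times

#' @rdname FlowSeries-class
#' @param series a `FlowSeries`.
#' @param i frame index.
#' @export
velocityFrame <- function(series, i) series@frames[[i]]

#' @rdname FlowSeries-class
#' @export
nFrames <- function(x) {
  if (is(x, "FlowSeries")) length(x@frames)
  else if (is(x, "WallShearSeries")) dim(x@tau)[3]
  else if (is(x, "VortexSeries")) length(x@masks)
  else stop("unsupported class")
}

#' @rdname FlowSeries-class
#' @export
flowDomain <- function(series) series@domain
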