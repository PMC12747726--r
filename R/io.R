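# Container I/O: a native directory container (gzip-compressed
# full-precision CSV arrays plus JSON metadata) for flow and wall-shear
# series, and legacy VTK structured-points ASCII export/import for visual
# inspection in ParaView-class tools.

fmtNum <- function(x) sprintf("%.17g", x)

writeGzLines <- function(lines, path) {
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
}

readGzLines <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  readLines(con)
}

#' Write a flow series to the native container
#'
#' The container is a directory holding `meta.json` (grid, times, period,
#' ostium plane, provenance) plus gzip-compressed CSV arrays: the sac mask,
#' the wall nodes, and one velocity file per frame. Values are written with
#' 17 significant digits so a read round-trip is bit-exact.
#'
#' @param series a [FlowSeries-class].
#' @param path container directory (created if needed).
#' @return `path`, invisibly.
#' @export
writeFlowSeries <- function(series, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  dom <- series@domain
  meta <- list(type = "FlowSeries", dim = dim(dom@sacMask),
               spacing = dom@spacing, times = series@times,
               period = series@period, ostiumPoint = dom@ostiumPoint,
               ostiumNormal = dom@ostiumNormal,
               nWallNodes = nrow(dom@wallPoints), units = "mm/s",
               package = "sacflow")
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = I(17))
  writeGzLines(as.character(as.integer(dom@sacMask)),
               file.path(path, "sac_mask.csv.gz"))
  wn <- cbind(dom@wallPoints, dom@wallNormals, dom@wallAreas)
  writeGzLines(apply(wn, 1, function(r) paste(fmtNum(r), collapse = ",")),
               file.path(path, "wall_nodes.csv.gz"))
  for (i in seq_along(series@frames)) {
    f <- series@frames[[i]]
    m <- cbind(as.numeric(f[, , , 1]), as.numeric(f[, , , 2]),
               as.numeric(f[, , , 3]))
    writeGzLines(paste(fmtNum(m[, 1]), fmtNum(m[, 2]), fmtNum(m[, 3]),
                       sep = ","),
                 file.path(path, sprintf("frame_%03d.csv.gz", i)))
  }
  invisible(path)
}

#' Read a flow series from the native container
#'
#' @param path container directory written by [writeFlowSeries()].
#' @return A [FlowSeries-class].
#' @export
readFlowSeries <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$type, "FlowSeries")) stop("not a FlowSeries container")
  d <- as.integer(meta$dim)
  mask <- array(as.integer(readGzLines(file.path(path, "sac_mask.csv.gz"))) == 1L, d)
  wn <- do.call(rbind, lapply(
    strsplit(readGzLines(file.path(path, "wall_nodes.csv.gz")), ","),
    as.numeric))
  dom <- new("AneurysmDomain", sacMask = mask, spacing = meta$spacing,
             ostiumPoint = as.numeric(meta$ostiumPoint),
             ostiumNormal = as.numeric(meta$ostiumNormal),
             wallPoints = wn[, 1:3, drop = FALSE],
             wallNormals = wn[, 4:6, drop = FALSE],
             wallAreas = wn[, 7])
  files <- sort(list.files(path, pattern = "^frame_\\d+\\.csv\\.gz$"))
  frames <- lapply(files, function(fn) {
    m <- do.call(rbind, lapply(strsplit(readGzLines(file.path(path, fn)), ","),
                               as.numeric))
    if (nrow(m) != prod(d)) stop("frame size mismatch in ", fn)
    array(c(m[, 1], m[, 2], m[, 3]), c(d, 3))
  })
  new("FlowSeries", frames = frames, times = as.numeric(meta$times),
      period = meta$period, domain = dom)
}

#' Write a wall shear series to the native container
#'
#' @param ws a [WallShearSeries-class].
#' @param path container directory.
#' @return `path`, invisibly.
#' @export
writeWallShearSeries <- function(ws, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(ws@tau)
  meta <- list(type = "WallShearSeries", nNodes = d[1], nFrames = d[3],
               times = ws@times, period = ws@period, units = "Pa",
               package = "sacflow")
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = I(17))
  writeGzLines(fmtNum(ws@areas), file.path(path, "areas.csv.gz"))
  writeGzLines(fmtNum(as.numeric(ws@tau)), file.path(path, "tau.csv.gz"))
  invisible(path)
}

#' Read a wall shear series from the native container
#'
#' @param path container directory written by [writeWallShearSeries()].
#' @return A [WallShearSeries-class].
#' @export
readWallShearSeries <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$type, "WallShearSeries"))
    stop("not a WallShearSeries container")
  tau <- array(as.numeric(readGzLines(file.path(path, "tau.csv.gz"))),
               c(meta$nNodes, 3, meta$nFrames))
  new("WallShearSeries", tau = tau,
      areas = as.numeric(readGzLines(file.path(path, "areas.csv.gz"))),
      times = as.numeric(meta$times), period = meta$period)
}

#' Export a volume to legacy VTK structured points (ASCII)
#'
#' Accepts a 3-D scalar array (written as `SCALARS`) or a `(nx,ny,nz,3)`
#' vector array (written as `VECTORS`). Column-major voxel order matches
#' the VTK x-fastest convention.
#'
#' @param data 3-D or 4-D numeric array.
#' @param path output file.
#' @param spacing voxel size, mm.
#' @param origin grid origin, mm.
#' @param name data array name in the file.
#' @return `path`, invisibly.
#' @export
writeVTKStructuredPoints <- function(data, path, spacing = 1,
                                     origin = c(0, 0, 0), name = "field") {
  d <- dim(data)
  vec <- length(d) == 4L
  if (vec && d[4] != 3L) stop("vector data must have 3 components")
  if (!vec && length(d) != 3L) stop("data must be a 3-D or (nx,ny,nz,3) array")
  hdr <- c("# vtk DataFile Version 3.0", name, "ASCII",
           "DATASET STRUCTURED_POINTS",
           paste("DIMENSIONS", d[1], d[2], d[3]),
           paste("ORIGIN", fmtNum(origin[1]), fmtNum(origin[2]), fmtNum(origin[3])),
           paste("SPACING", fmtNum(spacing), fmtNum(spacing), fmtNum(spacing)),
           paste("POINT_DATA", prod(d[1:3])))
  if (vec) {
    body <- c(paste("VECTORS", name, "double"),
              paste(fmtNum(as.numeric(data[, , , 1])),
                    fmtNum(as.numeric(data[, , , 2])),
                    fmtNum(as.numeric(data[, , , 3]))))
  } else {
    body <- c(paste("SCALARS", name, "double 1"), "LOOKUP_TABLE default",
              fmtNum(as.numeric(data)))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Import a legacy VTK structured-points (ASCII) file
#'
#' Reads files written by [writeVTKStructuredPoints()] (one `SCALARS` or
#' `VECTORS` point-data array).
#'
#' @param path VTK file path.
#' @return list with `data` (3-D or 4-D array), `spacing`, `origin`,
#'   `name`.
#' @export
readVTKStructuredPoints <- function(path) {
  lines <- readLines(path)
  getLine <- function(key) {
    hit <- grep(paste0("^", key, " "), lines, value = TRUE)[1]
    if (is.na(hit)) stop("missing ", key, " in VTK file")
    strsplit(hit, " +")[[1]][-1]
  }
  if (!any(grepl("^DATASET STRUCTURED_POINTS", lines)))
    stop("not a structured-points VTK file")
  d <- as.integer(getLine("DIMENSIONS"))
  origin <- as.numeric(getLine("ORIGIN"))
  spacing <- as.numeric(getLine("SPACING"))[1]
  n <- prod(d)
  vecAt <- grep("^VECTORS ", lines)
  if (length(vecAt)) {
    name <- strsplit(lines[vecAt[1]], " +")[[1]][2]
    vals <- do.call(rbind, lapply(strsplit(lines[(vecAt[1] + 1):(vecAt[1] + n)],
                                           " +"), as.numeric))
    data <- array(c(vals[, 1], vals[, 2], vals[, 3]), c(d, 3))
  } else {
    scAt <- grep("^SCALARS ", lines)
    if (!length(scAt)) stop("no point data found")
    name <- strsplit(lines[scAt[1]], " +")[[1]][2]
    data <- array(as.numeric(lines[(scAt[1] + 2):(scAt[1] + 1 + n)]), d)
  }
  list(data = data, spacing = spacing, origin = origin, name = name)
}

#' Write a cohort table as CSV with a provenance header
#'
#' Comment lines (`#`) record the package version, seed and a configuration
#' fingerprint; the table follows as plain CSV. [readCohortCsv()] reads it
#' back.
#'
#' @param cohort cohort data.frame (see [makeCohort()]).
#' @param path output file.
#' @param provenance optional named list recorded in the header.
#' @return `path`, invisibly.
#' @export
writeCohortCsv <- function(cohort, path, provenance = list()) {
  hdr <- c(paste0("# sacflow cohort v",
                  as.character(utils::packageVersion("sacflow"))),
           vapply(names(provenance), function(k)
             paste0("# ", k, ": ", provenance[[k]]), character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(cohort, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortCsv
#' @export
readCohortCsv <- function(path) {
  out <- read.csv(path, comment.char = "#", check.names = FALSE)
  out$label <- factor(out$label, levels = c("unruptured", "ruptured"))
  out$location <- factor(out$location, levels = c("ICA", "MCA", "ACA"))
  out
}
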