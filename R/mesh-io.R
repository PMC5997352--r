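#' Write a mesh in the CARP-style dialect
#'
#' Writes \code{<basename>.pts} (first line node count, then "x y z" per
#' line, mm), \code{<basename>.elem} (first line element count, then
#' "Tr n1 n2 n3 tag" with 0-based indices; the tag is the region code of the
#' element's first corner), \code{<basename>.lon} (one "fx fy fz" per
#' element) and \code{<basename>.regions.json} (region name map, per-node
#' labels, layers, rims and interlayer pairs). Coordinates are written in
#' single precision.
#'
#' @param mesh a \code{\linkS4class{SurfaceMesh}}.
#' @param basename path prefix for the four files.
#' @return invisibly, the paths written
#' @export
writeMesh <- function(mesh, basename) {
  pts <- paste0(basename, ".pts")
  elem <- paste0(basename, ".elem")
  lon <- paste0(basename, ".lon")
  rj <- paste0(basename, ".regions.json")
  con <- file(pts, "w")
  writeLines(as.character(nNodes(mesh)), con)
  writeLines(sprintf("%.8g %.8g %.8g", mesh@nodes[, 1], mesh@nodes[, 2],
                     mesh@nodes[, 3]), con)
  close(con)
  con <- file(elem, "w")
  writeLines(as.character(nElements(mesh)), con)
  tag <- mesh@nodeRegion[mesh@triangles[, 1]]
  writeLines(sprintf("Tr %d %d %d %d", mesh@triangles[, 1] - 1L,
                     mesh@triangles[, 2] - 1L, mesh@triangles[, 3] - 1L,
                     tag), con)
  close(con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh@fibers[, 1], mesh@fibers[, 2],
                     mesh@fibers[, 3]), lon)
  meta <- list(regionCodes = as.list(REGION_CODES),
               nodeRegion = mesh@nodeRegion,
               layerOfNode = mesh@layerOfNode,
               interlayerPairs = mesh@interlayerPairs,
               rims = mesh@rims)
  jsonlite::write_json(meta, rj, auto_unbox = TRUE, digits = NA)
  invisible(c(pts, elem, lon, rj))
}

#' Read a mesh written by \code{\link{writeMesh}}
#'
#' @param basename path prefix of the \code{.pts/.elem/.lon} files; a
#'   \code{.regions.json} sidecar is used when present, otherwise regions
#'   are taken from the element tags.
#' @return a \code{\linkS4class{SurfaceMesh}}
#' @export
readMesh <- function(basename) {
  pts <- paste0(basename, ".pts")
  elem <- paste0(basename, ".elem")
  lon <- paste0(basename, ".lon")
  rj <- paste0(basename, ".regions.json")
  ptsLines <- readLines(pts)
  n <- suppressWarnings(as.integer(ptsLines[1]))
  if (is.na(n) || length(ptsLines) < n + 1)
    stop("malformed .pts file: bad node count at line 1")
  co <- matrix(scan(text = ptsLines[2:(n + 1)], quiet = TRUE), ncol = 3,
               byrow = TRUE)
  elLines <- readLines(elem)
  m <- suppressWarnings(as.integer(elLines[1]))
  if (is.na(m) || length(elLines) < m + 1)
    stop("malformed .elem file: bad element count at line 1")
  tri <- matrix(0L, m, 3)
  tags <- integer(m)
  for (i in seq_len(m)) {
    f <- strsplit(trimws(elLines[i + 1]), "\\s+")[[1]]
    if (length(f) < 4 || f[1] != "Tr")
      stop("malformed .elem file at line ", i + 1)
    idx <- suppressWarnings(as.integer(f[2:4]))
    if (anyNA(idx) || any(idx < 0) || any(idx >= n))
      stop("node index out of range in .elem file at line ", i + 1)
    tri[i, ] <- idx + 1L
    tags[i] <- if (length(f) >= 5) as.integer(f[5]) else 0L
  }
  fib <- matrix(scan(lon, quiet = TRUE), ncol = 3, byrow = TRUE)
  if (nrow(fib) != m) stop("fiber count does not match element count")
  # coordinates are single precision on disk; re-project fibers onto the
  # (slightly perturbed) element planes so mesh invariants hold exactly
  fib <- unname(.projectFibers(co, tri, fib))
  if (file.exists(rj)) {
    meta <- jsonlite::read_json(rj, simplifyVector = TRUE)
    region <- as.integer(meta$nodeRegion)
    layer <- as.integer(meta$layerOfNode)
    ip <- if (length(meta$interlayerPairs))
      matrix(as.integer(unlist(meta$interlayerPairs)), ncol = 2)
    else matrix(integer(0), 0, 2)
    rims <- lapply(meta$rims, function(r)
      list(junction = as.integer(r$junction), distal = as.integer(r$distal)))
  } else {
    region <- rep(REGION_CODES[["LA_BODY"]], n)
    for (i in seq_len(m)) region[tri[i, ]] <- tags[i]
    layer <- rep(1L, n)
    ip <- matrix(integer(0), 0, 2)
    rims <- list()
  }
  new("SurfaceMesh", nodes = co, triangles = tri, fibers = fib,
      nodeRegion = region, layerOfNode = layer, interlayerPairs = ip,
      rims = rims)
}

#' Export a mesh (with optional fields) as legacy ASCII VTK polydata
#'
#' @param mesh a \code{\linkS4class{SurfaceMesh}}.
#' @param path output \code{.vtk} file.
#' @param nodeFields named list of per-node numeric vectors.
#' @param cellFields named list of per-element numeric vectors.
#' @return invisibly, \code{path}
#' @export
writeVtk <- function(mesh, path, nodeFields = list(), cellFields = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nNodes(mesh); m <- nElements(mesh)
  writeLines(c("# vtk DataFile Version 3.0", "atrialab surface mesh",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", n)), con)
  writeLines(sprintf("%.6g %.6g %.6g", mesh@nodes[, 1], mesh@nodes[, 2],
                     mesh@nodes[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", m, 4 * m), con)
  writeLines(sprintf("3 %d %d %d", mesh@triangles[, 1] - 1L,
                     mesh@triangles[, 2] - 1L, mesh@triangles[, 3] - 1L),
             con)
  nodeFields <- c(list(region = as.numeric(mesh@nodeRegion)), nodeFields)
  writeLines(sprintf("POINT_DATA %d", n), con)
  for (nm in names(nodeFields)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm),
                 "LOOKUP_TABLE default"), con)
    v <- nodeFields[[nm]]
    v[is.na(v)] <- -1
    writeLines(sprintf("%.6g", v), con)
  }
  cellFields <- c(list(fiber = NULL), cellFields)
  writeLines(sprintf("CELL_DATA %d", m), con)
  writeLines(c("VECTORS fiber float"), con)
  writeLines(sprintf("%.6g %.6g %.6g", mesh@fibers[, 1], mesh@fibers[, 2],
                     mesh@fibers[, 3]), con)
  for (nm in setdiff(names(cellFields), "fiber")) {
    writeLines(c(sprintf("SCALARS %s float 1", nm),
                 "LOOKUP_TABLE default"), con)
    v <- cellFields[[nm]]
    v[is.na(v)] <- -1
    writeLines(sprintf("%.6g", v), con)
  }
  invisible(path)
}

#' Write / read a voltage record
#'
#' On-disk layout: a JSON header (node count, sample count, sample interval,
#' start time, metadata) next to a flat little-endian float32 file of
#' node-major frames.
#'
#' @param record a \code{\linkS4class{VoltageRecord}}.
#' @param basename path prefix (\code{.header.json} + \code{.f32} written).
#' @return invisibly, the paths written
#' @export
writeVoltageRecord <- function(record, basename) {
  hdr <- paste0(basename, ".header.json")
  dat <- paste0(basename, ".f32")
  jsonlite::write_json(list(nNode = ncol(record@V), nTime = nrow(record@V),
                            sampleInterval = record@sampleInterval,
                            t0 = record@times[1], meta = record@meta),
                       hdr, auto_unbox = TRUE, digits = NA)
  con <- file(dat, "wb")
  writeBin(as.vector(t(record@V)), con, size = 4L, endian = "little")
  close(con)
  invisible(c(hdr, dat))
}

#' @rdname writeVoltageRecord
#' @param basename path prefix used by \code{writeVoltageRecord}
#' @export
readVoltageRecord <- function(basename) {
  hdr <- jsonlite::read_json(paste0(basename, ".header.json"),
                             simplifyVector = TRUE)
  con <- file(paste0(basename, ".f32"), "rb")
  x <- readBin(con, "numeric", n = hdr$nNode * hdr$nTime, size = 4L,
               endian = "little")
  close(con)
  V <- matrix(x, nrow = hdr$nTime, ncol = hdr$nNode, byrow = TRUE)
  new("VoltageRecord", V = V,
      times = hdr$t0 + hdr$sampleInterval * (seq_len(hdr$nTime) - 1),
      sampleInterval = hdr$sampleInterval,
      meta = if (is.null(hdr$meta)) list() else as.list(hdr$meta))
}
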