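#' Region label codes
#'
#' Integer codes used in the \code{nodeRegion} slot of a
#' \code{\linkS4class{SurfaceMesh}}. The codes cover the left-atrial body,
#' appendage, right atrium, sinoatrial-node patch, the four pulmonary veins
#' and the two PVI lesion bands (one encircling each ipsilateral vein pair).
#'
#' @format Named integer vector.
#' @export
REGION_CODES <- c(
  LA_BODY = 1L, LAA = 2L, RA = 3L, SAN = 4L,
  LSPV = 11L, LIPV = 12L, RSPV = 13L, RIPV = 14L,
  PVI_LESION_L = 21L, PVI_LESION_R = 22L
)

#' Names of the four pulmonary veins
#' @export
PV_NAMES <- c("LSPV", "LIPV", "RSPV", "RIPV")

.regionName <- function(code) names(REGION_CODES)[match(code, REGION_CODES)]

#' SurfaceMesh: a triangulated atrial surface
#'
#' Triangulated open surface with per-element fiber vectors and per-node
#' region labels. Coordinates are in millimetres. A bilayer mesh carries two
#' resistively coupled layers (endocardium and epicardium) in the same node
#' set, linked by \code{interlayerPairs}.
#'
#' @slot nodes numeric matrix (n x 3), node coordinates in mm.
#' @slot triangles integer matrix (m x 3), 1-based node indices; corner order
#'   fixes the surface orientation used for phase-singularity chirality.
#' @slot fibers numeric matrix (m x 3), per-element unit fiber vectors lying
#'   in the element plane.
#' @slot nodeRegion integer vector (n), codes from \code{\link{REGION_CODES}}.
#' @slot layerOfNode integer vector (n), 1 = endo, 2 = epi.
#' @slot interlayerPairs integer matrix (k x 2), endo/epi coupling pairs.
#' @slot rims named list, per-vein \code{list(junction=, distal=)} node-index
#'   vectors marking the closed rim loops.
#'
#' @export
setClass("SurfaceMesh", slots = c(
  nodes = "matrix",
  triangles = "matrix",
  fibers = "matrix",
  nodeRegion = "integer",
  layerOfNode = "integer",
  interlayerPairs = "matrix",
  rims = "list"
))

setValidity("SurfaceMesh", function(object) {
  n <- nrow(object@nodes)
  tri <- object@triangles
  msgs <- character()
  if (ncol(object@nodes) != 3) msgs <- c(msgs, "nodes must be n x 3")
  if (ncol(tri) != 3) msgs <- c(msgs, "triangles must be m x 3")
  if (length(tri) && (min(tri) < 1L || max(tri) > n))
    msgs <- c(msgs, "triangle indices out of range")
  if (nrow(object@fibers) != nrow(tri))
    msgs <- c(msgs, "one fiber vector per element required")
  if (length(object@nodeRegion) != n)
    msgs <- c(msgs, "one region label per node required")
  if (length(object@layerOfNode) != n)
    msgs <- c(msgs, "one layer label per node required")
  if (nrow(object@fibers)) {
    nrm <- sqrt(rowSums(object@fibers^2))
    if (any(abs(nrm - 1) > 1e-9))
      msgs <- c(msgs, "fiber vectors must have unit norm (tol 1e-9)")
    # in-plane check: |fiber . normal| small
    p1 <- object@nodes[tri[, 1], , drop = FALSE]
    e1 <- object@nodes[tri[, 2], , drop = FALSE] - p1
    e2 <- object@nodes[tri[, 3], , drop = FALSE] - p1
    nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    nn <- sqrt(nx^2 + ny^2 + nz^2)
    sine <- abs(object@fibers[, 1] * nx + object@fibers[, 2] * ny +
                  object@fibers[, 3] * nz) / pmax(nn, 1e-300)
    if (any(sine > 1e-6))
      msgs <- c(msgs, "fiber vectors must lie in their element plane")
  }
  if (nrow(object@interlayerPairs)) {
    ip <- object@interlayerPairs
    if (any(object@layerOfNode[ip[, 1]] == object@layerOfNode[ip[, 2]]))
      msgs <- c(msgs, "interlayer pairs must link nodes in different layers")
  }
  # edge-manifold: every undirected edge in at most two triangles
  if (nrow(tri)) {
    ed <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
    key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    if (any(tabulate(factor(key)) > 2))
      msgs <- c(msgs, "mesh is not edge-manifold")
  }
  if (length(msgs)) msgs else TRUE
})

#' ScalarNodeField: a per-node scalar field
#'
#' Values are \code{NA} outside the field's domain (e.g. the ostial-distal
#' distance parameter is defined only on its vein).
#'
#' @slot values numeric vector, one value per mesh node (NA = undefined).
#' @slot name character, what the field measures.
#' @export
setClass("ScalarNodeField", slots = c(values = "numeric", name = "character"))

#' ConductivityField: per-element conductivities and decoupled edges
#'
#' @slot sigmaL numeric, longitudinal conductivity per element (S/m).
#' @slot sigmaT numeric, transverse conductivity per element (S/m).
#' @slot beta numeric(1), surface-to-volume ratio (1/m).
#' @slot cm numeric(1), membrane capacitance (F/m^2).
#' @slot interlayerG numeric(1), interlayer coupling rate (1/ms) applied to
#'   each coupling pair (bilayer meshes only).
#' @slot decoupledEdges integer matrix (k x 2), mesh edges carrying no-flux
#'   interstitial-fibrosis barriers.
#' @export
setClass("ConductivityField", slots = c(
  sigmaL = "numeric", sigmaT = "numeric",
  beta = "numeric", cm = "numeric", interlayerG = "numeric",
  decoupledEdges = "matrix"
))

setValidity("ConductivityField", function(object) {
  if (any(object@sigmaL < 0) || any(object@sigmaT < 0))
    return("conductivities must be non-negative")
  TRUE
})

#' VoltageRecord: transmembrane voltage sampled on all nodes
#'
#' @slot V numeric matrix (ntime x nnode), voltage in mV.
#' @slot times numeric vector (ntime), sample times in ms.
#' @slot sampleInterval numeric(1), ms between samples.
#' @slot meta list, simulation metadata (dt, model, seed, config hash,
#'   stimulus schedule, early-stop information).
#' @export
setClass("VoltageRecord", slots = c(
  V = "matrix", times = "numeric", sampleInterval = "numeric", meta = "list"
))

setValidity("VoltageRecord", function(object) {
  if (nrow(object@V) != length(object@times))
    return("one time per sample row required")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  TRUE
})

#' EdgeSet: mesh edges selected as interstitial-fibrosis barriers
#'
#' @slot edges integer matrix (k x 2), node-index pairs (min index first).
#' @slot seed integer(1), generating seed.
#' @slot params list, selection parameters (base density, anisotropy factor,
#'   weighting field id, clamping report).
#' @export
setClass("EdgeSet", slots = c(edges = "matrix", seed = "integer",
                              params = "list"))

setValidity("EdgeSet", function(object) {
  e <- object@edges
  if (nrow(e)) {
    if (any(e[, 1] >= e[, 2])) return("edges must be stored (min,max)")
    if (anyDuplicated(paste(e[, 1], e[, 2]))) return("duplicate edges")
  }
  TRUE
})

# ---- show methods ---------------------------------------------------------

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d nodes, %d triangles, %d layer(s)\n",
              nrow(object@nodes), nrow(object@triangles),
              length(unique(object@layerOfNode))))
  tab <- table(.regionName(object@nodeRegion))
  cat("  regions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (length(object@rims))
    cat("  veins with rims:", paste(names(object@rims), collapse = ", "), "\n")
  if (nrow(object@interlayerPairs))
    cat("  interlayer pairs:", nrow(object@interlayerPairs), "\n")
})

setMethod("show", "ScalarNodeField", function(object) {
  v <- object@values
  cat(sprintf("ScalarNodeField '%s': %d nodes (%d defined), range [%g, %g]\n",
              object@name, length(v), sum(!is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
})

setMethod("show", "ConductivityField", function(object) {
  cat(sprintf(
    "ConductivityField: %d elements, sigma_l [%g, %g] S/m, sigma_t [%g, %g] S/m\n",
    length(object@sigmaL), min(object@sigmaL), max(object@sigmaL),
    min(object@sigmaT), max(object@sigmaT)))
  cat(sprintf("  beta = %g 1/m, Cm = %g F/m^2, decoupled edges: %d\n",
              object@beta, object@cm, nrow(object@decoupledEdges)))
})

setMethod("show", "VoltageRecord", function(object) {
  cat(sprintf(
    "VoltageRecord: %d nodes x %d samples, every %g ms, t in [%g, %g] ms\n",
    ncol(object@V), nrow(object@V), object@sampleInterval,
    min(object@times), max(object@times)))
  if (!is.null(object@meta$model)) cat("  model:", object@meta$model, "\n")
})

setMethod("show", "EdgeSet", function(object) {
  cat(sprintf("EdgeSet: %d edges (seed %d)\n", nrow(object@edges),
              object@seed))
})

# ---- accessors ------------------------------------------------------------

#' @rdname SurfaceMesh-class
#' @param mesh,object a \code{SurfaceMesh}
#' @export
nNodes <- function(mesh) nrow(mesh@nodes)

#' @rdname SurfaceMesh-class
#' @export
nElements <- function(mesh) nrow(mesh@triangles)

#' @rdname SurfaceMesh-class
#' @export
nodeCoords <- function(mesh) mesh@nodes

#' @rdname SurfaceMesh-class
#' @export
meshTriangles <- function(mesh) mesh@triangles

#' @rdname SurfaceMesh-class
#' @export
meshFibers <- function(mesh) mesh@fibers

#' @rdname SurfaceMesh-class
#' @export
nodeRegion <- function(mesh) mesh@nodeRegion

#' @rdname SurfaceMesh-class
#' @export
veinRims <- function(mesh) mesh@rims

#' Nodes belonging to a named region
#' @param mesh a \code{SurfaceMesh}
#' @param region region name (see \code{\link{REGION_CODES}})
#' @return integer vector of node indices
#' @export
regionNodes <- function(mesh, region) {
  code <- REGION_CODES[[region]]
  which(mesh@nodeRegion == code)
}

#' @rdname VoltageRecord-class
#' @param record a \code{VoltageRecord}
#' @export
voltage <- function(record) record@V

#' @rdname VoltageRecord-class
#' @export
sampleTimes <- function(record) record@times

#' @rdname EdgeSet-class
#' @param es an \code{EdgeSet}
#' @export
edgePairs <- function(es) es@edges

#' Field values of a ScalarNodeField
#' @param field a \code{ScalarNodeField}
#' @export
fieldValues <- function(field) field@values

# internal constructors
.newField <- function(values, name) new("ScalarNodeField",
                                        values = as.numeric(values),
                                        name = name)

#' Per-element mean edge length of a mesh
#' @param mesh a \code{SurfaceMesh}
#' @return mean length (mm) over the unique mesh edges
#' @export
meanEdgeLength <- function(mesh) {
  e <- uniqueEdges(mesh)
  d <- mesh@nodes[e[, 1], , drop = FALSE] - mesh@nodes[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Unique undirected edges of a mesh
#' @param mesh a \code{SurfaceMesh}
#' @return integer matrix (k x 2), each row (min,max) node indices
#' @export
uniqueEdges <- function(mesh) {
  tri <- mesh@triangles
  ed <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  ed <- ed[!duplicated(ed %*% c(1, nrow(mesh@nodes) + 1)), , drop = FALSE]
  storage.mode(ed) <- "integer"
  ed
}

#' Element areas and centroids
#' @param mesh a \code{SurfaceMesh}
#' @return list with numeric vector \code{area} (mm^2) and matrix
#'   \code{centroid} (m x 3, mm)
#' @export
elementGeometry <- function(mesh) {
  tri <- mesh@triangles
  p1 <- mesh@nodes[tri[, 1], , drop = FALSE]
  p2 <- mesh@nodes[tri[, 2], , drop = FALSE]
  p3 <- mesh@nodes[tri[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  list(area = 0.5 * sqrt(cx^2 + cy^2 + cz^2), centroid = (p1 + p2 + p3) / 3)
}
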