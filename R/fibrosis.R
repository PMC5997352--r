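#' Edge table of a mesh with fiber angles
#'
#' Unique edges in canonical (min,max) order together with the angle
#' between each edge and the fiber direction of its first incident element
#' (by element order), used for anisotropic fibrosis selection.
#'
#' @param mesh a \code{SurfaceMesh}.
#' @return data.frame: n1, n2, length (mm), cosTheta (|cos| of the
#'   edge-fiber angle)
#' @export
edgeTable <- function(mesh) {
  tri <- mesh@triangles
  ed <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  el <- rep(seq_len(nrow(tri)), 3)
  o <- order(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]), el)
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))[o, ,
                                                              drop = FALSE]
  el <- el[o]
  first <- !duplicated(ed %*% c(1, nNodes(mesh) + 1))
  ed <- ed[first, , drop = FALSE]
  el <- el[first]
  dvec <- mesh@nodes[ed[, 2], , drop = FALSE] -
    mesh@nodes[ed[, 1], , drop = FALSE]
  len <- sqrt(rowSums(dvec^2))
  ct <- abs(rowSums(dvec * mesh@fibers[el, , drop = FALSE])) / len
  data.frame(n1 = ed[, 1], n2 = ed[, 2], length = len,
             cosTheta = pmin(1, ct))
}

.selectEdges <- function(mesh, weightPerNode, rho, anisotropy, seed,
                         fieldId) {
  stopifnot(rho >= 0, rho <= 1, anisotropy > 0)
  et <- edgeTable(mesh)
  w <- (weightPerNode[et$n1] + weightPerNode[et$n2]) / 2
  eligible <- !is.na(w) & w > 0
  wAng <- 1 + (anisotropy - 1) * et$cosTheta^2
  p <- rep(0, nrow(et))
  p[eligible] <- rho * w[eligible] * wAng[eligible]
  nClamped <- sum(p > 1)
  p <- pmin(1, p)
  sel <- .withSeed(seed, runif(nrow(et)) < p)
  if (nClamped > 0)
    warning(nClamped, " edge selection probabilities clamped to 1")
  new("EdgeSet",
      edges = matrix(as.integer(c(et$n1[sel], et$n2[sel])), ncol = 2),
      seed = as.integer(seed),
      params = list(rho = rho, anisotropy = anisotropy, field = fieldId,
                    nClamped = nClamped, expectedCount = sum(p)))
}

#' Select interstitial-fibrosis edges in the pulmonary veins
#'
#' Each PV edge is selected independently with probability
#' \code{p = rho * d(e) * w(theta)}, where \code{d(e)} is the mean
#' ostial-distal distance parameter of the edge endpoints (fibrosis density
#' increases toward the distal vein) and
#' \code{w(theta) = 1 + (A - 1) cos^2(theta)} interpolates from 1 for edges
#' transverse to the local fiber direction to the anisotropy factor
#' \code{A} for longitudinal edges, making longitudinal edges \code{A}
#' times more likely to be selected. Probabilities are clamped at 1 (with a
#' report). The draw is seeded and edges are processed in canonical
#' (min,max) order, so results are portable across runs.
#'
#' @param mesh a \code{SurfaceMesh}.
#' @param distance distance-parameter field
#'   (\code{\link{computeAllDistanceParameters}}).
#' @param rho base selection density in [0, 1] (calibration knob; 0.15
#'   "moderate", 0.3 "high").
#' @param anisotropy longitudinal:transverse likelihood ratio (default 4).
#' @param seed integer seed.
#' @return an \code{\linkS4class{EdgeSet}}
#' @export
selectPvFibroticEdges <- function(mesh, distance, rho, anisotropy = 4,
                                  seed = 1L) {
  w <- distance@values
  pv <- mesh@nodeRegion %in% REGION_CODES[PV_NAMES]
  w[!pv] <- NA
  .selectEdges(mesh, w, rho, anisotropy, seed, distance@name)
}

#' Select interstitial-fibrosis edges from an LGE-intensity field
#'
#' As \code{\link{selectPvFibroticEdges}}, with the distance parameter
#' replaced by the mean normalized LGE intensity of the edge endpoints.
#'
#' @param mesh a \code{SurfaceMesh}.
#' @param lge LGE field (\code{\link{generateSyntheticLge}}), values in
#'   [0, 1].
#' @param rho base selection density in [0, 1].
#' @param anisotropy longitudinal:transverse likelihood ratio.
#' @param seed integer seed.
#' @return an \code{\linkS4class{EdgeSet}}
#' @export
selectLgeFibroticEdges <- function(mesh, lge, rho, anisotropy = 4,
                                   seed = 1L) {
  v <- lge@values
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("LGE intensity must be normalized to [0, 1]")
  .selectEdges(mesh, v, rho, anisotropy, seed, lge@name)
}

#' Connected decoupled-edge networks and the node-splitting plan
#'
#' Partitions the selected edges into connected components (edges sharing
#' an endpoint) and classifies each component's nodes: interior nodes are
#' duplicated by the solver's node splitting, path endpoints (crack tips)
#' remain shared.
#'
#' @param edgeSet an \code{EdgeSet}.
#' @param mesh the mesh it belongs to.
#' @return list of components; each has \code{edges} (k x 2), \code{nodes},
#'   \code{interior} and \code{tips}
#' @export
buildEdgeNetworks <- function(edgeSet, mesh) {
  e <- edgeSet@edges
  if (!nrow(e)) return(list())
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  memb <- igraph::components(g)$membership
  deg <- igraph::degree(g)
  comps <- sort(unique(memb[as.vector(e)]))
  lapply(comps, function(cc) {
    nodesIn <- which(memb == cc & deg > 0)
    keep <- memb[e[, 1]] == cc
    list(edges = e[keep, , drop = FALSE],
         nodes = nodesIn,
         interior = nodesIn[deg[nodesIn] >= 2],
         tips = nodesIn[deg[nodesIn] == 1])
  })
}

#' Attach decoupled edges to a conductivity field
#'
#' @param cond a \code{ConductivityField}.
#' @param edgeSet an \code{EdgeSet} of fibrotic edges.
#' @return the field with \code{decoupledEdges} set
#' @export
withFibrosis <- function(cond, edgeSet) {
  cond@decoupledEdges <- edgeSet@edges
  cond
}

#' Write / read an EdgeSet as a text file
#'
#' Format: a JSON header line (prefixed \code{#}) with seed and selection
#' parameters, then one "n1 n2" pair per line.
#'
#' @param edgeSet an \code{EdgeSet}.
#' @param path output path.
#' @return invisibly, \code{path}
#' @export
writeEdgeSet <- function(edgeSet, path) {
  hdr <- paste0("# ", jsonlite::toJSON(
    c(list(seed = edgeSet@seed), edgeSet@params), auto_unbox = TRUE))
  writeLines(c(hdr, sprintf("%d %d", edgeSet@edges[, 1],
                            edgeSet@edges[, 2])), path)
  invisible(path)
}

#' @rdname writeEdgeSet
#' @export
readEdgeSet <- function(path) {
  lines <- readLines(path)
  meta <- jsonlite::fromJSON(sub("^# ", "", lines[1]))
  body <- lines[-1]
  e <- if (length(body))
    matrix(as.integer(scan(text = body, quiet = TRUE)), ncol = 2,
           byrow = TRUE)
  else matrix(integer(0), 0, 2)
  new("EdgeSet", edges = e, seed = as.integer(meta$seed),
      params = meta[setdiff(names(meta), "seed")])
}
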