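#' Geometry parameters for the idealized atrium
#'
#' The idealized left-atrial geometry is a flat disc (the LA body) with four
#' tubular PV sleeves rising from circular ostia, each sleeve ending in an
#' open distal rim. Defaults are chosen to permit reentry at the LA/PV
#' junction at desk scale: body disc radius 35 mm, ostial radii 6-8 mm,
#' sleeve lengths 10-20 mm, target mean edge length 0.34 mm, single layer.
#'
#' @param bodyRadius LA body disc radius (mm).
#' @param veinRadius named numeric, ostial radius per vein (mm).
#' @param veinLength named numeric, sleeve length per vein (mm).
#' @param veinCenter 4 x 2 matrix of ostium centres (mm), rows named by vein.
#' @param edgeLength target mean edge length (mm).
#' @param layers 1 (endo only) or 2 (bilayer).
#' @param layerOffset epi-layer normal offset for bilayer meshes (mm).
#' @param lesionClearance radial clearance between a vein pair and its PVI
#'   lesion band (mm).
#' @param lesionWidth PVI lesion band width (mm); widened automatically on
#'   coarse meshes so the band always contains a closed ring of elements.
#' @param seed integer seed (the construction is deterministic; the seed is
#'   recorded in provenance and used by downstream stochastic stages).
#' @return validated parameter list of class \code{GeometryParams}
#' @export
geometryParams <- function(bodyRadius = 35,
                           veinRadius = c(LSPV = 7, LIPV = 6, RSPV = 8,
                                          RIPV = 6.5),
                           veinLength = c(LSPV = 20, LIPV = 15, RSPV = 10,
                                          RIPV = 12),
                           veinCenter = rbind(LSPV = c(-18, 13),
                                              LIPV = c(-18, -13),
                                              RSPV = c(18, 13),
                                              RIPV = c(18, -13)),
                           edgeLength = 0.34,
                           layers = 1,
                           layerOffset = 0.3,
                           lesionClearance = 4,
                           lesionWidth = 1.5,
                           seed = 1L) {
  stopifnot(bodyRadius > 0, edgeLength > 0, all(veinRadius > 0),
            all(veinLength > 0), layers %in% c(1, 2))
  veins <- names(veinRadius)
  if (!setequal(veins, rownames(veinCenter)) ||
      !setequal(veins, names(veinLength)))
    stop("vein names must agree across veinRadius, veinLength, veinCenter")
  # feasibility: ostia must fit in the body and not touch each other
  for (v in veins) {
    if (sqrt(sum(veinCenter[v, ]^2)) + veinRadius[v] + 2 * edgeLength >
        bodyRadius)
      stop("infeasible geometry: vein ", v, " does not fit inside the body")
  }
  for (i in seq_along(veins)) for (j in seq_len(i - 1)) {
    vi <- veins[i]; vj <- veins[j]
    gap <- sqrt(sum((veinCenter[vi, ] - veinCenter[vj, ])^2)) -
      veinRadius[vi] - veinRadius[vj]
    if (gap < 2 * edgeLength)
      stop("infeasible geometry: veins ", vi, " and ", vj,
           " overlap (gap ", signif(gap, 3), " mm)")
  }
  structure(list(bodyRadius = bodyRadius, veinRadius = veinRadius,
                 veinLength = veinLength, veinCenter = veinCenter,
                 edgeLength = edgeLength, layers = layers,
                 layerOffset = layerOffset,
                 lesionClearance = lesionClearance,
                 lesionWidth = lesionWidth, seed = as.integer(seed)),
            class = "GeometryParams")
}

# regular triangular lattice covering [xmin,xmax] x [ymin,ymax]:
# rows spaced sqrt(3)/2*a apart, odd rows offset a/2; returns nodes (k x 2)
# and CCW triangles
.triLattice <- function(xmin, xmax, ymin, ymax, a) {
  h <- sqrt(3) / 2 * a
  nrow_ <- floor((ymax - ymin) / h) + 1L
  ncol_ <- floor((xmax - xmin) / a) + 2L
  jj <- rep(seq_len(nrow_) - 1L, each = ncol_)
  ii <- rep(seq_len(ncol_) - 1L, nrow_)
  x <- xmin + ii * a + (jj %% 2L) * a / 2
  y <- ymin + jj * h
  id <- function(i, j) j * ncol_ + i + 1L  # 0-based i,j -> 1-based index
  tris <- vector("list", nrow_ - 1L)
  for (j in seq_len(nrow_ - 1L) - 1L) {
    i <- seq_len(ncol_ - 1L) - 1L
    if (j %% 2L == 0L) {
      t1 <- cbind(id(i, j), id(i + 1L, j), id(i, j + 1L))
      t2 <- cbind(id(i + 1L, j), id(i + 1L, j + 1L), id(i, j + 1L))
    } else {
      t1 <- cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L))
      t2 <- cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L))
    }
    tris[[j + 1L]] <- rbind(t1, t2)
  }
  list(nodes = cbind(x, y), triangles = do.call(rbind, tris))
}

# order boundary edges (each used by exactly one triangle) into closed loops
.boundaryLoops <- function(triangles, nNode) {
  ed <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  key <- pmin(ed[, 1], ed[, 2]) + (pmax(ed[, 1], ed[, 2]) - 1) * nNode
  cnt <- table(key)
  bkey <- as.numeric(names(cnt)[cnt == 1])
  bmat <- cbind((bkey - 1) %% nNode + 1, (bkey - 1) %/% nNode + 1)
  if (!nrow(bmat)) return(list())
  # adjacency: each boundary node has exactly two boundary neighbours
  nb <- split(c(bmat[, 2], bmat[, 1]), c(bmat[, 1], bmat[, 2]))
  loops <- list()
  visited <- new.env(hash = TRUE)
  for (s in as.integer(names(nb))) {
    if (!is.null(visited[[as.character(s)]])) next
    loop <- integer(0)
    prev <- NA_integer_; cur <- s
    repeat {
      loop <- c(loop, cur)
      visited[[as.character(cur)]] <- TRUE
      nxts <- nb[[as.character(cur)]]
      nxt <- nxts[is.na(prev) | nxts != prev][1]
      if (is.na(nxt)) break
      prev <- cur; cur <- nxt
      if (cur == s) break
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

# greedy zipper triangulation between two closed CCW loops (indices into a
# shared node table); loopA below, loopB above; returns triangles oriented
# consistently with an outward (radial) normal
.zipper <- function(nodes, loopA, loopB) {
  nA <- length(loopA); nB <- length(loopB)
  # align start nodes
  j0 <- which.min(colSums((t(nodes[loopB, 1:2, drop = FALSE]) -
                             nodes[loopA[1], 1:2])^2))
  loopB <- loopB[c(j0:nB, seq_len(j0 - 1L))]
  tris <- matrix(0L, nA + nB, 3)
  i <- 1L; j <- 1L; k <- 0L
  adA <- 0L; adB <- 0L
  while (adA < nA || adB < nB) {
    ai <- loopA[(i - 1L) %% nA + 1L]; a2 <- loopA[i %% nA + 1L]
    bj <- loopB[(j - 1L) %% nB + 1L]; b2 <- loopB[j %% nB + 1L]
    dA <- sum((nodes[a2, ] - nodes[bj, ])^2)
    dB <- sum((nodes[b2, ] - nodes[ai, ])^2)
    k <- k + 1L
    if (adB >= nB || (adA < nA && dA <= dB)) {
      tris[k, ] <- c(ai, a2, bj); i <- i + 1L; adA <- adA + 1L
    } else {
      tris[k, ] <- c(ai, b2, bj); j <- j + 1L; adB <- adB + 1L
    }
  }
  tris[seq_len(k), , drop = FALSE]
}

# per-element unit fiber vectors projected into the element plane
.projectFibers <- function(nodes, triangles, dirs) {
  p1 <- nodes[triangles[, 1], , drop = FALSE]
  e1 <- nodes[triangles[, 2], , drop = FALSE] - p1
  e2 <- nodes[triangles[, 3], , drop = FALSE] - p1
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  nrm <- cbind(nx, ny, nz) / nn
  dp <- rowSums(dirs * nrm)
  f <- dirs - dp * nrm
  ln <- sqrt(rowSums(f^2))
  bad <- ln < 1e-8
  if (any(bad)) {  # direction parallel to normal: fall back to first edge
    f[bad, ] <- e1[bad, , drop = FALSE]
    ln[bad] <- sqrt(rowSums(f[bad, , drop = FALSE]^2))
  }
  f / ln
}

.elementNormals <- function(nodes, triangles) {
  p1 <- nodes[triangles[, 1], , drop = FALSE]
  e1 <- nodes[triangles[, 2], , drop = FALSE] - p1
  e2 <- nodes[triangles[, 3], , drop = FALSE] - p1
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  cbind(nx, ny, nz) / nn
}

#' Generate the idealized atrial surface mesh
#'
#' Builds a connected open surface: a disc-shaped LA body with four tubular
#' PV sleeves, each ending in an open distal rim, with labelled junction and
#' distal rim loops per vein, a sinoatrial-node stimulus patch, a left-atrial
#' appendage patch, and PVI lesion bands encircling the ipsilateral vein
#' pairs. Default fibers are uniform (+x) on the body and circumferential on
#' the veins (fiber case 0); use \code{\link{assignPvFibers}} for the other
#' arrangements.
#'
#' @param params a \code{\link{geometryParams}} object.
#' @return a \code{\linkS4class{SurfaceMesh}}
#' @export
generateIdealizedAtrium <- function(params = geometryParams()) {
  stopifnot(inherits(params, "GeometryParams"))
  a <- params$edgeLength
  R <- params$bodyRadius
  lat <- .triLattice(-R - 2 * a, R + 2 * a, -R - 2 * a, R + 2 * a, a)
  xy <- lat$nodes
  r2 <- rowSums(xy^2)
  inDisc <- r2 <= R^2
  inHole <- rep(FALSE, nrow(xy))
  holeOf <- rep(NA_character_, nrow(xy))
  for (v in rownames(params$veinCenter)) {
    d2 <- (xy[, 1] - params$veinCenter[v, 1])^2 +
      (xy[, 2] - params$veinCenter[v, 2])^2
    hit <- d2 < params$veinRadius[v]^2
    inHole <- inHole | hit
    holeOf[hit] <- v
  }
  keepNode <- inDisc & !inHole
  tri <- lat$triangles
  keepTri <- keepNode[tri[, 1]] & keepNode[tri[, 2]] & keepNode[tri[, 3]]
  tri <- tri[keepTri, , drop = FALSE]
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(xy)); remap[used] <- seq_along(used)
  tri <- matrix(remap[tri], ncol = 3)
  nodes <- cbind(xy[used, , drop = FALSE], 0)
  nBody <- nrow(nodes)

  # classify boundary loops: one outer rim + one per vein ostium
  loops <- .boundaryLoops(tri, nBody)
  veinLoop <- list()
  for (lp in loops) {
    ctr <- colMeans(nodes[lp, 1:2, drop = FALSE])
    dc <- sqrt((params$veinCenter[, 1] - ctr[1])^2 +
                 (params$veinCenter[, 2] - ctr[2])^2)
    v <- which.min(dc)
    if (dc[v] > params$veinRadius[v]) next  # the outer disc rim stays open
    veinLoop[[rownames(params$veinCenter)[v]]] <- lp
  }
  if (length(veinLoop) != nrow(params$veinCenter))
    stop("mesh generation failed to carve all vein ostia; ",
         "check vein radii against edge length")

  region <- rep(REGION_CODES[["LA_BODY"]], nBody)
  triList <- list(tri)
  rims <- list()
  h <- sqrt(3) / 2 * a

  for (v in names(veinLoop)) {
    ctr <- params$veinCenter[v, ]
    rv <- params$veinRadius[v]
    lp <- veinLoop[[v]]
    # project junction rim onto the ostial circle
    dxy <- nodes[lp, 1:2, drop = FALSE] - matrix(ctr, length(lp), 2,
                                                 byrow = TRUE)
    ang <- atan2(dxy[, 2], dxy[, 1])
    nodes[lp, 1] <- ctr[1] + rv * cos(ang)
    nodes[lp, 2] <- ctr[2] + rv * sin(ang)
    # orient the rim CCW (viewed from +z): positive signed polygon area
    px <- nodes[lp, 1]; py <- nodes[lp, 2]
    px2 <- c(px[-1], px[1]); py2 <- c(py[-1], py[1])
    if (sum(px * py2 - px2 * py) < 0) lp <- rev(lp)
    # regular rings of the sleeve
    nc <- max(8L, round(2 * pi * rv / a))
    nr <- max(2L, round(params$veinLength[v] / h))
    ringIdx <- vector("list", nr)
    for (j in seq_len(nr)) {
      th <- 2 * pi * (seq_len(nc) - 1) / nc + (j %% 2) * pi / nc
      ring <- cbind(ctr[1] + rv * cos(th), ctr[2] + rv * sin(th), j * h)
      ringIdx[[j]] <- nrow(nodes) + seq_len(nc)
      nodes <- rbind(nodes, ring)
      region <- c(region, rep(REGION_CODES[[v]], nc))
    }
    # zipper junction rim -> first ring, then regular bands up the sleeve
    triList[[length(triList) + 1L]] <- .zipper(nodes, lp, ringIdx[[1]])
    for (j in seq_len(nr - 1L)) {
      A <- ringIdx[[j]]; B <- ringIdx[[j + 1L]]
      i <- seq_len(nc); i2 <- c(seq_len(nc)[-1], 1L)
      # rings alternate angular offset by pi/nc; pick the index pairing
      # that keeps the band diagonals short (near-equilateral bands)
      triList[[length(triList) + 1L]] <- if (j %% 2L == 1L)
        rbind(cbind(A[i], A[i2], B[i2]), cbind(A[i], B[i2], B[i]))
      else
        rbind(cbind(A[i], A[i2], B[i]), cbind(A[i2], B[i2], B[i]))
    }
    region[lp] <- REGION_CODES[[v]]
    rims[[v]] <- list(junction = as.integer(lp),
                      distal = as.integer(ringIdx[[nr]]))
  }
  tri <- do.call(rbind, triList)

  # SAN stimulus patch and LAA label patch on the body
  sanCtr <- c(0, -(R - 3)); laaCtr <- c(0, R - 6)
  bodyIdx <- which(region == REGION_CODES[["LA_BODY"]])
  dSan <- sqrt((nodes[bodyIdx, 1] - sanCtr[1])^2 +
                 (nodes[bodyIdx, 2] - sanCtr[2])^2)
  dLaa <- sqrt((nodes[bodyIdx, 1] - laaCtr[1])^2 +
                 (nodes[bodyIdx, 2] - laaCtr[2])^2)
  region[bodyIdx[dSan <= max(2.5, 3 * a)]] <- REGION_CODES[["SAN"]]
  region[bodyIdx[dLaa <= 4]] <- REGION_CODES[["LAA"]]

  # PVI lesion bands: an annular band around each ipsilateral vein pair
  wl <- max(params$lesionWidth, 2.5 * a)
  for (side in c("L", "R")) {
    vs <- if (side == "L") c("LSPV", "LIPV") else c("RSPV", "RIPV")
    if (!all(vs %in% rownames(params$veinCenter))) next
    c1 <- params$veinCenter[vs[1], ]; c2 <- params$veinCenter[vs[2], ]
    renc <- max(params$veinRadius[vs]) + params$lesionClearance
    dseg <- .distToSegment(nodes[, 1:2, drop = FALSE], c1, c2)
    hit <- region == REGION_CODES[["LA_BODY"]] & dseg >= renc &
      dseg <= renc + wl
    region[hit] <- REGION_CODES[[paste0("PVI_LESION_", side)]]
  }

  # default fibers: +x on the body, circumferential on the sleeves
  cent <- (nodes[tri[, 1], , drop = FALSE] + nodes[tri[, 2], , drop = FALSE] +
             nodes[tri[, 3], , drop = FALSE]) / 3
  dirs <- matrix(rep(c(1, 0, 0), each = nrow(tri)), ncol = 3)
  for (v in names(veinLoop)) {
    inVein <- region[tri[, 1]] == REGION_CODES[[v]] &
      region[tri[, 2]] == REGION_CODES[[v]] &
      region[tri[, 3]] == REGION_CODES[[v]]
    if (!any(inVein)) next
    dx <- cent[inVein, 1] - params$veinCenter[v, 1]
    dy <- cent[inVein, 2] - params$veinCenter[v, 2]
    ln <- sqrt(dx^2 + dy^2)
    dirs[inVein, ] <- cbind(-dy / ln, dx / ln, 0)
  }
  fib <- .projectFibers(nodes, tri, dirs)

  mesh <- new("SurfaceMesh", nodes = nodes,
              triangles = matrix(as.integer(tri), ncol = 3),
              fibers = fib, nodeRegion = as.integer(region),
              layerOfNode = rep(1L, nrow(nodes)),
              interlayerPairs = matrix(integer(0), 0, 2), rims = rims)
  if (params$layers == 2) mesh <- .addEpiLayer(mesh, params$layerOffset)
  mesh
}

.distToSegment <- function(p, a, b) {
  ab <- b - a
  t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) / sum(ab^2)
  t <- pmin(1, pmax(0, t))
  sqrt((p[, 1] - (a[1] + t * ab[1]))^2 + (p[, 2] - (a[2] + t * ab[2]))^2)
}

# duplicate the surface as an epicardial layer offset along node normals
.addEpiLayer <- function(mesh, offset) {
  n <- nNodes(mesh)
  en <- .elementNormals(mesh@nodes, mesh@triangles)
  # accumulate element normals onto nodes
  nodeN <- matrix(0, n, 3)
  for (k in 1:3) {
    i <- mesh@triangles[, k]
    for (c in 1:3) {
      acc <- rep(0, n)
      acc[sort(unique(i))] <- rowsum(en[, c], i)[, 1]
      nodeN[, c] <- nodeN[, c] + acc
    }
  }
  ln <- sqrt(rowSums(nodeN^2)); ln[ln < 1e-12] <- 1
  nodeN <- nodeN / ln
  epiNodes <- mesh@nodes + offset * nodeN
  tri2 <- mesh@triangles + n
  # flip epi orientation so outward normals stay consistent per layer
  new("SurfaceMesh",
      nodes = rbind(mesh@nodes, epiNodes),
      triangles = rbind(mesh@triangles, tri2[, c(1, 3, 2)]),
      fibers = rbind(mesh@fibers,
                     .projectFibers(rbind(mesh@nodes, epiNodes),
                                    tri2[, c(1, 3, 2)], mesh@fibers)),
      nodeRegion = rep(mesh@nodeRegion, 2),
      layerOfNode = rep(1:2, each = n),
      interlayerPairs = cbind(seq_len(n), seq_len(n) + n),
      rims = c(mesh@rims,
               setNames(lapply(mesh@rims, function(r)
                 list(junction = r$junction + n, distal = r$distal + n)),
                 paste0(names(mesh@rims), ".epi"))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a rectangular fiber-aligned strand mesh
#'
#' A planar strip triangulated at the requested resolution with fibers along
#' +x, used for planar-wave conduction-velocity measurement and tuning.
#'
#' @param lengthMm strand length along the fiber axis (mm).
#' @param widthMm strand width (mm).
#' @param edgeLength target edge length (mm).
#' @return a \code{\linkS4class{SurfaceMesh}} with all nodes labelled LA_BODY
#' @export
generateStrandMesh <- function(lengthMm = 40, widthMm = 8,
                               edgeLength = 0.34) {
  lat <- .triLattice(0, lengthMm, 0, widthMm, edgeLength)
  nodes <- cbind(lat$nodes, 0)
  tri <- lat$triangles
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  tri <- matrix(as.integer(remap[tri]), ncol = 3)
  nodes <- nodes[used, , drop = FALSE]
  dirs <- matrix(rep(c(1, 0, 0), each = nrow(tri)), ncol = 3)
  new("SurfaceMesh", nodes = nodes, triangles = tri,
      fibers = .projectFibers(nodes, tri, dirs),
      nodeRegion = rep(REGION_CODES[["LA_BODY"]], nrow(nodes)),
      layerOfNode = rep(1L, nrow(nodes)),
      interlayerPairs = matrix(integer(0), 0, 2), rims = list())
}

#' Euler characteristic of a mesh (nodes - edges + faces)
#' @param mesh a \code{SurfaceMesh}
#' @export
eulerCharacteristic <- function(mesh) {
  nNodes(mesh) - nrow(uniqueEdges(mesh)) + nElements(mesh)
}

#' Ostial-distal distance parameter of a vein
#'
#' Graph-geodesic distances are computed from the junction rim (\code{g_j})
#' and from the distal rim (\code{g_d}) to every node of the vein, along
#' mesh edges restricted to the vein; the distance parameter is the
#' normalized ratio \code{d = g_j / (g_j + g_d)}, 0 at the LA/PV junction
#' and 1 at the distal boundary.
#'
#' @param mesh a \code{SurfaceMesh} with rims for \code{vein}.
#' @param vein vein name ("LSPV", "LIPV", "RSPV" or "RIPV").
#' @return a \code{\linkS4class{ScalarNodeField}} defined on the vein
#' @export
computeDistanceParameter <- function(mesh, vein) {
  if (is.null(mesh@rims[[vein]]))
    stop("vein ", vein, " has no rim loops on this mesh")
  # a bilayer mesh carries separate rim loops per layer
  rimNames <- intersect(c(vein, paste0(vein, ".epi")), names(mesh@rims))
  junction <- unlist(lapply(mesh@rims[rimNames], `[[`, "junction"))
  distal <- unlist(lapply(mesh@rims[rimNames], `[[`, "distal"))
  vn2 <- which(mesh@nodeRegion == REGION_CODES[[vein]])
  ed <- uniqueEdges(mesh)
  keep <- ed[, 1] %in% vn2 & ed[, 2] %in% vn2
  ed <- ed[keep, , drop = FALSE]
  w <- sqrt(rowSums((mesh@nodes[ed[, 1], , drop = FALSE] -
                       mesh@nodes[ed[, 2], , drop = FALSE])^2))
  ids <- sort(unique(as.vector(ed)))
  remap <- integer(nNodes(mesh)); remap[ids] <- seq_along(ids)
  g <- igraph::graph_from_edgelist(cbind(remap[ed[, 1]], remap[ed[, 2]]),
                                   directed = FALSE)
  igraph::E(g)$weight <- w
  gj <- suppressWarnings(igraph::distances(
    g, v = remap[intersect(junction, ids)]))
  gd <- suppressWarnings(igraph::distances(
    g, v = remap[intersect(distal, ids)]))
  dj <- apply(gj, 2, min); dd <- apply(gd, 2, min)
  val <- rep(NA_real_, nNodes(mesh))
  val[ids] <- dj / (dj + dd)
  val[junction] <- 0
  val[distal] <- 1
  .newField(val, paste0("distance.", vein))
}

#' Distance parameter for all veins combined
#' @param mesh a \code{SurfaceMesh}
#' @return a \code{ScalarNodeField} defined on all PV nodes
#' @export
computeAllDistanceParameters <- function(mesh) {
  val <- rep(NA_real_, nNodes(mesh))
  for (v in intersect(PV_NAMES, names(mesh@rims))) {
    f <- computeDistanceParameter(mesh, v)
    def <- !is.na(f@values)
    val[def] <- f@values[def]
  }
  .newField(val, "distance.PV")
}

#' Assign PV fiber arrangements
#'
#' Applies one of six literature-motivated PV fiber arrangements (plus the
#' generator default, case 0):
#' \enumerate{
#'   \item circular on both layers;
#'   \item spiralling (45 degrees) on both layers;
#'   \item circular endocardium, longitudinal epicardium;
#'   \item circumferential at the junction rotating to longitudinal at the
#'     distal end (90-degree rotation with the distance parameter), both
#'     layers identical;
#'   \item epicardium as case 4, circumferential endocardium;
#'   \item case 4 plus chaotic disorder at the junction: zero-mean Gaussian
#'     angle noise with standard deviation \code{sigma0 * (1 - d)}.
#' }
#' On a single-layer mesh the endocardial rule is applied to the only layer.
#'
#' @param mesh a \code{SurfaceMesh}.
#' @param case integer 0-6.
#' @param seed seed for the case-6 noise.
#' @param sigma0 case-6 noise scale at the junction (degrees).
#' @param distance optional precomputed \code{\link{computeAllDistanceParameters}}
#'   field.
#' @return the mesh with updated element fibers
#' @export
assignPvFibers <- function(mesh, case, seed = 1L, sigma0 = 45,
                           distance = NULL) {
  if (!case %in% 0:6) stop("unknown fiber case: ", case)
  if (case == 0) return(mesh)
  if (is.null(distance)) distance <- computeAllDistanceParameters(mesh)
  dval <- distance@values
  tri <- mesh@triangles
  nrm <- .elementNormals(mesh@nodes, tri)
  fib <- mesh@fibers
  rg <- mesh@nodeRegion
  for (v in intersect(PV_NAMES, names(mesh@rims))) {
    inVein <- rg[tri[, 1]] == REGION_CODES[[v]] &
      rg[tri[, 2]] == REGION_CODES[[v]] & rg[tri[, 3]] == REGION_CODES[[v]]
    if (!any(inVein)) next
    el <- which(inVein)
    dbar <- (dval[tri[el, 1]] + dval[tri[el, 2]] + dval[tri[el, 3]]) / 3
    # longitudinal = in-plane gradient of the distance parameter
    long <- .p1Gradient(mesh, dval, el)
    ln <- sqrt(rowSums(long^2))
    ok <- ln > 1e-9
    long[ok, ] <- long[ok, ] / ln[ok]
    if (any(!ok)) long[!ok, ] <- mesh@fibers[el[!ok], , drop = FALSE]
    circ <- cbind(nrm[el, 2] * long[, 3] - nrm[el, 3] * long[, 2],
                  nrm[el, 3] * long[, 1] - nrm[el, 1] * long[, 3],
                  nrm[el, 1] * long[, 2] - nrm[el, 2] * long[, 1])
    layer <- mesh@layerOfNode[tri[el, 1]]
    theta <- switch(as.character(case),
      "1" = rep(0, length(el)),
      "2" = rep(pi / 4, length(el)),
      "3" = ifelse(layer == 1L, 0, pi / 2),
      "4" = pi / 2 * dbar,
      "5" = ifelse(layer == 1L, 0, NA),  # endo circular, epi filled below
      "6" = pi / 2 * dbar)
    if (case == 5) theta[layer == 2L] <- (pi / 2 * dbar)[layer == 2L]
    if (case == 6) {
      noise <- .withSeed(seed, rnorm(length(el)))
      theta <- theta + sigma0 * pi / 180 * (1 - dbar) * noise
    }
    fib[el, ] <- cos(theta) * circ + sin(theta) * long
  }
  ln <- sqrt(rowSums(fib^2))
  mesh@fibers <- fib / ln
  validObject(mesh)
  mesh
}

# P1 gradient of a node field on selected elements
.p1Gradient <- function(mesh, values, elements) {
  tri <- mesh@triangles[elements, , drop = FALSE]
  p1 <- mesh@nodes[tri[, 1], , drop = FALSE]
  p2 <- mesh@nodes[tri[, 2], , drop = FALSE]
  p3 <- mesh@nodes[tri[, 3], , drop = FALSE]
  v1 <- values[tri[, 1]]; v2 <- values[tri[, 2]]; v3 <- values[tri[, 3]]
  e1 <- p2 - p1; e2 <- p3 - p1
  # solve for gradient in the (e1, e2) basis using the metric tensor
  g11 <- rowSums(e1 * e1); g12 <- rowSums(e1 * e2); g22 <- rowSums(e2 * e2)
  det <- g11 * g22 - g12^2
  a <- ((v2 - v1) * g22 - (v3 - v1) * g12) / det
  b <- ((v3 - v1) * g11 - (v2 - v1) * g12) / det
  a * e1 + b * e2
}

# evaluate expr with a local, restored RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Partition mesh nodes into PV, LA and RA analysis regions
#'
#' The PV region is the set of nodes enclosed by, and including, the PVI
#' lesion lines; enclosure is determined topologically: after removing the
#' lesion nodes from the node-adjacency graph, every connected component
#' containing a vein node lies inside a lesion loop and is assigned to PV.
#' The RA region collects RA-labelled nodes (empty on the idealized
#' single-atrium mesh); everything else (LA body and appendage) is LA.
#'
#' @param mesh a \code{SurfaceMesh} with PVI lesion bands labelled.
#' @return integer vector (1 = PV, 2 = LA, 3 = RA) with attribute
#'   \code{levels = c("PV", "LA", "RA")}
#' @export
definePsRegions <- function(mesh) {
  lesion <- mesh@nodeRegion %in% REGION_CODES[c("PVI_LESION_L",
                                               "PVI_LESION_R")]
  if (!any(lesion))
    stop("no PVI lesion bands labelled on this mesh")
  ed <- uniqueEdges(mesh)
  keep <- !lesion[ed[, 1]] & !lesion[ed[, 2]]
  g <- igraph::graph_from_edgelist(ed[keep, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nNodes(mesh) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  veinComp <- unique(comp[mesh@nodeRegion %in% REGION_CODES[PV_NAMES]])
  out <- rep(2L, nNodes(mesh))
  out[comp %in% veinComp] <- 1L
  out[lesion] <- 1L
  out[mesh@nodeRegion == REGION_CODES[["RA"]]] <- 3L
  attr(out, "levels") <- c("PV", "LA", "RA")
  out
}

#' Synthetic LGE-intensity field
#'
#' Stands in for population-averaged or patient LGE-MRI intensity maps.
#' Patterns: \code{uniform} (constant), \code{pv_graded} (intensity rises
#' with the ostial-distal distance parameter on the veins), \code{patchy}
#' (seeded smooth random blobs with configurable correlation length).
#'
#' @param mesh a \code{SurfaceMesh}.
#' @param pattern one of "uniform", "pv_graded", "patchy".
#' @param scale maximum intensity in [0, 1].
#' @param seed integer seed (patchy pattern).
#' @param corrLength blob correlation length (mm).
#' @return a \code{\linkS4class{ScalarNodeField}} normalized to [0, 1]
#' @export
generateSyntheticLge <- function(mesh, pattern = c("uniform", "pv_graded",
                                                   "patchy"),
                                 scale = 1, seed = 1L, corrLength = 5) {
  pattern <- match.arg(pattern)
  n <- nNodes(mesh)
  val <- switch(pattern,
    uniform = rep(scale, n),
    pv_graded = {
      d <- computeAllDistanceParameters(mesh)@values
      v <- rep(0, n)
      v[!is.na(d)] <- scale * d[!is.na(d)]
      v
    },
    patchy = {
      nb <- max(3L, round(n / 3000))
      ctrs <- .withSeed(seed, sample.int(n, nb))
      v <- rep(0, n)
      for (c in ctrs) {
        d2 <- rowSums((mesh@nodes -
                         matrix(mesh@nodes[c, ], n, 3, byrow = TRUE))^2)
        v <- v + exp(-d2 / (2 * corrLength^2))
      }
      if (max(v) > 0) v <- v / max(v)
      scale * v
    })
  if (any(val < -1e-12) || any(val > 1 + 1e-12))
    stop("LGE intensity must lie in [0, 1]; got scale ", scale)
  .newField(pmin(1, pmax(0, val)), paste0("lge.", pattern))
}
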