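# Shared fixtures, memoised across test files within one session.

.cacheEnv <- function() {
  if (is.null(getOption("atrialab.testCache")))
    options(atrialab.testCache = new.env(parent = emptyenv()))
  getOption("atrialab.testCache")
}

.memo <- function(key, expr) {
  env <- .cacheEnv()
  if (is.null(env[[key]])) env[[key]] <- force(expr)
  env[[key]]
}

coarseAtriumParams <- function(layers = 1)
  geometryParams(bodyRadius = 20,
                 veinRadius = c(LSPV = 4, LIPV = 3.5, RSPV = 4.5,
                                RIPV = 3.8),
                 veinLength = c(LSPV = 10, LIPV = 8, RSPV = 6, RIPV = 7),
                 veinCenter = rbind(LSPV = c(-10, 7.5),
                                    LIPV = c(-10, -7.5),
                                    RSPV = c(10, 7.5),
                                    RIPV = c(10, -7.5)),
                 edgeLength = 1.0, lesionClearance = 2.5, layers = layers)

coarseAtrium <- function() .memo("coarseAtrium",
                                 generateIdealizedAtrium(coarseAtriumParams()))

coarseDistance <- function() .memo("coarseDistance",
                                   computeAllDistanceParameters(coarseAtrium()))

bilayerAtrium <- function() .memo("bilayerAtrium",
  generateIdealizedAtrium(coarseAtriumParams(layers = 2)))

tinyStrand <- function() .memo("tinyStrand", generateStrandMesh(20, 4, 0.5))

# finer single-vein mesh (5 mm radius, 10 mm sleeve, 0.6 mm edges)
cylAtrium <- function() .memo("cylAtrium", {
  gp <- geometryParams(bodyRadius = 20, veinRadius = c(LSPV = 5),
                       veinLength = c(LSPV = 10),
                       veinCenter = rbind(LSPV = c(0, 0)),
                       edgeLength = 0.6)
  generateIdealizedAtrium(gp)
})

# single-vein mesh for cheap protocol smoke tests
oneVeinAtrium <- function() .memo("oneVeinAtrium", {
  gp <- geometryParams(bodyRadius = 16,
                       veinRadius = c(LSPV = 4),
                       veinLength = c(LSPV = 8),
                       veinCenter = rbind(LSPV = c(-7, 0)),
                       edgeLength = 1.2, lesionClearance = 2.5)
  generateIdealizedAtrium(gp)
})

# right-triangle grid with +x fibers: edges at exactly 0, 45 and 90 degrees
# to the fiber direction (the equilateral generator has none at 90)
rightAngleGrid <- function(nx, ny, h = 1) {
  id <- function(i, j) (j - 1L) * nx + i
  nodes <- cbind(rep(seq_len(nx) - 1, ny) * h,
                 rep(seq_len(ny) - 1, each = nx) * h, 0)
  tris <- list()
  for (j in seq_len(ny - 1L)) {
    i <- seq_len(nx - 1L)
    tris[[j]] <- rbind(cbind(id(i, j), id(i + 1L, j), id(i, j + 1L)),
                       cbind(id(i + 1L, j), id(i + 1L, j + 1L),
                             id(i, j + 1L)))
  }
  tri <- matrix(as.integer(do.call(rbind, tris)), ncol = 3)
  fib <- matrix(rep(c(1, 0, 0), each = nrow(tri)), ncol = 3)
  new("SurfaceMesh", nodes = nodes, triangles = tri, fibers = fib,
      nodeRegion = rep(REGION_CODES[["LA_BODY"]], nrow(nodes)),
      layerOfNode = rep(1L, nrow(nodes)),
      interlayerPairs = matrix(integer(0), 0, 2), rims = list())
}

# construct a VoltageRecord from a matrix
makeRecord <- function(V, dt = 2, meta = list()) {
  new("VoltageRecord", V = V, times = dt * (seq_len(nrow(V)) - 1),
      sampleInterval = dt,
      meta = c(list(model = "fixture", earlyStop = NA_real_), meta))
}

# analytic rotor movie: V(x, t) = rest + amp * cos(phi0(x) - omega t) where
# phi0 winds once around each listed centre (chirality by sign)
rotorMovie <- function(mesh, centers, omega = 2 * pi / 200, nFrames = 300,
                       dt = 2, amp = 40, rest = -40) {
  xy <- nodeCoords(mesh)
  phi0 <- rep(0, nNodes(mesh))
  for (k in seq_len(nrow(centers)))
    phi0 <- phi0 + centers[k, 3] * atan2(xy[, 2] - centers[k, 2],
                                         xy[, 1] - centers[k, 1])
  tt <- dt * (seq_len(nFrames) - 1)
  V <- outer(tt, phi0, function(t, p) rest + amp * cos(p - omega * t))
  makeRecord(V, dt)
}

# independent Dijkstra oracle (binary-heap-free, O(n^2); fine for fixtures)
dijkstraOracle <- function(n, edges, weights, sources) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, weights[k]))
    adj[[b]] <- rbind(adj[[b]], c(a, weights[k]))
  }
  dist <- rep(Inf, n)
  dist[sources] <- 0
  done <- rep(FALSE, n)
  repeat {
    u <- which(!done & is.finite(dist))
    if (!length(u)) break
    u <- u[which.min(dist[u])]
    done[u] <- TRUE
    for (r in seq_len(NROW(adj[[u]]))) {
      v <- adj[[u]][r, 1]; w <- adj[[u]][r, 2]
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  dist
}

# exact McNemar enumeration oracle: two-sided binomial tail doubling via
# explicit combinatorial sums
mcnemarOracle <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  m <- min(b, c)
  min(1, 2 * sum(choose(n, 0:m)) / 2^n)
}
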