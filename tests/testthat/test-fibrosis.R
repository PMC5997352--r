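test_that("zero density or zero weight selects nothing", {
  mesh <- coarseAtrium()
  d <- coarseDistance()
  expect_identical(nrow(edgePairs(selectPvFibroticEdges(mesh, d, 0))), 0L)
  lge0 <- generateSyntheticLge(mesh, "uniform", scale = 0)
  expect_identical(nrow(edgePairs(selectLgeFibroticEdges(mesh, lge0,
                                                         0.5))), 0L)
})

test_that("longitudinal edges are selected ~4x more often than transverse", {
  # regular grid with exact 0- and 90-degree edges; uniform unit weight so
  # the fiber-angle factor is the only modulation
  grid <- rightAngleGrid(200, 170)
  ones <- rep(1, nNodes(grid))
  et <- edgeTable(grid)
  expect_gt(nrow(et), 1e5)
  es <- atrialab:::.selectEdges(grid, ones, rho = 0.05,
                                anisotropy = 4, seed = 11, fieldId = "unit")
  sel <- paste(edgePairs(es)[, 1], edgePairs(es)[, 2])
  key <- paste(et$n1, et$n2)
  isSel <- key %in% sel
  long <- et$cosTheta > 0.99
  trans <- et$cosTheta < 0.01
  ratio <- mean(isSel[long]) / mean(isSel[trans])
  expect_lt(abs(ratio - 4), 0.2)
})

test_that("selected counts match the analytic expectation", {
  mesh <- coarseAtrium()
  d <- coarseDistance()
  es <- selectPvFibroticEdges(mesh, d, rho = 0.1, seed = 42)
  expected <- es@params$expectedCount
  sdBin <- sqrt(expected)  # upper bound on the binomial sd
  expect_lt(abs(nrow(edgePairs(es)) - expected), 3 * sdBin + 1)
  # density scales linearly with rho while no probability clamps
  esHi <- selectPvFibroticEdges(mesh, d, rho = 0.2, seed = 42)
  expect_equal(esHi@params$expectedCount, 2 * expected, tolerance = 1e-9)
  lgeHalf <- generateSyntheticLge(mesh, "uniform", scale = 0.5)
  lgeFull <- generateSyntheticLge(mesh, "uniform", scale = 1)
  eH <- selectLgeFibroticEdges(mesh, lgeHalf, 0.1, seed = 1)
  eF <- selectLgeFibroticEdges(mesh, lgeFull, 0.1, seed = 1)
  expect_equal(eF@params$expectedCount / eH@params$expectedCount, 2,
               tolerance = 1e-9)
})

test_that("selection is deterministic given the seed", {
  mesh <- coarseAtrium()
  d <- coarseDistance()
  e1 <- selectPvFibroticEdges(mesh, d, 0.25, seed = 9)
  e2 <- selectPvFibroticEdges(mesh, d, 0.25, seed = 9)
  expect_identical(edgePairs(e1), edgePairs(e2))
  e3 <- selectPvFibroticEdges(mesh, d, 0.25, seed = 10)
  expect_false(identical(edgePairs(e1), edgePairs(e3)))
  # probability clamping is reported
  expect_warning(selectPvFibroticEdges(mesh, d, 1, anisotropy = 8,
                                       seed = 1), "clamped")
})

test_that("edge networks partition into components with correct splitting", {
  mesh <- tinyStrand()
  ed <- uniqueEdges(mesh)
  # two disjoint edges
  pick <- ed[c(1, nrow(ed)), , drop = FALSE]
  es <- new("EdgeSet", edges = pick, seed = 1L, params = list())
  nets <- buildEdgeNetworks(es, mesh)
  expect_length(nets, 2)
  # a 5-edge simple path along one lattice row (consecutive nodes in a
  # row are mesh edges)
  xy <- nodeCoords(mesh)
  rowY <- unique(xy[, 2])
  rowY <- rowY[which.min(abs(rowY - 2))]
  inRow <- which(abs(xy[, 2] - rowY) < 1e-9)
  row0 <- inRow[order(xy[inRow, 1])][3:8]
  path <- cbind(pmin(row0[-6], row0[-1]), pmax(row0[-6], row0[-1]))
  esp <- new("EdgeSet", edges = matrix(as.integer(path), ncol = 2),
             seed = 1L, params = list())
  nets <- buildEdgeNetworks(esp, mesh)
  expect_length(nets, 1)
  expect_length(nets[[1]]$interior, 4)
  expect_length(nets[[1]]$tips, 2)
  # node splitting duplicates exactly the interior nodes of the crack
  sp <- splitMeshAlongEdges(mesh, esp@edges)
  expect_identical(nNodes(sp$mesh), nNodes(mesh) + 4L)
  expect_true(validObject(sp$mesh))
  expect_setequal(sp$origin[(nNodes(mesh) + 1):nNodes(sp$mesh)],
                  nets[[1]]$interior)
})

test_that("a closed fibrotic loop around a vein disconnects it", {
  mesh <- oneVeinAtrium()
  rim <- veinRims(mesh)$LSPV$junction
  ed <- uniqueEdges(mesh)
  onRim <- ed[, 1] %in% rim & ed[, 2] %in% rim
  loop <- ed[onRim, , drop = FALSE]
  sp <- splitMeshAlongEdges(mesh, loop)
  g <- igraph::graph_from_edgelist(uniqueEdges(sp$mesh), directed = FALSE)
  expect_gt(igraph::components(g)$no,
            igraph::components(igraph::graph_from_edgelist(
              uniqueEdges(mesh), directed = FALSE))$no)
})

test_that("edge sets round-trip through the text format", {
  mesh <- coarseAtrium()
  es <- selectPvFibroticEdges(mesh, coarseDistance(), 0.2, seed = 3)
  p <- file.path(tempdir(), "edges.txt")
  writeEdgeSet(es, p)
  back <- readEdgeSet(p)
  expect_identical(edgePairs(back), edgePairs(es))
  expect_identical(back@seed, es@seed)
  expect_equal(back@params$rho, 0.2)
})
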