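test_that("idealized atrium has the forced topology and clean labels", {
  mesh <- coarseAtrium()
  # disc with four holes: chi = 1 - 4
  expect_identical(eulerCharacteristic(mesh), -3L)
  expect_true(validObject(mesh))
  # every PV node carries exactly one vein label by construction; rims are
  # closed loops (every rim node has exactly two rim neighbours)
  for (v in PV_NAMES) {
    rim <- veinRims(mesh)[[v]]$junction
    sub <- uniqueEdges(mesh)
    onRim <- sub[, 1] %in% rim & sub[, 2] %in% rim
    deg <- table(factor(as.vector(sub[onRim, ]), levels = rim))
    expect_true(all(deg == 2), label = paste(v, "junction rim closed"))
  }
  # mean edge length near the target (the coarse fixture has a large
  # boundary fraction; the production-resolution check is in the
  # acceptance suite)
  expect_lt(abs(meanEdgeLength(mesh) - 1.0) / 1.0, 0.10)
})

test_that("distal rim circumference matches the requested vein radius", {
  mesh <- cylAtrium()
  rim <- veinRims(mesh)$LSPV$distal
  ed <- uniqueEdges(mesh)
  onRim <- ed[, 1] %in% rim & ed[, 2] %in% rim
  len <- sum(sqrt(rowSums((nodeCoords(mesh)[ed[onRim, 1], ] -
                             nodeCoords(mesh)[ed[onRim, 2], ])^2)))
  expect_lt(abs(len - 2 * pi * 5) / (2 * pi * 5), 0.05)
})

test_that("infeasible vein placement is rejected with a diagnostic", {
  expect_error(geometryParams(bodyRadius = 20,
                              veinRadius = c(LSPV = 12, LIPV = 12),
                              veinLength = c(LSPV = 5, LIPV = 5),
                              veinCenter = rbind(LSPV = c(-5, 0),
                                                 LIPV = c(5, 0)),
                              edgeLength = 1),
               "overlap")
  expect_error(geometryParams(bodyRadius = 10,
                              veinRadius = c(LSPV = 6),
                              veinLength = c(LSPV = 5),
                              veinCenter = rbind(LSPV = c(6, 0)),
                              edgeLength = 1),
               "does not fit")
})

test_that("distance parameter is a [0,1] junction-to-distal coordinate", {
  mesh <- coarseAtrium()
  d <- computeDistanceParameter(mesh, "LSPV")
  v <- fieldValues(d)
  rims <- veinRims(mesh)$LSPV
  expect_true(all(v[rims$junction] == 0))
  expect_true(all(v[rims$distal] == 1))
  def <- !is.na(v)
  expect_true(all(v[def] >= 0 & v[def] <= 1))
  # defined exactly on the vein
  expect_setequal(which(def), regionNodes(mesh, "LSPV"))
  # undefined off the vein
  expect_true(all(is.na(v[regionNodes(mesh, "LA_BODY")])))
})

test_that("distance parameter agrees with an independent Dijkstra oracle", {
  gp <- geometryParams(bodyRadius = 15, veinRadius = c(LSPV = 4),
                       veinLength = c(LSPV = 10),
                       veinCenter = rbind(LSPV = c(0, 0)),
                       edgeLength = 1)
  mesh <- generateIdealizedAtrium(gp)
  d <- fieldValues(computeDistanceParameter(mesh, "LSPV"))
  vn <- regionNodes(mesh, "LSPV")
  ed <- uniqueEdges(mesh)
  keep <- ed[, 1] %in% vn & ed[, 2] %in% vn
  ed <- ed[keep, , drop = FALSE]
  w <- sqrt(rowSums((nodeCoords(mesh)[ed[, 1], ] -
                       nodeCoords(mesh)[ed[, 2], ])^2))
  rims <- veinRims(mesh)$LSPV
  gj <- dijkstraOracle(nNodes(mesh), ed, w, rims$junction)
  gd <- dijkstraOracle(nNodes(mesh), ed, w, rims$distal)
  ref <- gj / (gj + gd)
  expect_equal(d[vn], ref[vn], tolerance = 1e-10)
  # axial midpoint of the straight 10 mm sleeve sits at d = 0.5
  zmid <- abs(nodeCoords(mesh)[vn, 3] - 5) < 0.5
  expect_true(all(abs(d[vn][zmid] - 0.5) <= 1 / 10 + 0.02))
})

test_that("fiber cases produce the documented arrangements", {
  mesh <- coarseAtrium()
  dist <- coarseDistance()
  tri <- meshTriangles(mesh)
  inVein <- nodeRegion(mesh)[tri[, 1]] == REGION_CODES[["LSPV"]] &
    nodeRegion(mesh)[tri[, 2]] == REGION_CODES[["LSPV"]] &
    nodeRegion(mesh)[tri[, 3]] == REGION_CODES[["LSPV"]]
  ctr <- coarseAtriumParams()$veinCenter["LSPV", ]
  # case 1: circumferential everywhere in the vein. The circumferential
  # direction is the level-set tangent of the ostial-distal coordinate:
  # fibers must be orthogonal to its gradient (exact), and geometrically
  # aligned with the analytic cylinder tangent to within the geodesic
  # discretization tolerance.
  m1 <- assignPvFibers(mesh, 1, distance = dist)
  grad <- atrialab:::.p1Gradient(mesh, fieldValues(dist), which(inVein))
  grad <- grad / sqrt(rowSums(grad^2))
  expect_lt(max(abs(rowSums(m1@fibers[inVein, ] * grad))), 1e-6)
  cent <- elementGeometry(m1)$centroid[inVein, ]
  circ <- cbind(-(cent[, 2] - ctr[2]), cent[, 1] - ctr[1], 0)
  circ <- circ / sqrt(rowSums(circ^2))
  align <- abs(rowSums(m1@fibers[inVein, ] * circ))
  expect_true(all(align > cos(0.15)))
  # case 4 on the finer cylinder: ~45 degrees between circumferential and
  # longitudinal at mid-sleeve (d = 0.5)
  cyl <- cylAtrium()
  dCyl <- computeAllDistanceParameters(cyl)
  c4 <- assignPvFibers(cyl, 4, distance = dCyl)
  triC <- meshTriangles(cyl)
  inC <- nodeRegion(cyl)[triC[, 1]] == REGION_CODES[["LSPV"]] &
    nodeRegion(cyl)[triC[, 2]] == REGION_CODES[["LSPV"]] &
    nodeRegion(cyl)[triC[, 3]] == REGION_CODES[["LSPV"]]
  dbarC <- (fieldValues(dCyl)[triC[inC, 1]] +
              fieldValues(dCyl)[triC[inC, 2]] +
              fieldValues(dCyl)[triC[inC, 3]]) / 3
  centC <- elementGeometry(cyl)$centroid[inC, ]
  circC <- cbind(-centC[, 2], centC[, 1], 0)
  circC <- circC / sqrt(rowSums(circC^2))
  mid <- abs(dbarC - 0.5) < 0.05
  angle <- acos(pmin(1, abs(rowSums(c4@fibers[inC, ][mid, ] *
                                      circC[mid, ]))))
  expect_true(all(abs(angle - pi / 4) < 0.1))
  expect_lt(abs(mean(angle) - pi / 4), 0.05)
  # case 4 on the coarse mesh for the remaining checks
  m4 <- assignPvFibers(mesh, 4, distance = dist)
  # case 6 with zero noise is case 4; with noise it differs but stays valid
  expect_equal(assignPvFibers(mesh, 6, seed = 5, sigma0 = 0,
                              distance = dist)@fibers, m4@fibers)
  m6 <- assignPvFibers(mesh, 6, seed = 5, sigma0 = 45, distance = dist)
  expect_true(validObject(m6))
  expect_gt(max(abs(m6@fibers - m4@fibers)), 0.01)
  # case-6 noise is seeded: same seed reproduces
  expect_equal(assignPvFibers(mesh, 6, seed = 5, sigma0 = 45,
                              distance = dist)@fibers, m6@fibers)
  expect_error(assignPvFibers(mesh, 9), "unknown fiber case")
})

test_that("bilayer fiber cases: epicardium of case 5 equals case 4", {
  mesh <- bilayerAtrium()
  dist <- computeAllDistanceParameters(mesh)
  m4 <- assignPvFibers(mesh, 4, distance = dist)
  m5 <- assignPvFibers(mesh, 5, distance = dist)
  epi <- which(mesh@layerOfNode[meshTriangles(mesh)[, 1]] == 2L)
  expect_equal(m4@fibers[epi, ], m5@fibers[epi, ])
  expect_true(validObject(m4))
})

test_that("PS region partition is disjoint, exhaustive and lesion-inclusive", {
  mesh <- coarseAtrium()
  reg <- definePsRegions(mesh)
  expect_length(reg, nNodes(mesh))
  expect_true(all(reg %in% 1:3))
  # lesion nodes belong to PV
  lesion <- which(nodeRegion(mesh) %in%
                    REGION_CODES[c("PVI_LESION_L", "PVI_LESION_R")])
  expect_true(all(reg[lesion] == 1L))
  # vein nodes are enclosed
  expect_true(all(reg[regionNodes(mesh, "LSPV")] == 1L))
  # the appendage is LA; no RA on the idealized mesh
  expect_true(all(reg[regionNodes(mesh, "LAA")] == 2L))
  expect_identical(sum(reg == 3L), 0L)
  expect_error(definePsRegions(tinyStrand()), "lesion")
})

test_that("synthetic LGE patterns honour their contracts", {
  mesh <- coarseAtrium()
  expect_true(all(fieldValues(generateSyntheticLge(mesh, "uniform",
                                                   scale = 0)) == 0))
  g <- generateSyntheticLge(mesh, "pv_graded")
  d <- fieldValues(coarseDistance())
  vn <- regionNodes(mesh, "LSPV")
  expect_equal(cor(fieldValues(g)[vn], d[vn], method = "spearman"), 1)
  p1 <- generateSyntheticLge(mesh, "patchy", seed = 7)
  p2 <- generateSyntheticLge(mesh, "patchy", seed = 7)
  expect_identical(fieldValues(p1), fieldValues(p2))
  expect_true(all(fieldValues(p1) >= 0 & fieldValues(p1) <= 1))
  expect_gt(max(abs(fieldValues(generateSyntheticLge(mesh, "patchy",
                                                     seed = 8)) -
                      fieldValues(p1))), 0)
  expect_error(generateSyntheticLge(mesh, "blobby"))
})

test_that("mesh generation is reproducible", {
  m1 <- generateIdealizedAtrium(coarseAtriumParams())
  m2 <- generateIdealizedAtrium(coarseAtriumParams())
  expect_identical(m1@nodes, m2@nodes)
  expect_identical(m1@triangles, m2@triangles)
  expect_identical(m1@nodeRegion, m2@nodeRegion)
})
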