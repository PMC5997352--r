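test_that("diffusion operator conserves uniform states", {
  mesh <- coarseAtrium()
  op <- assembleDiffusion(mesh, conductivityField(mesh))
  u <- rep(1, nrow(op$K))
  expect_lt(max(abs(op$K %*% u)), 1e-10)
  expect_lt(max(abs(Matrix::t(op$K) %*% u)), 1e-10)
  # and on a bilayer mesh with interlayer coupling
  b <- bilayerAtrium()
  opb <- assembleDiffusion(b, conductivityField(b))
  expect_lt(max(abs(opb$K %*% rep(1, nrow(opb$K)))), 1e-10)
})

test_that("resting tissue stays at rest and single waves activate once", {
  strand <- tinyStrand()
  cond <- conductivityField(strand)
  recRest <- runSimulation(strand, cond, list(), duration = 50,
                           model = "surrogate", sampleInterval = 5)
  expect_true(all(abs(voltage(recRest) + 80) < 1))
  stim <- stimulus(which(nodeCoords(strand)[, 1] < 1), 2)
  rec <- runSimulation(strand, cond, list(stim), duration = 120,
                       model = "surrogate", sampleInterval = 1)
  acts <- atrialab:::count_upcrossings(voltage(rec), -40)
  expect_true(all(acts == 1L))
})

test_that("simulation output is bitwise reproducible", {
  strand <- tinyStrand()
  cond <- conductivityField(strand)
  stim <- stimulus(which(nodeCoords(strand)[, 1] < 1), 2)
  r1 <- runSimulation(strand, cond, list(stim), duration = 40,
                      model = "surrogate", sampleInterval = 1)
  r2 <- runSimulation(strand, cond, list(stim), duration = 40,
                      model = "surrogate", sampleInterval = 1)
  expect_identical(voltage(r1), voltage(r2))
})

test_that("isotropic conduction is rotationally symmetric on a sheet", {
  sheet <- generateStrandMesh(20, 20, 0.5)
  cond <- conductivityField(sheet, sigmaL = 0.1746, sigmaT = 0.1746)
  ctr <- which.min(rowSums((nodeCoords(sheet) -
                              matrix(c(10, 10, 0), nNodes(sheet), 3,
                                     byrow = TRUE))^2))
  stim <- stimulus(which(rowSums((nodeCoords(sheet) -
                                    matrix(nodeCoords(sheet)[ctr, ],
                                           nNodes(sheet), 3,
                                           byrow = TRUE))^2) < 1), 2)
  rec <- runSimulation(sheet, cond, list(stim), duration = 60,
                       model = "surrogate", sampleInterval = 0.5)
  at <- atrialab:::first_activation_time(voltage(rec), sampleTimes(rec),
                                         -20)
  xy <- nodeCoords(sheet)
  alongX <- which(abs(xy[, 2] - 10) < 0.3 & abs(xy[, 1] - 16) < 0.3)[1]
  alongY <- which(abs(xy[, 1] - 10) < 0.3 & abs(xy[, 2] - 16) < 0.3)[1]
  expect_lt(abs(at[alongX] - at[alongY]) / at[alongX], 0.1)
})

test_that("conductivity scaling modes follow the gradient contracts", {
  mesh <- coarseAtrium()
  d <- coarseDistance()
  cond <- conductivityField(mesh)
  expect_equal(scaleConductivity(cond, mesh, "homogeneous", 1)@sigmaL,
               cond@sigmaL)
  tri <- meshTriangles(mesh)
  pv <- nodeRegion(mesh)[tri[, 1]] %in% REGION_CODES[PV_NAMES] &
    nodeRegion(mesh)[tri[, 2]] %in% REGION_CODES[PV_NAMES] &
    nodeRegion(mesh)[tri[, 3]] %in% REGION_CODES[PV_NAMES]
  dbar <- (fieldValues(d)[tri[, 1]] + fieldValues(d)[tri[, 2]] +
             fieldValues(d)[tri[, 3]]) / 3
  junctionEls <- which(pv & dbar < 0.1)
  distalEls <- which(pv & dbar > 0.9)
  g1 <- scaleConductivity(cond, mesh, "gradient_distal_slow", 5,
                          distance = d)
  expect_true(all(g1@sigmaL[junctionEls] > cond@sigmaL[junctionEls] / 1.6))
  expect_true(all(g1@sigmaL[distalEls] < cond@sigmaL[distalEls] / 4))
  g2 <- scaleConductivity(cond, mesh, "gradient_junction_slow", 5,
                          distance = d)
  expect_true(all(g2@sigmaL[junctionEls] < cond@sigmaL[junctionEls] / 4))
  expect_true(all(g2@sigmaL[distalEls] > cond@sigmaL[distalEls] / 1.6))
  expect_error(scaleConductivity(cond, mesh, "gradient_distal_slow", 5),
               "distance")
})

test_that("PVI sets lesion conductivity to 0.001 S/m and blocks exits", {
  mesh <- coarseAtrium()
  cond <- applyPvi(conductivityField(mesh), mesh)
  lesionEls <- which(apply(matrix(nodeRegion(mesh)[meshTriangles(mesh)] %in%
                                    REGION_CODES[c("PVI_LESION_L",
                                                   "PVI_LESION_R")],
                                  ncol = 3), 1, any))
  expect_true(all(cond@sigmaL[lesionEls] == 0.001))
  expect_true(all(cond@sigmaT[lesionEls] == 0.001))
  bodyFar <- which.max(abs(nodeCoords(mesh)[, 2]) *
                         (nodeRegion(mesh) == REGION_CODES[["LA_BODY"]]))
  expect_gt(conductivityField(mesh)@sigmaL[1], 0.001)
  # pacing a vein inside the closed lesion loop must not escape
  stim <- stimulus(veinRims(mesh)$LSPV$distal, 2)
  rec <- runSimulation(mesh, cond, list(stim), duration = 150,
                       model = "surrogate", sampleInterval = 2)
  at <- atrialab:::first_activation_time(voltage(rec), sampleTimes(rec),
                                         -20)
  expect_true(all(!is.na(at[regionNodes(mesh, "LSPV")])))
  outside <- definePsRegions(mesh) == 2L
  expect_true(all(is.na(at[outside])))
  expect_error(applyPvi(conductivityField(tinyStrand()), tinyStrand()),
               "lesion")
})

test_that("a decoupled edge chain blocks a planar wave iff it spans the width", {
  strand <- rightAngleGrid(25, 7, 0.5)  # 12 x 3 mm, vertical edges exist
  xy <- nodeCoords(strand)
  ed <- uniqueEdges(strand)
  # vertical chain of edges at x = 6
  vertical <- abs(xy[ed[, 1], 1] - xy[ed[, 2], 1]) < 1e-9 &
    abs(xy[ed[, 1], 1] - 6) < 1e-9
  full <- ed[vertical, , drop = FALSE]
  ys <- pmin(xy[full[, 1], 2], xy[full[, 2], 2])
  partial <- full[ys > 0.3, , drop = FALSE]  # leaves a gap at the bottom
  runBlock <- function(chain) {
    cond <- conductivityField(strand)
    cond@decoupledEdges <- chain
    stim <- stimulus(which(xy[, 1] < 0.6), 2)
    rec <- runSimulation(strand, cond, list(stim), duration = 120,
                         model = "surrogate", sampleInterval = 2)
    simMesh <- splitMeshAlongEdges(strand, chain)$mesh
    at <- atrialab:::first_activation_time(voltage(rec), sampleTimes(rec),
                                           -20)
    probe <- which(simMesh@nodes[, 1] > 11)
    all(!is.na(at[probe]))
  }
  expect_false(runBlock(full))    # full-width crack blocks
  expect_true(runBlock(partial))  # gapped crack lets the wave through
})

test_that("measured CV converges under time-step refinement", {
  strand <- tinyStrand()
  cv1 <- strandCv(0.1746, strand = strand, model = "surrogate",
                  probeGap = 10, dtOde = 0.05, dtDiff = 0.2)
  cv2 <- strandCv(0.1746, strand = strand, model = "surrogate",
                  probeGap = 10, dtOde = 0.025, dtDiff = 0.1)
  expect_lt(abs(cv1 - cv2) / cv2, 0.02)
})

test_that("probe errors are reported", {
  strand <- tinyStrand()
  rec <- runSimulation(strand, conductivityField(strand), list(),
                       duration = 20, model = "surrogate",
                       sampleInterval = 2)
  expect_error(measureCv(rec, strand, 1, nNodes(strand)),
               "did not activate")
})
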