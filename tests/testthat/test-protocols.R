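test_that("battery enumeration is the documented Cartesian product", {
  mesh <- coarseAtrium()
  bat <- buildBattery(mesh)
  expect_identical(nrow(bat), 32L)
  expect_identical(bat$vein[1], "LSPV")
  expect_identical(bat$ci[1], 200)
  expect_identical(bat$protocol, 1:32)
  # vein-major, CI ascending
  expect_identical(bat$ci[1:8], STANDARD_CIS)
  expect_identical(unique(bat$vein), PV_NAMES)
  one <- buildBattery(oneVeinAtrium(), veins = "LSPV")
  expect_identical(nrow(one), 8L)
  expect_error(buildBattery(oneVeinAtrium()), "lacks vein")
})

test_that("inducibility ratio reproduces the printed roundings", {
  expect_identical(inducibilityRatio(c(rep(TRUE, 12), rep(FALSE, 20))),
                   0.38)
  expect_identical(inducibilityRatio(c(TRUE, rep(FALSE, 31))), 0.03)
  expect_identical(inducibilityRatio(rep(FALSE, 32)), 0)
  expect_error(inducibilityRatio(logical(0)), "no outcomes")
})

test_that("induction detection separates quiescence from reentry", {
  mesh <- generateStrandMesh(16, 16, 0.8)
  n <- nNodes(mesh)
  # quiescent record: one early paced wave, rest thereafter
  tt <- seq(0, 1598, by = 2)
  Vq <- matrix(-80, length(tt), n)
  Vq[tt < 150, ] <- ifelse(outer(tt[tt < 150], nodeCoords(mesh)[, 1],
                                 function(t, x) abs(t - 3 * x - 20) < 15),
                           0, -80)
  recQ <- makeRecord(Vq, dt = 2)
  outQ <- detectInduction(recQ, mesh, lastStimEnd = 100, tSustain = 1000)
  expect_false(outQ$induced)
  expect_false(outQ$byPs)
  expect_false(outQ$byReactivation)
  expect_false(is.na(outQ$terminationTime))
  # persistent rotor: induced via both sub-criteria
  recR <- rotorMovie(mesh, cbind(8, 8, 1), nFrames = 800, dt = 2)
  outR <- detectInduction(recR, mesh, lastStimEnd = 100, tSustain = 1000)
  expect_true(outR$induced)
  expect_true(outR$byPs)
  expect_true(outR$byReactivation)
  expect_lt(outR$inductionTime, 400)
  expect_error(detectInduction(recQ, mesh, lastStimEnd = 1500),
               "too short")
})

test_that("exact McNemar p-values match the enumeration oracle", {
  for (n in 0:12) for (b in 0:n) {
    expect_equal(mcnemarTest(b = b, c = n - b),
                 mcnemarOracle(b, n - b),
                 label = sprintf("b=%d c=%d", b, n - b))
  }
  # worked cases: no discordance, near-complete asymmetry, symmetry
  expect_identical(mcnemarTest(b = 0, c = 0), 1)
  expect_equal(mcnemarTest(b = 1, c = 7), 0.0703125, tolerance = 1e-7)
  expect_identical(mcnemarTest(b = 5, c = 5), 1)
  # pairs interface and chi-square variant
  pairs <- cbind(c(TRUE, TRUE, FALSE, FALSE, TRUE),
                 c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(mcnemarTest(pairs), mcnemarTest(b = 2, c = 1))
  p <- mcnemarTest(b = 3, c = 10, method = "chisq")
  expect_equal(p, stats::mcnemar.test(matrix(c(5, 3, 10, 5), 2))$p.value)
})

test_that("post-PVI classification separates the three outcome classes", {
  mesh <- coarseAtrium()
  n <- nNodes(mesh)
  # quiescent field -> TERMINATION
  recT <- makeRecord(matrix(-80, 200, n), dt = 2)
  expect_identical(classifyPostPvi(recT, mesh)$outcome, "TERMINATION")
  # circulating activation around the mesh without any PS -> MACROREENTRY
  xy <- nodeCoords(mesh)
  theta <- atan2(xy[, 2], xy[, 1])
  tt <- seq(0, 1198, by = 2)
  period <- 300
  Vm <- outer(tt, theta, function(t, th) {
    ph <- (th - 2 * pi * t / period) %% (2 * pi)
    ifelse(ph < 0.8, 0, -80)
  })
  # suppress the winding singularity at the centre: clamp the middle patch
  ctrNodes <- which(xy[, 1]^2 + xy[, 2]^2 < 36)
  Vm[, ctrNodes] <- -80
  recM <- makeRecord(Vm, dt = 2)
  clsM <- classifyPostPvi(recM, mesh)
  expect_identical(clsM$outcome, "MACROREENTRY")
  expect_equal(clsM$details$periodicity$cl, period, tolerance = 0.05)
  # stable rotor in the LA body -> LA_ROTORS
  recR <- rotorMovie(mesh, cbind(0, -14, 1), nFrames = 600, dt = 2)
  clsR <- classifyPostPvi(recR, mesh)
  expect_identical(clsR$outcome, "LA_ROTORS")
  expect_gt(clsR$details$sustainedPs, 0)
})

test_that("a PVI experiment on a quiescent episode terminates", {
  mesh <- coarseAtrium()
  cond <- conductivityField(mesh)
  n <- nNodes(mesh)
  res <- runPviExperiment(mesh, cond, state = cbind(rep(0, n), rep(1, n)),
                          model = "surrogate", postMs = 400)
  expect_identical(res$outcome, "TERMINATION")
})

test_that("protocol stimuli follow the pacing schedule", {
  mesh <- oneVeinAtrium()
  ps <- protocolStimuli(mesh, "LSPV", ci = 280)
  expect_length(ps$stimuli, 2)
  pvTimes <- ps$stimuli[[2]]$times
  expect_length(pvTimes, 5)
  expect_equal(diff(pvTimes), rep(160, 4))
  expect_equal(pvTimes[1], 700 + 280)  # anchored to the second sinus beat
  sinus <- ps$stimuli[[1]]$times
  expect_equal(diff(sinus)[1], 700)
  expect_gte(max(sinus), max(pvTimes))  # sinus continues throughout
  # ectopic site is inside the distal third of the vein
  d <- fieldValues(computeDistanceParameter(mesh, "LSPV"))
  expect_true(all(d[ps$stimuli[[2]]$nodes] > 0.55))
})
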