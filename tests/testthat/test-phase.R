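test_that("phase of a sinusoid advances linearly and ignores offsets", {
  dt <- 2
  tt <- seq(0, 2000 - dt, by = dt)
  f <- 5e-3  # 5 Hz in 1/ms
  V <- matrix(sin(2 * pi * f * tt), ncol = 1)
  rec <- makeRecord(cbind(V, V + 17), dt = dt)
  pm <- computePhase(rec, guard = 100)
  ph <- pm$phase[pm$valid, 1]
  unw <- cumsum(c(ph[1], atrialab:::.wrapPi(diff(ph))))
  tv <- pm$times[pm$valid]
  fit <- lm(unw ~ tv)
  expect_equal(unname(coef(fit)[2]), 2 * pi * f, tolerance = 0.01)
  expect_lt(max(abs(residuals(fit))), 0.05)
  # constant voltage offset does not change the phase
  expect_lt(max(abs(atrialab:::.wrapPi(pm$phase[, 2] - pm$phase[, 1]))),
            1e-6)
  # constant signals are flagged undefined
  rec2 <- makeRecord(cbind(V, matrix(-80, nrow(V), 1)), dt = dt)
  pm2 <- computePhase(rec2, guard = 100)
  expect_identical(pm2$undefinedNodes, 2L)
  expect_true(all(is.na(pm2$phase[, 2])))
})

test_that("topological charge finds analytic winding fields exactly", {
  mesh <- generateStrandMesh(20, 20, 0.5)
  xy <- nodeCoords(mesh)
  # single +1 winding about (10.2, 10.3)
  phi <- atan2(xy[, 2] - 10.3, xy[, 1] - 10.2)
  pm <- list(phase = matrix(phi, nrow = 1), times = 0, valid = TRUE,
             undefinedNodes = integer(0))
  ev <- detectPs(pm, mesh, frames = 1)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$charge, 1L)
  expect_lt((ev$x - 10.2)^2 + (ev$y - 10.3)^2, 0.5^2)
  # uniform phase: no events
  pm0 <- list(phase = matrix(1.3, 1, nNodes(mesh)), times = 0,
              valid = TRUE, undefinedNodes = integer(0))
  expect_identical(nrow(detectPs(pm0, mesh, frames = 1)), 0L)
  # opposite pair: two events of opposite chirality, zero total charge
  phi2 <- atan2(xy[, 2] - 6, xy[, 1] - 6) - atan2(xy[, 2] - 14,
                                                  xy[, 1] - 14)
  pmp <- list(phase = matrix(phi2, nrow = 1), times = 0, valid = TRUE,
              undefinedNodes = integer(0))
  evp <- detectPs(pmp, mesh, frames = 1)
  expect_identical(nrow(evp), 2L)
  expect_identical(sum(evp$charge), 0L)
  expect_setequal(evp$charge, c(-1L, 1L))
})

test_that("per-element charge is quantized and matches the loop oracle", {
  mesh <- generateStrandMesh(20, 20, 0.5)
  xy <- nodeCoords(mesh)
  phi <- atan2(xy[, 2] - 10.3, xy[, 1] - 10.2) +
    0.5 * sin(xy[, 1]) * cos(xy[, 2])  # smooth disturbance
  tri <- meshTriangles(mesh)
  p1 <- phi[tri[, 1]]; p2 <- phi[tri[, 2]]; p3 <- phi[tri[, 3]]
  w <- atrialab:::.wrapPi(p2 - p1) + atrialab:::.wrapPi(p3 - p2) +
    atrialab:::.wrapPi(p1 - p3)
  charge <- round(w / (2 * pi))
  expect_true(all(charge %in% -1:1))
  # 50 random closed loops (lattice rectangles): enclosed charge equals
  # the independent winding number along the loop
  set.seed(2024)
  for (rep in 1:50) {
    x0 <- runif(1, 1, 9); y0 <- runif(1, 1, 9)
    x1 <- x0 + runif(1, 2, 9); y1 <- y0 + runif(1, 2, 9)
    # keep the loop clear of the singular core so the enclosed-charge
    # comparison is unambiguous at mesh resolution
    if (min(abs(c(x0, x1) - 10.2)) < 0.8 ||
        min(abs(c(y0, y1) - 10.3)) < 0.8) next
    onB <- function(lo, hi, v) v >= lo - 1e-9 & v <= hi + 1e-9
    south <- which(abs(xy[, 2] - y0) < 0.26 & onB(x0, x1, xy[, 1]))
    north <- which(abs(xy[, 2] - y1) < 0.26 & onB(x0, x1, xy[, 1]))
    east <- which(abs(xy[, 1] - x1) < 0.26 & onB(y0, y1, xy[, 2]))
    west <- which(abs(xy[, 1] - x0) < 0.26 & onB(y0, y1, xy[, 2]))
    loop <- c(south[order(xy[south, 1])], east[order(xy[east, 2])],
              rev(north[order(xy[north, 1])]), rev(west[order(xy[west, 2])]))
    loop <- loop[!duplicated(loop)]
    if (length(loop) < 8) next
    wn <- loopWindingNumber(phi, loop)
    inside <- xy[, 1] > x0 & xy[, 1] < x1 & xy[, 2] > y0 & xy[, 2] < y1
    enclosed <- sum(charge[inside[tri[, 1]] & inside[tri[, 2]] &
                             inside[tri[, 3]]])
    expect_identical(wn, as.integer(enclosed))
  }
})

test_that("rotor movies unwrap by one cycle per rotation period", {
  mesh <- generateStrandMesh(16, 16, 0.8)
  period <- 200
  rec <- rotorMovie(mesh, cbind(8, 8, 1), omega = 2 * pi / period,
                    nFrames = 400, dt = 2)
  pm <- computePhase(rec, guard = 100)
  node <- which.min(rowSums((nodeCoords(mesh) -
                               matrix(c(12, 8, 0), nNodes(mesh), 3,
                                      byrow = TRUE))^2))
  ph <- pm$phase[pm$valid, node]
  unw <- cumsum(c(0, atrialab:::.wrapPi(diff(ph))))
  cycles <- abs(unw[length(unw)]) / (2 * pi)
  expected <- diff(range(pm$times[pm$valid])) / period
  expect_lt(abs(cycles - expected) / expected, 0.05)
  # and the detected PS sits at the rotor core, same chirality every frame
  ev <- detectPs(pm, mesh)
  perFrame <- table(ev$t)
  expect_true(all(perFrame == 1))
  expect_true(all(ev$charge == ev$charge[1]))
  expect_true(all((ev$x - 8)^2 + (ev$y - 8)^2 < 1.5^2))
})

test_that("trajectory linking respects radius and chirality", {
  mkEv <- function(t, x, y, charge = 1L)
    data.frame(t = t, element = 1L, charge = charge, x = x, y = y, z = 0)
  # stationary PS: one trajectory spanning the window
  ev <- do.call(rbind, lapply(0:99, function(f) mkEv(2 * f, 5, 5)))
  tr <- trackPs(ev)
  expect_identical(length(unique(tr$trajectory)), 1L)
  expect_equal(attr(tr, "lifetimes")$lifetime, 198)
  # movement at 2 mm/frame: linked iff the radius allows
  ev2 <- do.call(rbind, lapply(0:20, function(f) mkEv(2 * f, 2 * f, 0)))
  expect_identical(length(unique(trackPs(ev2, maxJump = 2.5)$trajectory)),
                   1L)
  expect_gt(length(unique(trackPs(ev2, maxJump = 1.5)$trajectory)), 1L)
  # two well-separated PSs never swap identity
  ev3 <- do.call(rbind, lapply(0:50, function(f)
    rbind(mkEv(2 * f, 0, 0), mkEv(2 * f, 20, 0, charge = -1L))))
  tr3 <- trackPs(ev3)
  expect_identical(length(unique(tr3$trajectory)), 2L)
  byTraj <- split(tr3$x, tr3$trajectory)
  expect_true(all(vapply(byTraj, function(x) length(unique(x)) == 1,
                         logical(1))))
})

test_that("PS density maps have compact support and stable normalization", {
  mesh <- generateStrandMesh(20, 10, 0.5)
  ev <- data.frame(t = seq(0, 998, by = 2), element = 1L, charge = 1L,
                   x = 10, y = 5, z = 0)
  dm <- psDensity(ev, mesh, window = c(0, 1000), radius = 2.5)
  v <- fieldValues(dm)
  d2 <- (nodeCoords(mesh)[, 1] - 10)^2 + (nodeCoords(mesh)[, 2] - 5)^2
  expect_true(all(v[d2 > 2.5^2] == 0))
  expect_true(all(v[d2 <= 2.4^2] > 0))
  # doubling the window with proportional events keeps per-ms density
  ev2 <- data.frame(t = seq(0, 1998, by = 2), element = 1L, charge = 1L,
                    x = 10, y = 5, z = 0)
  dm2 <- psDensity(ev2, mesh, window = c(0, 2000), radius = 2.5)
  expect_equal(fieldValues(dm2), v, tolerance = 1e-3)
  # 2:1 dwell times give a 2:1 peak ratio
  evA <- rbind(ev, data.frame(t = seq(0, 498, by = 2), element = 1L,
                              charge = 1L, x = 3, y = 5, z = 0))
  dmA <- psDensity(evA, mesh, window = c(0, 1000), radius = 2.5)
  vA <- fieldValues(dmA)
  peakMain <- max(vA[d2 <= 1])
  d2b <- (nodeCoords(mesh)[, 1] - 3)^2 + (nodeCoords(mesh)[, 2] - 5)^2
  expect_equal(peakMain / max(vA[d2b <= 1]), 2, tolerance = 0.05)
  # empty event list is a valid zero map
  none <- psDensity(ev[0, ], mesh, window = c(0, 100))
  expect_true(all(fieldValues(none) == 0))
})

test_that("PV PS density ratio counts events by analysis region", {
  mesh <- coarseAtrium()
  regions <- definePsRegions(mesh)
  cent <- elementGeometry(mesh)$centroid
  elReg <- atrialab:::.elementRegion(mesh, regions)
  pvEls <- which(elReg == 1L)[1:30]
  laEls <- which(elReg == 2L)[1:70]
  ev <- data.frame(t = seq_len(100), element = c(pvEls, laEls),
                   charge = 1L, x = cent[c(pvEls, laEls), 1],
                   y = cent[c(pvEls, laEls), 2],
                   z = cent[c(pvEls, laEls), 3])
  rr <- pvPsDensityRatio(ev, mesh, regions)
  expect_identical(rr$pvCount, 30L)
  expect_identical(rr$totalCount, 100L)
  expect_equal(rr$ratio, 0.3)
  # all-PV and no-PV extremes
  expect_equal(pvPsDensityRatio(ev[1:30, ], mesh, regions)$ratio, 1)
  expect_equal(pvPsDensityRatio(ev[31:100, ], mesh, regions)$ratio, 0)
  # invariant under temporal subsampling of a stationary fixture
  sub <- ev[seq(1, 100, by = 2), ]
  expect_equal(pvPsDensityRatio(sub, mesh, regions)$ratio, 0.3)
})
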