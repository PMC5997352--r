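#' Construct a conductivity field
#'
#' Monodomain surface model: per-element longitudinal and transverse
#' conductivities (S/m), a surface-to-volume ratio and membrane capacitance.
#' The effective diffusivity along the fiber is
#' \code{D = 1000 sigma / (beta Cm)} in mm^2/ms. The default baseline
#' conductivities are tuned so a fiber-aligned planar wave on a 0.34 mm
#' strand propagates at 0.67 m/s with the baseline LA membrane model
#' (see \code{\link{tuneStrandConductivity}}); the anisotropy ratio
#' sigma_l : sigma_t = 4 (2:1 CV anisotropy).
#'
#' @param mesh a \code{SurfaceMesh}.
#' @param sigmaL,sigmaT longitudinal/transverse conductivity (S/m), scalar
#'   or per element.
#' @param beta surface-to-volume ratio (1/m).
#' @param cm membrane capacitance (F/m^2).
#' @param interlayerG interlayer coupling rate (1/ms) for bilayer meshes.
#' @return a \code{\linkS4class{ConductivityField}}
#' @export
conductivityField <- function(mesh, sigmaL = 0.1746, sigmaT = 0.04365,
                              beta = 140000, cm = 0.01,
                              interlayerG = 0.5) {
  m <- nElements(mesh)
  new("ConductivityField",
      sigmaL = rep_len(sigmaL, m), sigmaT = rep_len(sigmaT, m),
      beta = beta, cm = cm, interlayerG = interlayerG,
      decoupledEdges = matrix(integer(0), 0, 2))
}

#' Scale PV conductivities
#'
#' Divides both conductivities on PV elements by \code{r}, either
#' homogeneously or following the ostial-distal gradient:
#' \code{gradient_distal_slow} interpolates the divisor from 1 at the
#' junction to \code{r} at the distal boundary (slowest conduction
#' distally); \code{gradient_junction_slow} reverses the gradient (slowest
#' conduction at the LA/PV junction).
#'
#' @param cond a \code{ConductivityField}.
#' @param mesh the mesh it belongs to.
#' @param mode "homogeneous", "gradient_distal_slow" or
#'   "gradient_junction_slow".
#' @param r conductivity divisor (>= 1; the study grid uses 1, 2, 3, 5).
#' @param distance distance-parameter field (gradient modes).
#' @return the rescaled \code{ConductivityField}
#' @export
scaleConductivity <- function(cond, mesh,
                              mode = c("homogeneous", "gradient_distal_slow",
                                       "gradient_junction_slow"),
                              r, distance = NULL) {
  mode <- match.arg(mode)
  stopifnot(r >= 1)
  tri <- mesh@triangles
  pvCode <- REGION_CODES[PV_NAMES]
  inPv <- mesh@nodeRegion[tri[, 1]] %in% pvCode &
    mesh@nodeRegion[tri[, 2]] %in% pvCode &
    mesh@nodeRegion[tri[, 3]] %in% pvCode
  if (mode == "homogeneous") {
    div <- rep(r, sum(inPv))
  } else {
    if (is.null(distance)) stop("gradient modes require a distance field")
    d <- distance@values
    dbar <- (d[tri[inPv, 1]] + d[tri[inPv, 2]] + d[tri[inPv, 3]]) / 3
    dbar[is.na(dbar)] <- 0
    div <- if (mode == "gradient_distal_slow") 1 + (r - 1) * dbar
           else r - (r - 1) * dbar
  }
  cond@sigmaL[inPv] <- cond@sigmaL[inPv] / div
  cond@sigmaT[inPv] <- cond@sigmaT[inPv] / div
  cond
}

#' Apply pulmonary-vein isolation
#'
#' Sets both conductivities to 0.001 S/m on every element touching a PVI
#' lesion band, electrically disconnecting the veins.
#'
#' @param cond a \code{ConductivityField}.
#' @param mesh the mesh it belongs to (lesion bands labelled).
#' @return the modified \code{ConductivityField}
#' @export
applyPvi <- function(cond, mesh) {
  lesion <- mesh@nodeRegion %in% REGION_CODES[c("PVI_LESION_L",
                                                "PVI_LESION_R")]
  if (!any(lesion)) stop("no PVI lesion region on this mesh")
  tri <- mesh@triangles
  hit <- lesion[tri[, 1]] | lesion[tri[, 2]] | lesion[tri[, 3]]
  cond@sigmaL[hit] <- 0.001
  cond@sigmaT[hit] <- 0.001
  cond
}

#' Split a mesh along decoupled (fibrotic) edge networks
#'
#' Implements no-flux interstitial barriers by node splitting: nodes
#' interior to a connected decoupled-edge path are duplicated, one copy per
#' side of the crack, and the incident elements are reassigned; path
#' endpoints (crack tips) remain shared, so the barrier is a true
#' discontinuity with intact tips.
#'
#' @param mesh a \code{SurfaceMesh}.
#' @param edges integer matrix (k x 2) of decoupled edges.
#' @return list: \code{mesh} (split mesh), \code{origin} (for each node of
#'   the new mesh, the originating node in the input mesh)
#' @export
splitMeshAlongEdges <- function(mesh, edges) {
  n0 <- nNodes(mesh)
  origin <- seq_len(n0)
  if (!nrow(edges)) return(list(mesh = mesh, origin = origin))
  tri <- mesh@triangles
  crackKey <- paste(pmin(edges[, 1], edges[, 2]),
                    pmax(edges[, 1], edges[, 2]))
  isCrack <- function(a, b) paste(pmin(a, b), pmax(a, b)) %in% crackKey
  # incident elements per crack node
  crackNodes <- sort(unique(as.vector(edges)))
  incid <- lapply(crackNodes, function(v) which(tri[, 1] == v |
                                                  tri[, 2] == v |
                                                  tri[, 3] == v))
  names(incid) <- crackNodes
  nodes <- mesh@nodes
  region <- mesh@nodeRegion
  layer <- mesh@layerOfNode
  for (vi in seq_along(crackNodes)) {
    v <- crackNodes[vi]
    els <- incid[[vi]]
    if (length(els) < 2) next
    # adjacency between incident elements through non-crack spokes at v
    other <- lapply(els, function(e) setdiff(tri[e, ], v))
    adj <- matrix(FALSE, length(els), length(els))
    for (a in seq_along(els)) for (b in seq_len(a - 1)) {
      shared <- intersect(other[[a]], other[[b]])
      if (length(shared) && any(!isCrack(rep(v, length(shared)), shared)))
        adj[a, b] <- adj[b, a] <- TRUE
    }
    comp <- integer(length(els)); cc <- 0L
    for (s in seq_along(els)) {
      if (comp[s]) next
      cc <- cc + 1L
      stack <- s
      while (length(stack)) {
        cur <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (comp[cur]) next
        comp[cur] <- cc
        stack <- c(stack, which(adj[cur, ] & comp == 0L))
      }
    }
    if (cc < 2) next
    for (side in 2:cc) {
      newId <- nrow(nodes) + 1L
      nodes <- rbind(nodes, nodes[v, , drop = FALSE])
      region <- c(region, region[v])
      layer <- c(layer, layer[v])
      origin <- c(origin, v)
      for (e in els[comp == side]) tri[e, tri[e, ] == v] <- newId
    }
  }
  out <- new("SurfaceMesh", nodes = nodes,
             triangles = matrix(as.integer(tri), ncol = 3),
             fibers = mesh@fibers, nodeRegion = as.integer(region),
             layerOfNode = as.integer(layer),
             interlayerPairs = mesh@interlayerPairs, rims = mesh@rims)
  list(mesh = out, origin = origin)
}

#' Assemble the monodomain diffusion operator
#'
#' Linear (P1) finite elements on the triangulated surface with per-element
#' conductivity tensor \code{sigma = sigma_t I + (sigma_l - sigma_t) f f'}
#' in the element plane. Decoupled edges are realised by node splitting
#' (see \code{\link{splitMeshAlongEdges}}), so no flux crosses them; with
#' pure no-flux boundaries the operator annihilates spatially uniform
#' states (rows sum to zero). Interlayer pairs add resistive coupling.
#'
#' @param mesh a \code{SurfaceMesh}.
#' @param cond a \code{ConductivityField} for this mesh.
#' @return list: \code{K} (sparse stiffness, 1/ms scale after mass
#'   division), \code{M} (lumped nodal masses, mm^2), \code{mesh} (the
#'   split mesh actually simulated), \code{origin} (node origin map)
#' @export
assembleDiffusion <- function(mesh, cond) {
  sp <- splitMeshAlongEdges(mesh, cond@decoupledEdges)
  msh <- sp$mesh
  tri <- msh@triangles
  n <- nNodes(msh)
  p1 <- msh@nodes[tri[, 1], , drop = FALSE]
  p2 <- msh@nodes[tri[, 2], , drop = FALSE]
  p3 <- msh@nodes[tri[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  l1 <- sqrt(rowSums(e1^2))
  u1 <- e1 / l1
  x3 <- rowSums(e2 * u1)
  pe <- e2 - x3 * u1
  y3 <- sqrt(rowSums(pe^2))
  u2 <- pe / y3
  A <- 0.5 * l1 * y3
  # diffusivities (mm^2/ms)
  Dl <- 1000 * cond@sigmaL / (cond@beta * cond@cm)
  Dt <- 1000 * cond@sigmaT / (cond@beta * cond@cm)
  fx <- rowSums(msh@fibers * u1)
  fy <- rowSums(msh@fibers * u2)
  G11 <- Dt + (Dl - Dt) * fx * fx
  G12 <- (Dl - Dt) * fx * fy
  G22 <- Dt + (Dl - Dt) * fy * fy
  # P1 shape-function gradients in local coords
  twoA <- 2 * A
  g1x <- -y3 / twoA; g1y <- (x3 - l1) / twoA
  g2x <- y3 / twoA;  g2y <- -x3 / twoA
  g3x <- rep(0, length(A)); g3y <- l1 / twoA
  gx <- cbind(g1x, g2x, g3x); gy <- cbind(g1y, g2y, g3y)
  ii <- jj <- xx <- vector("list", 9)
  k <- 0
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1
    ii[[k]] <- tri[, a]; jj[[k]] <- tri[, b]
    xx[[k]] <- A * (gx[, a] * (G11 * gx[, b] + G12 * gy[, b]) +
                      gy[, a] * (G12 * gx[, b] + G22 * gy[, b]))
  }
  iv <- unlist(ii); jv <- unlist(jj); xv <- unlist(xx)
  # lumped mass
  M <- rep(0, n)
  for (a in 1:3) {
    acc <- rowsum(A / 3, tri[, a])
    M[as.integer(rownames(acc))] <- M[as.integer(rownames(acc))] + acc[, 1]
  }
  # interlayer resistive coupling
  ip <- msh@interlayerPairs
  if (nrow(ip)) {
    gil <- cond@interlayerG * (M[ip[, 1]] + M[ip[, 2]]) / 2
    iv <- c(iv, ip[, 1], ip[, 2], ip[, 1], ip[, 2])
    jv <- c(jv, ip[, 1], ip[, 2], ip[, 2], ip[, 1])
    xv <- c(xv, gil, gil, -gil, -gil)
  }
  K <- Matrix::sparseMatrix(i = iv, j = jv, x = xv, dims = c(n, n))
  # consistent P1 mass matrix (A/12 off-diagonal, A/6 diagonal blocks)
  im <- jm <- xm <- vector("list", 9)
  k <- 0
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1
    im[[k]] <- tri[, a]; jm[[k]] <- tri[, b]
    xm[[k]] <- if (a == b) A / 6 else A / 12
  }
  Mc <- Matrix::sparseMatrix(i = unlist(im), j = unlist(jm),
                             x = unlist(xm), dims = c(n, n))
  list(K = K, M = M, Mc = Mc, mesh = msh, origin = sp$origin)
}

#' Define a stimulus
#'
#' @param nodes node indices receiving current.
#' @param times onset times (ms).
#' @param duration pulse duration (ms).
#' @param amplitude current (uA/uF for the CRN model; model units for the
#'   surrogate).
#' @return stimulus list
#' @export
stimulus <- function(nodes, times, duration = 2, amplitude = NULL) {
  stopifnot(length(nodes) > 0, all(times >= 0))
  list(nodes = as.integer(nodes), times = as.numeric(times),
       duration = duration, amplitude = amplitude)
}

#' Per-node CRN multiplier matrix for a mesh
#'
#' Builds the (n x 12) conductance-multiplier matrix from the regional
#' parameter table, optionally modulated by a per-node IK1 multiplier field
#' (from \code{\link{buildIk1Field}}).
#'
#' @param mesh a \code{SurfaceMesh}.
#' @param ik1Field optional \code{ScalarNodeField} of IK1 multipliers.
#' @param version ionic table version.
#' @return numeric matrix (n x 12), columns \code{\link{MULT_NAMES}}
#' @export
buildNodeMultipliers <- function(mesh, ik1Field = NULL, version = "v1") {
  regions <- .regionName(mesh@nodeRegion)
  out <- matrix(1, nNodes(mesh), length(MULT_NAMES),
                dimnames = list(NULL, MULT_NAMES))
  for (rg in unique(regions)) {
    out[regions == rg, ] <- matrix(makeRegionParams(rg, version),
                                   sum(regions == rg), length(MULT_NAMES),
                                   byrow = TRUE)
  }
  if (!is.null(ik1Field))
    out[, "gK1"] <- out[, "gK1"] * ik1Field@values
  out
}

#' Per-node surrogate multiplier matrix
#'
#' Column 1 scales \code{tauClose} (APD), column 2 scales \code{tauIn}
#' (excitability). An IK1-like multiplier field k maps to a 1/k scaling of
#' \code{tauClose}; a per-region APD scale sets the PV-LA APD difference.
#'
#' @param mesh a \code{SurfaceMesh}.
#' @param pvApdScale tauClose multiplier on PV nodes relative to LA.
#' @param ik1Field optional IK1-multiplier field.
#' @return numeric matrix (n x 2)
#' @export
buildSurrogateMultipliers <- function(mesh, pvApdScale = 1,
                                      ik1Field = NULL) {
  out <- matrix(1, nNodes(mesh), 2)
  pv <- mesh@nodeRegion %in% REGION_CODES[PV_NAMES]
  out[pv, 1] <- pvApdScale
  if (!is.null(ik1Field)) out[, 1] <- out[, 1] / ik1Field@values
  out
}

#' Run a monodomain simulation
#'
#' Operator-split time stepping: the membrane model advances with
#' \code{nsub = dtDiff/dtOde} Rush-Larsen/Euler substeps, then diffusion is
#' solved implicitly (backward Euler with a cached Cholesky factorisation).
#' The run is deterministic given its inputs; the seed is recorded in the
#' metadata for provenance.
#'
#' @param mesh a \code{SurfaceMesh}.
#' @param cond a \code{ConductivityField}.
#' @param stimuli list of \code{\link{stimulus}} objects.
#' @param duration simulated time (ms).
#' @param model "crn" or "surrogate".
#' @param mult per-node multiplier matrix
#'   (\code{\link{buildNodeMultipliers}} or
#'   \code{\link{buildSurrogateMultipliers}}); defaults to the regional
#'   table (CRN) or all-ones (surrogate).
#' @param dtOde membrane integration step (ms; default 0.05 for CRN tissue,
#'   0.1 for the surrogate).
#' @param dtDiff diffusion step (ms).
#' @param sampleInterval record sampling interval (ms).
#' @param seed integer recorded in metadata.
#' @param surrogateParamsList surrogate model parameters.
#' @param massLumping use the lumped (diagonal) mass matrix instead of the
#'   consistent P1 mass matrix. The consistent mass (default FALSE) keeps
#'   the planar CV close to its continuum value at 0.34 mm resolution;
#'   lumping is cheaper but slows waves on coarse meshes.
#' @param stopWhenQuiescentAfter if non-NULL, the run ends early once
#'   \code{t} exceeds this value, every node is below the quiescence
#'   threshold and no stimulus is pending (the record is truncated; the
#'   stop time is logged in \code{meta$earlyStop}).
#' @param initialState optional state matrix to resume from.
#' @return a \code{\linkS4class{VoltageRecord}} (voltage in mV); the final
#'   state matrix is attached as \code{meta$finalState}
#' @export
runSimulation <- function(mesh, cond, stimuli, duration,
                          model = c("crn", "surrogate"), mult = NULL,
                          dtOde = NULL, dtDiff = NULL, sampleInterval = 1,
                          seed = 1L, surrogateParamsList = surrogateParams(),
                          massLumping = FALSE,
                          stopWhenQuiescentAfter = NULL,
                          initialState = NULL) {
  model <- match.arg(model)
  if (is.null(dtOde)) dtOde <- if (model == "crn") 0.05 else 0.1
  if (is.null(dtDiff)) dtDiff <- if (model == "crn") 0.1 else 0.5
  nsub <- max(1L, round(dtDiff / dtOde))
  op <- assembleDiffusion(mesh, cond)
  msh <- op$mesh
  n <- nNodes(msh)
  if (is.null(mult)) {
    mult <- if (model == "crn") buildNodeMultipliers(mesh)
            else matrix(1, nNodes(mesh), 2)
  }
  mult <- mult[op$origin, , drop = FALSE]
  Mmat <- if (massLumping) Matrix::Diagonal(x = op$M) else op$Mc
  A <- Mmat + dtDiff * op$K
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  if (model == "crn") {
    state <- if (is.null(initialState))
      matrix(rep(crn_initial_state(), each = n), nrow = n)
    else initialState
    vOf <- function(s) s[, 1]
    rest <- -81.18; quiThr <- -70
    defaultAmp <- 30
  } else {
    state <- if (is.null(initialState)) cbind(rep(0, n), rep(1, n))
    else initialState
    vOf <- function(s) -80 + 100 * s[, 1]
    rest <- -80; quiThr <- -70
    defaultAmp <- 0.5
    spv <- unlist(surrogateParamsList[c("tauIn", "tauOut", "tauOpen",
                                        "tauClose", "uGate")])
  }
  # map stimulus nodes through splitting (duplicates inherit stimulation)
  stimNodes <- lapply(stimuli, function(s)
    which(op$origin %in% s$nodes))
  lastStimEnd <- if (length(stimuli))
    max(vapply(stimuli, function(s) max(s$times) + s$duration, 0))
  else 0
  nstep <- round(duration / dtDiff)
  every <- max(1L, round(sampleInterval / dtDiff))
  nsamp <- nstep %/% every + 1L
  V <- matrix(NA_real_, nsamp, n)
  tt <- numeric(nsamp)
  isamp <- 0L
  istim <- numeric(n)
  earlyStop <- NA_real_
  for (step in 0:nstep) {
    t <- step * dtDiff
    if (step %% every == 0L) {
      isamp <- isamp + 1L
      V[isamp, ] <- vOf(state)
      tt[isamp] <- t
    }
    if (step == nstep) break
    istim[] <- 0
    for (si in seq_along(stimuli)) {
      s <- stimuli[[si]]
      if (any(t + dtDiff > s$times & t < s$times + s$duration)) {
        amp <- s$amplitude %||% defaultAmp
        istim[stimNodes[[si]]] <- istim[stimNodes[[si]]] + amp
      }
    }
    if (model == "crn") {
      crn_step_inplace(state, mult, istim, dtOde, nsub)
    } else {
      ms_step_inplace(state, mult, istim, spv, dtOde, nsub)
    }
    vnew <- Matrix::solve(ch, Mmat %*% state[, 1], system = "A")
    set_col_inplace(state, 1L, as.numeric(vnew))
    if (!is.null(stopWhenQuiescentAfter) && t > stopWhenQuiescentAfter &&
        t > lastStimEnd && all(vOf(state) < quiThr) &&
        !any(vapply(stimuli, function(s) any(s$times > t), logical(1)))) {
      earlyStop <- t
      break
    }
  }
  keep <- seq_len(isamp)
  meta <- list(model = model, dtOde = dtOde, dtDiff = dtDiff, seed = seed,
               nNodesOriginal = nNodes(mesh), origin = op$origin,
               earlyStop = earlyStop, finalState = state,
               stimuli = stimuli)
  new("VoltageRecord", V = V[keep, , drop = FALSE], times = tt[keep],
      sampleInterval = sampleInterval, meta = meta)
}

#' Measure planar-wave conduction velocity between two probes
#'
#' Activation time is the time of maximum dV/dt within the upstroke of the
#' first crossing of -20 mV; CV is the probe separation divided by the
#' activation-time difference (mm/ms = m/s).
#'
#' @param record a \code{VoltageRecord}.
#' @param mesh the simulated mesh (for probe coordinates).
#' @param probeA,probeB node indices.
#' @param threshold activation threshold (mV).
#' @return conduction velocity (m/s)
#' @export
measureCv <- function(record, mesh, probeA, probeB, threshold = -20) {
  at <- first_activation_time(record@V[, c(probeA, probeB), drop = FALSE],
                              record@times, threshold)
  if (anyNA(at)) stop("probe did not activate")
  d <- sqrt(sum((mesh@nodes[probeA, ] - mesh@nodes[probeB, ])^2))
  d / abs(diff(at))
}

#' Planar-wave CV on a fiber-aligned strand
#'
#' Builds a strand, stimulates its left edge, and measures CV between two
#' probes on the strand midline separated by \code{probeGap} mm and at
#' least 5 mm from stimulus and boundary.
#'
#' @param sigmaL longitudinal conductivity (S/m); \code{sigmaT} is scaled
#'   to keep the 4:1 anisotropy.
#' @param strand a strand mesh from \code{\link{generateStrandMesh}}.
#' @param model "crn" or "surrogate".
#' @param mult optional multiplier matrix (defaults to LA-body parameters).
#' @param divisor conductivity divisor applied to the whole strand.
#' @param probeGap probe separation (mm).
#' @param dtOde,dtDiff integration steps (ms).
#' @param ... passed to \code{\link{runSimulation}}.
#' @return CV in m/s
#' @export
strandCv <- function(sigmaL, strand = generateStrandMesh(), model = "crn",
                     mult = NULL, divisor = 1, probeGap = 20,
                     dtOde = NULL, dtDiff = NULL, ...) {
  cond <- conductivityField(strand, sigmaL = sigmaL / divisor,
                            sigmaT = sigmaL / 4 / divisor)
  xr <- range(strand@nodes[, 1])
  ymid <- mean(range(strand@nodes[, 2]))
  stimN <- which(strand@nodes[, 1] < xr[1] + 1.0)
  midline <- abs(strand@nodes[, 2] - ymid) < 0.5
  x0 <- mean(xr) - probeGap / 2; x1 <- mean(xr) + probeGap / 2
  pA <- which(midline)[which.min(abs(strand@nodes[midline, 1] - x0))]
  pB <- which(midline)[which.min(abs(strand@nodes[midline, 1] - x1))]
  # generous duration: slowest plausible wave at ~0.1 m/s
  dur <- 15 + (xr[2] - xr[1]) / 0.1
  if (is.null(mult) && model == "crn")
    mult <- matrix(makeRegionParams("LA_BODY"), nNodes(strand),
                   length(MULT_NAMES), byrow = TRUE,
                   dimnames = list(NULL, MULT_NAMES))
  rec <- runSimulation(strand, cond,
                       list(stimulus(stimN, 5)), duration = dur,
                       model = model, mult = mult, dtOde = dtOde,
                       dtDiff = dtDiff, sampleInterval = 0.25,
                       stopWhenQuiescentAfter = 30, ...)
  measureCv(rec, strand, pA, pB)
}

#' Tune baseline conductivity to a target planar CV
#'
#' Uses the continuum square-root law (CV proportional to sqrt(sigma)) as a
#' fixed-point iteration: two to three strand simulations give the
#' conductivity whose measured CV matches the target within tolerance.
#'
#' @param targetCv target CV (m/s).
#' @param sigma0 starting longitudinal conductivity (S/m).
#' @param tol relative tolerance.
#' @param maxIter maximum iterations.
#' @param ... passed to \code{\link{strandCv}}.
#' @return list: \code{sigmaL}, \code{cv} (achieved), \code{iterations}
#' @export
tuneStrandConductivity <- function(targetCv = 0.67, sigma0 = 0.28,
                                   tol = 0.01, maxIter = 4, ...) {
  sig <- sigma0
  for (it in seq_len(maxIter)) {
    cv <- strandCv(sig, ...)
    if (abs(cv - targetCv) / targetCv < tol)
      return(list(sigmaL = sig, cv = cv, iterations = it))
    sig <- sig * (targetCv / cv)^2
  }
  list(sigmaL = sig, cv = strandCv(sig, ...), iterations = maxIter + 1)
}
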