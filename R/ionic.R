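#' Names of the per-current conductance multipliers
#' @export
MULT_NAMES <- c("gNa", "gK1", "gto", "gKur", "gCaL", "gKr", "gKs",
                "gbNa", "gbCa", "gNaK", "gNaCa", "gpCa")

.ionicTableCache <- new.env(parent = emptyenv())

#' Load the versioned ionic parameter table
#'
#' The table holds per-current maximal-conductance multipliers relative to
#' the published Courtemanche-Ramirez-Nattel values: a persistent-AF
#' electrical-remodelling row, a global row (sodium-conductance doubling and
#' 20\% IK1 reduction) and one regional row per region. Multipliers compose
#' multiplicatively (\code{af_remodelling * global * regional}).
#'
#' @param version table version string.
#' @return data.frame with one row per scope
#' @export
ionicTable <- function(version = "v1") {
  key <- version
  if (is.null(.ionicTableCache[[key]])) {
    path <- system.file("extdata",
                        paste0("ionic_regions_", version, ".tsv"),
                        package = "atrialab")
    if (!nzchar(path)) stop("unknown ionic table version: ", version)
    .ionicTableCache[[key]] <- read.table(path, header = TRUE, sep = "\t",
                                          comment.char = "#",
                                          stringsAsFactors = FALSE)
  }
  .ionicTableCache[[key]]
}

#' Composed ionic parameters for a region
#'
#' Returns the effective per-current multipliers for a region: published CRN
#' values x persistent-AF remodelling x global modifiers (gNa x2, gK1 x0.8)
#' x regional factors.
#'
#' @param region region name (e.g. "LA_BODY", "LSPV").
#' @param version ionic table version.
#' @param experimental optional named numeric of additional multipliers
#'   (e.g. \code{c(gK1 = 2.5)} for the IK1 scaling experiments).
#' @return named numeric vector over \code{\link{MULT_NAMES}}
#' @export
makeRegionParams <- function(region, version = "v1", experimental = NULL) {
  tab <- ionicTable(version)
  if (!region %in% tab$scope) stop("unknown region: ", region)
  pick <- function(s) unlist(tab[tab$scope == s, MULT_NAMES])
  m <- pick("af_remodelling") * pick("global") * pick(region)
  if (!is.null(experimental)) {
    bad <- setdiff(names(experimental), MULT_NAMES)
    if (length(bad)) stop("unknown multiplier(s): ",
                          paste(bad, collapse = ", "))
    m[names(experimental)] <- m[names(experimental)] * experimental
  }
  stopifnot(all(m > 0))
  setNames(as.numeric(m), MULT_NAMES)
}

#' Time-derivative of the CRN state
#'
#' Right-hand side of the 21-variable CRN ODE system with all conductance
#' multipliers applied (voltage in mV/ms, gates in 1/ms, concentrations in
#' mM/ms).
#'
#' @param state named 21-vector (see \code{\link{crnInitialState}}).
#' @param params multiplier vector over \code{\link{MULT_NAMES}} or region
#'   name.
#' @param stim stimulus current (uA/uF).
#' @return named derivative vector
#' @export
crnDerivatives <- function(state, params = setNames(rep(1, 12), MULT_NAMES),
                           stim = 0) {
  if (is.character(params)) params <- makeRegionParams(params)
  if (any(!is.finite(state))) stop("non-finite state")
  crn_rhs_cpp(as.numeric(state), as.numeric(params[MULT_NAMES]), stim)
}

#' Published CRN initial (resting) state
#' @return named numeric vector of the 21 state variables
#' @export
crnInitialState <- function() crn_initial_state()

#' Default single-cell stimulus (2 ms square pulse at twice threshold)
#'
#' @return list with amplitude (uA/uF) and duration (ms)
#' @export
defaultStimulus <- function() list(amplitude = 20, duration = 2)

#' Pace a single cell and return its voltage trace
#'
#' Runs \code{nBeats} beats at the given cycle length from the published
#' resting state; the trace of the whole run is returned so steady-state
#' convergence and capture can be checked. A beat "captures" when it
#' triggers an action potential (upstroke crossing -40 mV); loss of 1:1
#' capture is flagged, not silently ignored.
#'
#' @param params multiplier vector from \code{\link{makeRegionParams}}, or a
#'   region name.
#' @param cl cycle length (ms).
#' @param nBeats number of beats (default 20 conditioning + measurement).
#' @param dt integration step (ms).
#' @param model "crn" or "surrogate".
#' @param sampleDt trace sampling interval (ms).
#' @param stim stimulus list (amplitude, duration), see
#'   \code{\link{defaultStimulus}}.
#' @param surrogateParams surrogate model parameters
#'   (\code{\link{surrogateParams}}).
#' @return list: \code{t}, \code{V} (mV), \code{capture} (beats captured /
#'   beats delivered), \code{captured1to1} logical
#' @export
paceCell <- function(params, cl, nBeats = 20, dt = 0.02, model = "crn",
                     sampleDt = 0.5, stim = defaultStimulus(),
                     surrogateParams = NULL) {
  stopifnot(cl > stim$duration, nBeats >= 1)
  if (is.character(params)) params <- makeRegionParams(params)
  if (model == "crn") {
    tr <- crn_pace_cpp(as.numeric(params[MULT_NAMES]), cl, as.integer(nBeats),
                       dt, stim$amplitude, stim$duration, sampleDt)
    v <- tr$V
  } else if (model == "surrogate") {
    sp <- surrogateParams %||% surrogateParams()
    mult <- c(1 / params[["gK1"]], 1)  # IK1-like knob maps to tau_close
    tr <- ms_pace_cpp(mult, unlist(sp[c("tauIn", "tauOut", "tauOpen",
                                        "tauClose", "uGate")]),
                      cl, as.integer(nBeats), max(dt, 0.05), 0.6,
                      stim$duration, sampleDt)
    v <- -80 + 100 * tr$V
  } else stop("unknown model: ", model)
  nAct <- sum(v[-1] >= -40 & v[-length(v)] < -40)
  list(t = tr$t, V = v, capture = nAct / nBeats,
       captured1to1 = nAct == nBeats)
}

#' Action potential duration at 90\% repolarisation
#'
#' Measured on one beat of a voltage trace: activation is the time of
#' maximum upstroke dV/dt, the amplitude reference is the beat's own peak
#' minus its preceding diastolic minimum, and the crossing of the 90\%
#' repolarisation level is located by linear interpolation between samples.
#' The measurement is invariant to uniform time shifts and voltage offsets.
#'
#' @param t sample times (ms).
#' @param V voltage (mV).
#' @param beat which beat to measure: "last" or a beat number.
#' @return APD90 in ms (NA when the beat does not repolarise within the
#'   trace)
#' @export
apd90 <- function(t, V, beat = "last") {
  if (length(t) != length(V)) stop("t and V must have equal length")
  # upstroke threshold relative to the trace's own range, so the
  # measurement is invariant to voltage offsets
  thrUp <- min(V) + 0.5 * (max(V) - min(V))
  up <- which(V[-1] >= thrUp & V[-length(V)] < thrUp)
  if (!length(up)) stop("no upstroke detected")
  i0 <- if (identical(beat, "last")) up[length(up)] else up[beat]
  if (is.na(i0)) stop("requested beat not present")
  dv <- diff(V) / diff(t)
  seg <- i0:min(i0 + 60, length(dv))
  ia <- seg[which.max(dv[seg])]
  vMin <- min(V[max(1, i0 - 400):i0])
  vMax <- max(V[ia:min(ia + 1500, length(V))])
  thr <- vMax - 0.9 * (vMax - vMin)
  j <- ia + 5L
  while (j < length(V) && V[j + 1] > thr) j <- j + 1L
  if (j >= length(V)) return(NA_real_)
  tc <- t[j] + (t[j + 1] - t[j]) * (V[j] - thr) / (V[j] - V[j + 1])
  tc - t[ia]
}

#' Steady-state APD90 of a region model
#'
#' Paces to steady state and measures APD90 on the final captured beat,
#' reporting capture status alongside.
#'
#' @inheritParams paceCell
#' @return list: \code{apd90} (ms), \code{capture}, \code{captured1to1},
#'   \code{converged} (last two captured beats within 1 ms)
#' @export
steadyStateApd <- function(params, cl, nBeats = 20, dt = 0.02,
                           model = "crn", stim = defaultStimulus()) {
  tr <- paceCell(params, cl, nBeats, dt, model, stim = stim)
  up <- which(tr$V[-1] >= -40 & tr$V[-length(tr$V)] < -40)
  aLast <- apd90(tr$t, tr$V, "last")
  aPrev <- if (length(up) >= 2) apd90(tr$t, tr$V, length(up) - 1) else NA
  list(apd90 = aLast, capture = tr$capture,
       captured1to1 = tr$captured1to1,
       converged = !is.na(aPrev) && abs(aLast - aPrev) <= 1)
}

#' Per-node IK1 multiplier field
#'
#' Homogeneous mode applies the scaling \code{k} to every PV node; gradient
#' mode varies it from baseline (1) at the LA/PV junction to \code{k} at the
#' distal boundary via \code{1 + (k - 1) d}, where \code{d} is the
#' ostial-distal distance parameter. Non-PV nodes are unchanged
#' (multiplier 1).
#'
#' @param mesh a \code{SurfaceMesh}.
#' @param mode "homogeneous" or "gradient".
#' @param k maximum IK1 scaling factor (clinically motivated range
#'   [0.5, 2.5]; values outside produce a warning).
#' @param distance distance-parameter field (required in gradient mode).
#' @return a \code{\linkS4class{ScalarNodeField}} of multipliers (no NA)
#' @export
buildIk1Field <- function(mesh, mode = c("homogeneous", "gradient"), k,
                          distance = NULL) {
  mode <- match.arg(mode)
  if (k < 0.5 || k > 2.5)
    warning("IK1 scaling k = ", k, " is outside the clinical range [0.5, 2.5]")
  val <- rep(1, nNodes(mesh))
  pv <- mesh@nodeRegion %in% REGION_CODES[PV_NAMES]
  if (mode == "homogeneous") {
    val[pv] <- k
  } else {
    if (is.null(distance)) stop("gradient mode requires a distance field")
    d <- distance@values
    def <- pv & !is.na(d)
    val[def] <- 1 + (k - 1) * d[def]
  }
  .newField(val, sprintf("ik1.%s.k%g", mode, k))
}

# ---------------------------------------------------------------------------
# Mitchell-Schaeffer surrogate
# ---------------------------------------------------------------------------

#' Parameters of the two-variable surrogate model
#'
#' Mitchell-Schaeffer excitable model: normalized voltage u and recovery
#' gate h, with time constants in ms. The defaults give an APD90 near the
#' atrial range; \code{\link{calibrateSurrogate}} adjusts \code{tauClose}
#' (APD) and returns a conductivity scale (CV).
#'
#' @param tauIn,tauOut,tauOpen,tauClose time constants (ms).
#' @param uGate excitation threshold.
#' @return named list
#' @export
surrogateParams <- function(tauIn = 0.3, tauOut = 6, tauOpen = 120,
                            tauClose = 150, uGate = 0.13) {
  list(tauIn = tauIn, tauOut = tauOut, tauOpen = tauOpen,
       tauClose = tauClose, uGate = uGate)
}

#' Calibrate the surrogate model to a target APD
#'
#' Secant iteration on \code{tauClose} so the paced single-cell APD90
#' matches \code{targetApd} within tolerance.
#'
#' @param targetApd target APD90 (ms).
#' @param cl pacing cycle length (ms).
#' @param tol relative tolerance.
#' @param params starting \code{\link{surrogateParams}}.
#' @return calibrated parameter list with attribute \code{achievedApd}
#' @export
calibrateSurrogate <- function(targetApd, cl = 1000, tol = 0.02,
                               params = surrogateParams()) {
  measure <- function(tc) {
    p <- params; p$tauClose <- tc
    tr <- paceCell(c(gK1 = 1), cl, nBeats = 6, model = "surrogate",
                   surrogateParams = p)
    apd90(tr$t, tr$V)
  }
  x1 <- params$tauClose; a1 <- measure(x1)
  x2 <- x1 * targetApd / a1; a2 <- measure(x2)
  for (i in 1:8) {
    if (abs(a2 - targetApd) / targetApd < tol) break
    x3 <- x2 + (targetApd - a2) * (x2 - x1) / (a2 - a1)
    x1 <- x2; a1 <- a2; x2 <- max(5, x3); a2 <- measure(x2)
  }
  params$tauClose <- x2
  attr(params, "achievedApd") <- a2
  params
}
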