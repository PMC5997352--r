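#' Standard coupling intervals of the inducibility battery (ms)
#' @export
STANDARD_CIS <- c(200, 240, 280, 320, 360, 400, 440, 480)

#' Build the extrastimulus inducibility battery
#'
#' The standard battery is the Cartesian product of the eight coupling
#' intervals (200-480 ms in 40 ms steps) and the four PVs: 32 protocols in
#' deterministic vein-major, CI-ascending order. Sinus rhythm is paced at
#' the SAN patch at cycle length 700 ms throughout; each protocol adds five
#' ectopic beats at cycle length 160 ms in one vein, the first beat
#' starting one coupling interval after the onset of its anchor sinus beat.
#'
#' @param mesh a \code{SurfaceMesh} with labelled veins.
#' @param cis coupling intervals (ms).
#' @param veins vein names to pace.
#' @return data.frame: protocol id, vein, ci
#' @export
buildBattery <- function(mesh, cis = STANDARD_CIS, veins = PV_NAMES) {
  have <- unique(.regionName(mesh@nodeRegion))
  missing <- setdiff(veins, have)
  if (length(missing))
    stop("mesh lacks vein(s): ", paste(missing, collapse = ", "))
  out <- data.frame(vein = rep(veins, each = length(cis)),
                    ci = rep(sort(cis), length(veins)))
  out <- cbind(protocol = seq_len(nrow(out)), out)
  out
}

#' Pacing schedule and stimuli for one battery protocol
#'
#' Sinus beats at the SAN patch every 700 ms from t = 0. The PV train
#' (5 beats, CL 160 ms) starts CI ms after the anchor sinus beat (the
#' second sinus beat, so the tissue is conditioned); the ectopic site is a
#' 1.5 mm-radius node patch in the distal third of the vein.
#'
#' @param mesh a \code{SurfaceMesh}.
#' @param vein vein to pace.
#' @param ci coupling interval (ms).
#' @param sinusCl sinus cycle length (ms).
#' @param pvCl ectopic cycle length (ms).
#' @param nPvBeats ectopic beat count.
#' @param anchorBeat index of the sinus beat anchoring the CI (1-based).
#' @param tailMs observation time after the last stimulus (ms).
#' @param distance optional distance field (to locate the distal third).
#' @return list: stimuli, duration, lastStimEnd
#' @export
protocolStimuli <- function(mesh, vein, ci, sinusCl = 700, pvCl = 160,
                            nPvBeats = 5, anchorBeat = 2, tailMs = 1200,
                            distance = NULL) {
  sanN <- regionNodes(mesh, "SAN")
  if (!length(sanN)) stop("mesh has no SAN patch")
  if (is.null(distance)) distance <- computeDistanceParameter(mesh, vein)
  d <- distance@values
  vn <- which(mesh@nodeRegion == REGION_CODES[[vein]])
  distalish <- vn[!is.na(d[vn]) & d[vn] >= 2 / 3]
  ctr <- distalish[which.min(abs(d[distalish] - 0.8))]
  d2 <- rowSums((mesh@nodes - matrix(mesh@nodes[ctr, ], nNodes(mesh), 3,
                                     byrow = TRUE))^2)
  site <- which(d2 <= 1.5^2 & mesh@nodeRegion == REGION_CODES[[vein]])
  tTrain <- (anchorBeat - 1) * sinusCl + ci
  pvTimes <- tTrain + pvCl * (seq_len(nPvBeats) - 1)
  lastEnd <- max(pvTimes) + 2
  duration <- lastEnd + tailMs
  sinusTimes <- seq(0, duration, by = sinusCl)
  list(stimuli = list(stimulus(sanN, sinusTimes, duration = 2),
                      stimulus(site, pvTimes, duration = 2)),
       duration = duration, lastStimEnd = lastEnd)
}

#' Detect arrhythmia induction in a protocol record
#'
#' A protocol counts as induced when self-sustained activity persists
#' beyond \code{tSustain} ms after the end of the last ectopic stimulus,
#' operationalized by two logged sub-criteria: (a) a phase-singularity
#' trajectory of lifetime at least \code{psSustainMs} in the
#' post-stimulus window (transient wavebreak during a paced beat produces
#' short-lived PS pairs that are not reentry), or (b) some node activating
#' at least \code{minReactivations} times in that window \emph{beyond} the
#' activations accounted for by continued (sinus) pacing — paced beats
#' delivered after \code{lastStimEnd} are read from the record metadata
#' and discounted. Either sub-criterion suffices.
#'
#' @param record a \code{VoltageRecord} covering at least \code{tSustain}
#'   ms beyond the last stimulus.
#' @param mesh the simulated mesh (after any node splitting, i.e.
#'   \code{record} columns match it).
#' @param lastStimEnd end time of the last ectopic stimulus (ms).
#' @param tSustain sustain window (ms).
#' @param minReactivations excess activation count for sub-criterion (b).
#' @param psSustainMs PS-trajectory lifetime threshold for sub-criterion
#'   (a), ms.
#' @return list: induced, byPs, byReactivation, inductionTime (start of
#'   the first sustained PS trajectory, NA if not induced),
#'   terminationTime
#' @export
detectInduction <- function(record, mesh, lastStimEnd, tSustain = 1000,
                            minReactivations = 3, psSustainMs = 300) {
  tt <- record@times
  if (is.na(record@meta$earlyStop) &&
      max(tt) < lastStimEnd + tSustain - 1e-6)
    stop("record too short for the sustain window")
  sel <- which(tt > lastStimEnd)
  induced <- FALSE; byPs <- FALSE; byReact <- FALSE
  inductionTime <- NA_real_
  terminationTime <- NA_real_
  if (length(sel) >= 4) {
    v <- record@V[sel, , drop = FALSE]
    cnt <- count_upcrossings(v, -40)
    # activations explained by pacing that continues past lastStimEnd
    stims <- record@meta$stimuli %||% list()
    nPacedLate <- sum(vapply(stims, function(s)
      sum(s$times > lastStimEnd & s$times <= max(tt)), numeric(1)))
    byReact <- any(cnt >= nPacedLate + minReactivations)
    # quiescence: all nodes below threshold at the end
    lastRow <- v[nrow(v), ]
    if (!is.na(record@meta$earlyStop)) {
      terminationTime <- record@meta$earlyStop
    } else if (all(lastRow < -70)) {
      active <- apply(v > -70, 1, any)
      terminationTime <- tt[sel[max(c(which(active), 1))]]
    }
    win <- c(lastStimEnd, max(tt))
    if (diff(win) > 220) {
      pm <- computePhase(record, window = win, guard = 100)
      ev <- detectPs(pm, mesh,
                     frames = which(pm$valid)[seq(1, sum(pm$valid),
                                                  by = 2)])
      tr <- trackPs(ev)
      lt <- attr(tr, "lifetimes")
      sustained <- lt[lt$lifetime >= psSustainMs, , drop = FALSE]
      byPs <- nrow(sustained) > 0
      if (byPs) inductionTime <- min(sustained$start)
    }
    induced <- byPs || byReact
    if (induced && is.na(inductionTime)) inductionTime <- lastStimEnd
  }
  list(induced = induced, byPs = byPs, byReactivation = byReact,
       inductionTime = inductionTime, terminationTime = terminationTime)
}

#' Inducibility ratio
#'
#' Proportion of protocols resulting in reentry. Reported to two decimals
#' in the study tables (12/32 prints as 0.38, 1/32 as 0.03).
#'
#' @param outcomes logical vector (or list of \code{detectInduction}
#'   results).
#' @param digits decimals for the reported value (NULL = full precision).
#' @return fraction in [0, 1]
#' @export
inducibilityRatio <- function(outcomes, digits = 2) {
  if (is.list(outcomes))
    outcomes <- vapply(outcomes, function(o) isTRUE(o$induced), logical(1))
  if (!length(outcomes)) stop("no outcomes")
  r <- mean(outcomes)
  if (!is.null(digits)) round(r, digits) else r
}

#' Run one battery protocol
#'
#' @param mesh a \code{SurfaceMesh}.
#' @param cond a \code{ConductivityField}.
#' @param vein,ci protocol coordinates.
#' @param model "crn" or "surrogate".
#' @param mult per-node multiplier matrix.
#' @param tSustain sustain window (ms).
#' @param distance optional distance field.
#' @param ... passed to \code{\link{runSimulation}}.
#' @return list: outcome (from \code{\link{detectInduction}}), record,
#'   simMesh
#' @export
runProtocol <- function(mesh, cond, vein, ci, model = "surrogate",
                        mult = NULL, tSustain = 1000, distance = NULL,
                        ...) {
  ps <- protocolStimuli(mesh, vein, ci, tailMs = tSustain + 200,
                        distance = distance)
  rec <- runSimulation(mesh, cond, ps$stimuli, duration = ps$duration,
                       model = model, mult = mult,
                       stopWhenQuiescentAfter = ps$lastStimEnd + 50, ...)
  simMesh <- splitMeshAlongEdges(mesh, cond@decoupledEdges)$mesh
  out <- detectInduction(rec, simMesh, ps$lastStimEnd, tSustain = tSustain)
  list(outcome = out, record = rec, simMesh = simMesh)
}

#' Run a full inducibility battery
#'
#' @inheritParams runProtocol
#' @param battery data.frame from \code{\link{buildBattery}}.
#' @param keepRecords keep the voltage records (memory!).
#' @param verbose print one line per protocol.
#' @return data.frame battery with outcome columns; attribute
#'   \code{records} when kept
#' @export
runBattery <- function(mesh, cond, battery = buildBattery(mesh),
                       model = "surrogate", mult = NULL, tSustain = 1000,
                       keepRecords = FALSE, verbose = FALSE, ...) {
  dists <- list()
  res <- vector("list", nrow(battery))
  recs <- if (keepRecords) vector("list", nrow(battery)) else NULL
  for (i in seq_len(nrow(battery))) {
    v <- battery$vein[i]
    if (is.null(dists[[v]])) dists[[v]] <- computeDistanceParameter(mesh, v)
    r <- runProtocol(mesh, cond, v, battery$ci[i], model = model,
                     mult = mult, tSustain = tSustain,
                     distance = dists[[v]], ...)
    res[[i]] <- r$outcome
    if (keepRecords) recs[[i]] <- r$record
    if (verbose)
      message(sprintf("protocol %d (%s, CI %d): %s", battery$protocol[i],
                      v, battery$ci[i],
                      if (r$outcome$induced) "induced" else "-"))
  }
  battery$induced <- vapply(res, function(o) o$induced, logical(1))
  battery$byPs <- vapply(res, function(o) o$byPs, logical(1))
  battery$byReactivation <- vapply(res, function(o) o$byReactivation,
                                   logical(1))
  battery$inductionTime <- vapply(res, function(o)
    o$inductionTime %||% NA_real_, numeric(1))
  if (keepRecords) attr(battery, "records") <- recs
  battery
}

#' In-silico pulmonary-vein isolation experiment
#'
#' Eligibility requires the arrhythmia to have lasted at least 2 s after
#' initiation. PVI is applied 2 s post-initiation; the simulation continues
#' for at least 1 s, and the outcome 1 s after PVI is classified as:
#' \describe{
#'   \item{TERMINATION}{no activity: every node within 5 mV of rest and no
#'     activations in the final 200 ms;}
#'   \item{LA_ROTORS}{at least one sustained PS (trajectory lifetime >=
#'     \code{sustainedMs}) in the LA body;}
#'   \item{MACROREENTRY}{persisting activity without sustained PSs
#'     (anatomical reentry around the lesion sets / mitral ring); the
#'     periodicity of activation is recorded.}
#' }
#'
#' @param mesh a \code{SurfaceMesh} with lesion bands.
#' @param cond pre-PVI \code{ConductivityField}.
#' @param state state matrix of the ongoing AF episode at \code{tInit + 2000}
#'   ms (from \code{meta$finalState} of the induction record).
#' @param model,mult as in \code{\link{runSimulation}}.
#' @param postMs post-PVI simulated time (ms).
#' @param sustainedMs sustained-PS lifetime threshold (ms).
#' @param ... passed to \code{\link{runSimulation}}.
#' @return list: outcome ("TERMINATION", "MACROREENTRY", "LA_ROTORS"),
#'   record, details
#' @export
runPviExperiment <- function(mesh, cond, state, model = "surrogate",
                             mult = NULL, postMs = 1000,
                             sustainedMs = 500, ...) {
  condPvi <- applyPvi(cond, mesh)
  rec <- runSimulation(mesh, condPvi, list(), duration = postMs,
                       model = model, mult = mult, initialState = state,
                       ...)
  simMesh <- splitMeshAlongEdges(mesh, cond@decoupledEdges)$mesh
  cls <- classifyPostPvi(rec, simMesh, model = model,
                         sustainedMs = sustainedMs)
  c(list(record = rec), cls)
}

#' Classify post-PVI activity
#'
#' Applies the three-way outcome classification (see
#' \code{\link{runPviExperiment}}) to any voltage record: TERMINATION when
#' the field is quiescent, LA_ROTORS when a sustained PS lives in the LA
#' body, MACROREENTRY for persisting activity without sustained PSs (the
#' cycle-length periodicity of the activation sequence is recorded).
#'
#' @param record a \code{VoltageRecord}.
#' @param simMesh the simulated mesh (with lesion bands labelled).
#' @param model "surrogate" or "crn" (sets the resting potential).
#' @param sustainedMs sustained-PS lifetime threshold (ms).
#' @return list: outcome, details
#' @export
classifyPostPvi <- function(record, simMesh, model = "surrogate",
                            sustainedMs = 500) {
  tt <- record@times
  vEnd <- record@V[nrow(record@V), ]
  rest <- if (model == "surrogate") -80 else -81.18
  lastWin <- record@V[tt >= max(tt) - 200, , drop = FALSE]
  quiescent <- all(abs(vEnd - rest) < 5) &&
    !any(count_upcrossings(lastWin, -40) > 0)
  if (quiescent || !is.na(record@meta$earlyStop %||% NA))
    return(list(outcome = "TERMINATION",
                details = list(sustainedPs = 0)))
  pm <- computePhase(record, guard = min(100, (max(tt) - min(tt)) / 4))
  ev <- detectPs(pm, simMesh)
  tr <- trackPs(ev)
  lt <- attr(tr, "lifetimes")
  sustained <- lt$trajectory[lt$lifetime >= sustainedMs]
  regions <- definePsRegions(simMesh)
  elRegion <- .elementRegion(simMesh, regions)
  inLa <- vapply(sustained, function(id) {
    els <- tr$element[tr$trajectory == id]
    mean(elRegion[els] == 2L) > 0.5
  }, logical(1))
  out <- if (any(inLa)) "LA_ROTORS" else "MACROREENTRY"
  list(outcome = out,
       details = list(sustainedPs = length(sustained),
                      sustainedLaPs = sum(inLa),
                      periodicity = .activationPeriodicity(record)))
}

# cycle-length periodicity of activation: median inter-activation interval
# and its relative spread on the most active nodes
.activationPeriodicity <- function(record, threshold = -40) {
  cnt <- count_upcrossings(record@V, threshold)
  top <- order(cnt, decreasing = TRUE)[seq_len(min(20, ncol(record@V)))]
  ivals <- unlist(lapply(top, function(j) {
    v <- record@V[, j]
    up <- which(v[-1] >= threshold & v[-length(v)] < threshold)
    diff(record@times[up])
  }))
  if (length(ivals) < 3) return(list(cl = NA_real_, spread = NA_real_))
  list(cl = stats::median(ivals),
       spread = stats::mad(ivals) / stats::median(ivals))
}

#' Exact McNemar test for paired binary outcomes
#'
#' Two-sided exact binomial test on the discordant pairs; by convention
#' p = 1 when there are none. A continuity-corrected chi-square variant is
#' available.
#'
#' @param pairs two-column logical matrix / data.frame of paired outcomes,
#'   or NULL when \code{b} and \code{c} are given directly.
#' @param b,c discordant counts (condition 1 only / condition 2 only).
#' @param method "exact" or "chisq".
#' @return p-value
#' @export
mcnemarTest <- function(pairs = NULL, b = NULL, c = NULL,
                        method = c("exact", "chisq")) {
  method <- match.arg(method)
  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    b <- sum(pairs[, 1] & !pairs[, 2])
    c <- sum(!pairs[, 1] & pairs[, 2])
  }
  n <- b + c
  if (n == 0) return(1)
  if (method == "exact") {
    min(1, 2 * pbinom(min(b, c), n, 0.5))
  } else {
    stat <- (abs(b - c) - 1)^2 / n
    pchisq(stat, df = 1, lower.tail = FALSE)
  }
}
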