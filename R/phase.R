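#' Phase of the transmembrane voltage
#'
#' For each node, the temporal mean over the analysis window is subtracted,
#' the analytic signal is computed via the Hilbert transform (FFT
#' construction), and the phase is its angle, wrapped to (-pi, pi]. A guard
#' band at each end of the window limits transform edge effects: samples
#' inside the guard bands are computed but flagged, and downstream PS
#' detection skips them. Nodes with (numerically) constant voltage have
#' undefined phase and are returned as NA columns.
#'
#' @param record a \code{VoltageRecord}.
#' @param window numeric(2), analysis window (ms) within the record
#'   (default: whole record).
#' @param guard guard band discarded at each end (ms).
#' @return list of class \code{PhaseMap}: \code{phase} (ntime x nnode),
#'   \code{times}, \code{valid} (logical index of samples outside the guard
#'   bands), \code{undefinedNodes}
#' @export
computePhase <- function(record, window = NULL, guard = 100) {
  tt <- record@times
  if (is.null(window)) window <- range(tt)
  sel <- which(tt >= window[1] & tt <= window[2])
  if (length(sel) < 8) stop("analysis window too short")
  v <- record@V[sel, , drop = FALSE]
  nt <- nrow(v)
  vc <- sweep(v, 2, colMeans(v))
  undef <- apply(vc, 2, function(x) max(abs(x)) < 1e-9)
  # analytic signal: zero negative frequencies, double positive ones
  h <- numeric(nt)
  if (nt %% 2 == 0) {
    h[1] <- 1; h[nt / 2 + 1] <- 1; h[2:(nt / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((nt + 1) / 2)] <- 2
  }
  Fv <- mvfft(vc)
  an <- mvfft(Fv * h, inverse = TRUE) / nt
  ph <- matrix(atan2(Im(an), Re(an)), nrow = nt)
  ph[, undef] <- NA_real_
  tw <- tt[sel]
  valid <- tw >= window[1] + guard & tw <= window[2] - guard
  if (!any(valid)) valid <- rep(TRUE, length(tw))  # short records: log only
  structure(list(phase = ph, times = tw, valid = valid,
                 undefinedNodes = which(undef)),
            class = "PhaseMap")
}

.wrapPi <- function(x) ((x + pi) %% (2 * pi)) - pi

#' Detect phase singularities by topological charge
#'
#' For every triangle the wrapped phase differences around its (oriented)
#' corners are summed; the topological charge is the winding number
#' \code{round(sum / 2 pi)}, always in \{-1, 0, +1\} on a triangle. Non-zero
#' charge emits a PS event at the element centroid. Corner order follows
#' the mesh orientation, so chirality is consistent across frames and runs.
#'
#' @param phaseMap from \code{\link{computePhase}}.
#' @param mesh the mesh the record was simulated on.
#' @param frames frame indices to scan (default: all valid frames).
#' @return data.frame: t, element, charge, x, y, z
#' @export
detectPs <- function(phaseMap, mesh, frames = NULL) {
  tri <- mesh@triangles
  cent <- elementGeometry(mesh)$centroid
  if (is.null(frames)) frames <- which(phaseMap$valid)
  out <- vector("list", length(frames))
  skipLog <- 0L
  for (k in seq_along(frames)) {
    f <- frames[k]
    ph <- phaseMap$phase[f, ]
    p1 <- ph[tri[, 1]]; p2 <- ph[tri[, 2]]; p3 <- ph[tri[, 3]]
    ok <- !is.na(p1) & !is.na(p2) & !is.na(p3)
    skipLog <- skipLog + sum(!ok)
    wsum <- .wrapPi(p2 - p1) + .wrapPi(p3 - p2) + .wrapPi(p1 - p3)
    charge <- as.integer(round(wsum / (2 * pi)))
    hit <- which(ok & charge != 0L)
    if (length(hit))
      out[[k]] <- data.frame(t = phaseMap$times[f], element = hit,
                             charge = charge[hit],
                             x = cent[hit, 1], y = cent[hit, 2],
                             z = cent[hit, 3])
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(t = numeric(0), element = integer(0),
                      charge = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0))
  attr(res, "skippedElements") <- skipLog
  res
}

#' Winding number of the phase along a closed node loop
#'
#' Independent oracle for the per-element topological charge: the wrapped
#' phase differences are accumulated along an arbitrary closed loop of
#' nodes; the result equals the total charge enclosed by the loop.
#'
#' @param phase numeric vector of per-node phases (one frame).
#' @param loop integer vector of node indices forming a closed loop.
#' @return integer winding number
#' @export
loopWindingNumber <- function(phase, loop) {
  ph <- phase[c(loop, loop[1])]
  as.integer(round(sum(.wrapPi(diff(ph))) / (2 * pi)))
}

#' Track phase singularities over time
#'
#' Greedy nearest-neighbour linking between consecutive frames with a
#' maximum jump radius and a same-chirality constraint; unmatched events
#' open or close trajectories.
#'
#' @param events PS events from \code{\link{detectPs}}.
#' @param maxJump maximum linking distance between consecutive frames (mm).
#' @return data.frame of events with a \code{trajectory} id column;
#'   attribute \code{lifetimes} gives per-trajectory start, end and
#'   lifetime (ms)
#' @export
trackPs <- function(events, maxJump = 5) {
  if (!nrow(events)) {
    out <- cbind(events, trajectory = integer(0))
    attr(out, "lifetimes") <- data.frame(trajectory = integer(0),
                                         start = numeric(0),
                                         end = numeric(0),
                                         lifetime = numeric(0))
    return(out)
  }
  events <- events[order(events$t), , drop = FALSE]
  frames <- unique(events$t)
  traj <- integer(nrow(events))
  nextId <- 0L
  prevIdx <- integer(0)
  for (f in frames) {
    cur <- which(events$t == f)
    assigned <- rep(FALSE, length(cur))
    if (length(prevIdx)) {
      # candidate links sorted by distance
      cand <- expand.grid(i = seq_along(prevIdx), j = seq_along(cur))
      pi_ <- prevIdx[cand$i]; cj <- cur[cand$j]
      d <- sqrt((events$x[pi_] - events$x[cj])^2 +
                  (events$y[pi_] - events$y[cj])^2 +
                  (events$z[pi_] - events$z[cj])^2)
      okc <- events$charge[pi_] == events$charge[cj] & d <= maxJump
      cand <- cand[okc, , drop = FALSE]; d <- d[okc]
      usedPrev <- rep(FALSE, length(prevIdx))
      for (o in order(d)) {
        i <- cand$i[o]; j <- cand$j[o]
        if (usedPrev[i] || assigned[j]) next
        traj[cur[j]] <- traj[prevIdx[i]]
        usedPrev[i] <- TRUE; assigned[j] <- TRUE
      }
    }
    for (j in which(!assigned)) {
      nextId <- nextId + 1L
      traj[cur[j]] <- nextId
    }
    prevIdx <- cur
  }
  events$trajectory <- traj
  lt <- do.call(rbind, lapply(split(events$t, traj), range))
  lifetimes <- data.frame(trajectory = as.integer(rownames(lt)),
                          start = lt[, 1], end = lt[, 2],
                          lifetime = lt[, 2] - lt[, 1])
  attr(events, "lifetimes") <- lifetimes
  events
}

#' Phase-singularity spatial density map
#'
#' Per node: the number of PS events within radius \code{R} over the
#' analysis window, divided by the window length (events per ms). Optional
#' max-normalization for display.
#'
#' @param events PS events from \code{\link{detectPs}}.
#' @param mesh the mesh.
#' @param window numeric(2) analysis window (ms); defaults to the event
#'   time range.
#' @param radius counting radius (mm).
#' @param normalize if TRUE, scale the map to max 1.
#' @return a \code{\linkS4class{ScalarNodeField}}
#' @export
psDensity <- function(events, mesh, window = NULL, radius = 2.5,
                      normalize = FALSE) {
  n <- nNodes(mesh)
  if (is.null(window))
    window <- if (nrow(events)) range(events$t) else c(0, 1)
  len <- max(window[2] - window[1], 1e-9)
  ev <- events[events$t >= window[1] & events$t <= window[2], ,
               drop = FALSE]
  dens <- numeric(n)
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      d2 <- (mesh@nodes[, 1] - ev$x[i])^2 + (mesh@nodes[, 2] - ev$y[i])^2 +
        (mesh@nodes[, 3] - ev$z[i])^2
      hit <- d2 <= radius^2
      dens[hit] <- dens[hit] + 1
    }
    dens <- dens / len
  }
  if (normalize && max(dens) > 0) dens <- dens / max(dens)
  .newField(dens, "psDensity")
}

#' PV phase-singularity density ratio
#'
#' The total PV PS count divided by the total PS count over the whole
#' model: the study's predictor of PVI success. Events are counted by the
#' analysis region of their element (corner-majority; ties resolved in
#' favour of PV).
#'
#' @param events PS events from \code{\link{detectPs}}.
#' @param mesh the mesh.
#' @param regions partition from \code{\link{definePsRegions}}.
#' @return list: \code{pvCount}, \code{totalCount}, \code{ratio}
#' @export
pvPsDensityRatio <- function(events, mesh, regions) {
  elRegion <- .elementRegion(mesh, regions)
  if (nrow(events)) {
    r <- elRegion[events$element]
    if (anyNA(r)) stop("PS event in no analysis region")
    pv <- sum(r == 1L); tot <- nrow(events)
  } else {
    pv <- 0L; tot <- 0L
  }
  list(pvCount = pv, totalCount = tot,
       ratio = if (tot > 0) pv / tot else NA_real_)
}

# element region from node partition: majority vote, ties favour PV (1)
# then LA (2) then RA (3)
.elementRegion <- function(mesh, regions) {
  tri <- mesh@triangles
  r1 <- regions[tri[, 1]]; r2 <- regions[tri[, 2]]; r3 <- regions[tri[, 3]]
  out <- integer(nrow(tri))
  for (code in c(3L, 2L, 1L)) {
    cnt <- (r1 == code) + (r2 == code) + (r3 == code)
    out[cnt >= 2] <- code
  }
  none <- out == 0L
  out[none] <- pmin(r1, r2, r3)[none]
  out
}
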