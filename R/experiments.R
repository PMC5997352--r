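#' Build an experiment condition
#'
#' One row of the study grid: PV APD condition (IK1 mode and scaling k),
#' PV CV condition (conductivity mode and divisor), fiber case and fibrosis
#' specification.
#'
#' @param name condition label.
#' @param apdMode "none", "homogeneous" or "gradient".
#' @param k IK1 scaling factor.
#' @param cvMode "none", "homogeneous", "gradient_distal_slow",
#'   "gradient_junction_slow".
#' @param divisor conductivity divisor.
#' @param fiberCase PV fiber case 0-6.
#' @param fibrosisRho PV fibrosis base density (0 = none).
#' @param seed condition seed.
#' @return condition list
#' @export
condition <- function(name, apdMode = "none", k = 1, cvMode = "none",
                      divisor = 1, fiberCase = 0, fibrosisRho = 0,
                      seed = 1L) {
  list(name = name, apdMode = apdMode, k = k, cvMode = cvMode,
       divisor = divisor, fiberCase = fiberCase,
       fibrosisRho = fibrosisRho, seed = as.integer(seed))
}

# realise one condition on a mesh: returns cond, mult and helper fields
.realiseCondition <- function(cnd, mesh, baseCond, model, distance,
                              pvApdScale = 1) {
  msh <- mesh
  if (cnd$fiberCase != 0)
    msh <- assignPvFibers(msh, cnd$fiberCase, seed = cnd$seed,
                          distance = distance)
  cond <- baseCond
  cond@sigmaL <- rep(baseCond@sigmaL, length.out = nElements(msh))
  cond@sigmaT <- rep(baseCond@sigmaT, length.out = nElements(msh))
  if (cnd$cvMode != "none")
    cond <- scaleConductivity(cond, msh, cnd$cvMode, cnd$divisor,
                              distance = distance)
  ik1 <- if (cnd$apdMode != "none")
    buildIk1Field(msh, cnd$apdMode, cnd$k, distance = distance)
  else NULL
  if (cnd$fibrosisRho > 0) {
    es <- selectPvFibroticEdges(msh, distance, rho = cnd$fibrosisRho,
                                seed = cnd$seed)
    cond <- withFibrosis(cond, es)
  }
  mult <- if (model == "crn") buildNodeMultipliers(msh, ik1Field = ik1)
          else buildSurrogateMultipliers(msh, pvApdScale = pvApdScale,
                                         ik1Field = ik1)
  list(mesh = msh, cond = cond, mult = mult)
}

#' Run an experiment sweep
#'
#' One row per condition: the inducibility battery is run, and for induced
#' protocols the PV PS density ratio is computed over the post-induction
#' window. Conditions are independent and reproducible from their recorded
#' seeds; partial failures are isolated per row.
#'
#' @param conditions list of \code{\link{condition}} objects.
#' @param mesh a \code{SurfaceMesh}.
#' @param baseCond baseline \code{ConductivityField}.
#' @param battery battery data.frame (reduced batteries make cheap smoke
#'   tests).
#' @param model "surrogate" (default, desk scale) or "crn".
#' @param pvApdScale surrogate PV/LA APD ratio knob.
#' @param verbose print progress.
#' @param ... passed to \code{\link{runBattery}}.
#' @return data.frame: condition, inducibility ratio, per-vein ratios,
#'   mean PV PS density ratio, error (NA unless the row failed)
#' @export
runSweep <- function(conditions, mesh, baseCond,
                     battery = buildBattery(mesh), model = "surrogate",
                     pvApdScale = 1, verbose = FALSE, ...) {
  distance <- computeAllDistanceParameters(mesh)
  rows <- vector("list", length(conditions))
  for (ci in seq_along(conditions)) {
    cnd <- conditions[[ci]]
    row <- data.frame(condition = cnd$name, seed = cnd$seed,
                      inducibility = NA_real_, psRatio = NA_real_,
                      error = NA_character_)
    perVein <- setNames(rep(NA_real_, length(PV_NAMES)), PV_NAMES)
    res <- tryCatch({
      rc <- .realiseCondition(cnd, mesh, baseCond, model, distance,
                              pvApdScale = pvApdScale)
      simMesh <- splitMeshAlongEdges(rc$mesh,
                                     rc$cond@decoupledEdges)$mesh
      regions <- tryCatch(definePsRegions(simMesh), error = function(e)
        NULL)
      dists <- list()
      induced <- logical(nrow(battery))
      ratios <- c()
      for (i in seq_len(nrow(battery))) {
        v <- battery$vein[i]
        if (is.null(dists[[v]]))
          dists[[v]] <- computeDistanceParameter(rc$mesh, v)
        pr <- runProtocol(rc$mesh, rc$cond, v, battery$ci[i],
                          model = model, mult = rc$mult,
                          distance = dists[[v]], ...)
        induced[i] <- pr$outcome$induced
        if (induced[i] && !is.null(regions)) {
          rec <- pr$record
          win <- c(pr$outcome$inductionTime, max(rec@times))
          if (diff(win) > 150) {
            pm <- computePhase(rec, window = win, guard = 50)
            ev <- detectPs(pm, simMesh)
            rr <- pvPsDensityRatio(ev, simMesh, regions)
            if (!is.na(rr$ratio)) ratios <- c(ratios, rr$ratio)
          }
        }
        if (verbose)
          message(sprintf("  %s protocol %d/%d (%s, CI %d): %s",
                          cnd$name, i, nrow(battery), v, battery$ci[i],
                          if (induced[i]) "induced" else "-"))
      }
      row$inducibility <- inducibilityRatio(induced)
      for (v in intersect(unique(battery$vein), PV_NAMES))
        perVein[v] <- inducibilityRatio(induced[battery$vein == v])
      row$psRatio <- if (length(ratios)) mean(ratios) else NA_real_
      TRUE
    }, error = function(e) {
      row$error <<- conditionMessage(e)
      FALSE
    })
    rows[[ci]] <- cbind(row, as.data.frame(as.list(perVein)))
    if (verbose)
      message(sprintf("condition '%s': inducibility %s", cnd$name,
                      format(rows[[ci]]$inducibility)))
  }
  do.call(rbind, rows)
}

#' Summarize PVI outcomes
#'
#' Class proportions over eligible cases and the distribution of the
#' pre-PVI PV PS density ratio per class, with a two-sample t-test (plus
#' rank-sum alternative) between classes.
#'
#' @param rows data.frame with columns \code{outcome} (TERMINATION /
#'   MACROREENTRY / LA_ROTORS) and \code{preRatio}.
#' @return list: n, proportions, byClass (mean/sd of preRatio), tests
#' @export
summarizePvi <- function(rows) {
  classes <- c("TERMINATION", "MACROREENTRY", "LA_ROTORS")
  if (!nrow(rows))
    return(list(n = 0, proportions = setNames(rep(NA_real_, 3), classes),
                byClass = NULL, tests = NULL,
                message = "no eligible cases"))
  rows$outcome <- factor(rows$outcome, levels = classes)
  prop <- as.numeric(table(rows$outcome)) / nrow(rows)
  names(prop) <- classes
  byClass <- lapply(split(rows$preRatio, rows$outcome), function(x)
    c(n = length(x), mean = mean(x), sd = sd(x)))
  tests <- list()
  for (pair in list(c("TERMINATION", "LA_ROTORS"),
                    c("MACROREENTRY", "LA_ROTORS"))) {
    a <- rows$preRatio[rows$outcome == pair[1]]
    b <- rows$preRatio[rows$outcome == pair[2]]
    key <- paste(pair, collapse = "_vs_")
    if (length(a) >= 2 && length(b) >= 2) {
      tests[[key]] <- list(
        t = t.test(a, b)$p.value,
        ranksum = suppressWarnings(wilcox.test(a, b)$p.value))
    } else {
      tests[[key]] <- list(t = NA_real_, ranksum = NA_real_,
                           note = "class with n < 2 skipped")
    }
  }
  list(n = nrow(rows), proportions = prop, byClass = byClass,
       tests = tests)
}
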