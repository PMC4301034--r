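#' @include AllClasses.R configs.R fem.R materials.R
NULL

## Swap the elastic constants of the given mesh elements.
.setElements <- function(mesh, idx, E, nu) {
  mesh@E[idx] <- E
  mesh@nu[idx] <- nu
  mesh
}

#' Worst-case scenario: no fusion anywhere in the nonunion
#'
#' Sets every nonunion cell to soft tissue, solves the axial load case, and
#' returns the global maximum von Mises stress, which serves as the scaling
#' reference (it maps to 100 on the scaled axis).  In this scenario the
#' implant carries essentially the whole load while the nonunion cells are
#' nearly stress-free.
#'
#' @param labels a \linkS4class{LabelVolume} with a nonempty nonunion mask.
#' @param model a \linkS4class{CalibrationModel}.
#' @param bodyMass body mass in kg for the axial load (default 80).
#' @param tol,solver passed to \code{\link{solveDisplacements}}.
#' @return a list with \code{referenceMax} (Pa), the scaled
#'   \linkS4class{StressField} \code{field}, the \linkS4class{VoxelMesh}
#'   \code{mesh} and the \linkS4class{LoadCase} \code{load}.
#' @export
worstCaseReference <- function(labels, model = calibrationModel(),
                               bodyMass = 80, tol = 1e-8,
                               solver = c("auto", "direct", "cg")) {
  if (!any(labels@nonunion))
    stop("nonunion mask is empty; mark the nonunion region first")
  mats <- assignMaterials(labels, model, scenario = "worst_case")
  mesh <- buildMesh(mats)
  load <- applyLoadCase(mesh, bodyMass = bodyMass)
  sol <- solveDisplacements(mesh, load, tol = tol, solver = match.arg(solver))
  field <- elementStress(mesh, sol$u)
  field <- scaleStresses(field, max(vonMises(field)))
  list(referenceMax = field@referenceMax, field = field, mesh = mesh,
       load = load)
}

#' Minimal mechanically relevant fusion area
#'
#' Starting from full fusion (all nonunion cells set to cortical bone), each
#' sweep solves the finite-element system and simultaneously demotes to soft
#' tissue every still-active nonunion cell whose von Mises stress is below
#' \code{threshold} times the worst-case reference maximum.  Demoted cells
#' are never restored.  The loop stops when a sweep would push the scaled
#' global maximum above \code{stopCap} (that sweep is rolled back), when no
#' cell qualifies, or at \code{maxSteps}.  The cells still fused at
#' termination are the minimal mechanically relevant fusion set.
#'
#' @param labels a \linkS4class{LabelVolume} with a nonempty nonunion mask.
#' @param model a \linkS4class{CalibrationModel}.
#' @param config an \linkS4class{OptimizationConfig}.
#' @param bodyMass body mass in kg (default 80).
#' @param tol,solver passed to \code{\link{solveDisplacements}}.
#' @return an \linkS4class{OptimizationResult}.
#' @export
minimalFusion <- function(labels, model = calibrationModel(),
                          config = optimizationConfig(), bodyMass = 80,
                          tol = 1e-8, solver = c("auto", "direct", "cg")) {
  validObject(config)
  solver <- match.arg(solver)
  wc <- worstCaseReference(labels, model, bodyMass = bodyMass, tol = tol,
                           solver = solver)
  refMax <- wc$referenceMax
  load <- wc$load

  ## full-fusion start: same foreground, so same mesh topology as worst case
  mesh <- .setElements(wc$mesh, which(wc$mesh@nonunion),
                       model@ECortical, model@nuBone)
  nnE <- which(mesh@nonunion)
  n0 <- length(nnE)
  active <- rep(TRUE, n0)

  solveVM <- function(msh) {
    sol <- solveDisplacements(msh, load, tol = tol, solver = solver)
    vonMises(elementStress(msh, sol$u))
  }
  status <- "max_steps"
  rows <- list()
  vm <- tryCatch(solveVM(mesh), error = function(e) e)
  if (inherits(vm, "error")) {
    status <- "solver_failure"
    rows[[1]] <- data.frame(step = 0L, removed = 0L, reduction = NA_real_,
                            cumReduction = 0, scaledMax = NA_real_)
  } else {
    rows[[1]] <- data.frame(step = 0L, removed = 0L, reduction = NA_real_,
                            cumReduction = 0,
                            scaledMax = 100 * max(vm) / refMax)
    for (s in seq_len(config@maxSteps)) {
      refLocal <- if (config@perStepMax) max(vm) else refMax
      demote <- active & vm[nnE] < config@threshold * refLocal
      if (!any(demote)) { status <- "no_demotion"; break }
      trial <- .setElements(mesh, nnE[demote], model@ESoft, model@nuSoft)
      vmNew <- tryCatch(solveVM(trial), error = function(e) e)
      if (inherits(vmNew, "error")) { status <- "solver_failure"; break }
      scaledNew <- 100 * max(vmNew) / refMax
      if (scaledNew > config@stopCap) { status <- "stop_cap"; break }
      mesh <- trial
      vm <- vmNew
      active[demote] <- FALSE
      rows[[s + 1L]] <- data.frame(
        step = s, removed = sum(demote),
        reduction = 100 * sum(demote) / n0,
        cumReduction = 100 * (n0 - sum(active)) / n0,
        scaledMax = scaledNew)
    }
  }
  steps <- do.call(rbind, rows)
  surv <- array(FALSE, dim = mesh@dims)
  survVox <- mesh@voxel[nnE[active], , drop = FALSE]
  surv[survVox] <- TRUE
  total <- 100 * (n0 - sum(active)) / n0
  new("OptimizationResult", steps = steps, survivingMask = surv,
      totalReduction = total, remainingFraction = 100 - total,
      referenceMax = refMax, initialCells = as.integer(n0), status = status)
}

#' Summarize an optimization trajectory
#'
#' Emits the per-step table (step index, reduction percent, scaled maximum
#' stress), the total reduction as the sum of the per-step reductions, and
#' the remaining fraction \code{100 - total}.  Accepts either an
#' \linkS4class{OptimizationResult} or a bare numeric vector of per-step
#' reduction percentages.
#'
#' @param x an \linkS4class{OptimizationResult}, or numeric per-step
#'   reductions in percent of the initial nonunion cells.
#' @param path optional file stem; writes \code{<path>.csv} (the per-step
#'   table) and \code{<path>.json} (table plus totals).
#' @return a list with \code{steps} (data.frame), \code{totalReduction} and
#'   \code{remainingFraction} (percent).
#' @examples
#' s <- summarizeOptimization(c(50.7, 3.4, 21.9, 12.2, 5.5, 2.7))
#' s$totalReduction    # 96.4
#' s$remainingFraction # 3.6
#' @export
summarizeOptimization <- function(x, path = NULL) {
  if (is(x, "OptimizationResult")) {
    steps <- x@steps
  } else {
    red <- as.numeric(x)
    steps <- data.frame(step = seq_along(red), removed = NA_integer_,
                        reduction = red, cumReduction = cumsum(red),
                        scaledMax = NA_real_)
  }
  red <- steps$reduction[!is.na(steps$reduction)]
  total <- sum(red)
  out <- list(steps = steps, totalReduction = total,
              remainingFraction = 100 - total)
  if (!is.null(path)) {
    write.csv(steps, paste0(path, ".csv"), row.names = FALSE)
    jsonlite::write_json(list(steps = steps, totalReduction = total,
                              remainingFraction = 100 - total),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  out
}
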