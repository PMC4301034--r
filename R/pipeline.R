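#' @include AllClasses.R configs.R phantom.R imaging.R materials.R fem.R optimize.R
NULL

#' Default pipeline configuration
#'
#' A nested list holding the configuration of every pipeline stage at its
#' defaults; edit fields or supersede them with a YAML/JSON file.  The
#' nonunion slab defaults to the phantom's fracture gap.
#'
#' @return a nested configuration list.
#' @export
defaultPipelineConfig <- function() {
  pc <- phantomConfig()
  zlen <- pc@gridDims[3] * pc@spacing[3]
  gc <- if (is.na(pc@gapCenter)) zlen / 2 else pc@gapCenter
  list(
    seed = 1L,
    phantom = list(gridDims = as.integer(pc@gridDims),
                   spacing = pc@spacing, outerRadius = pc@outerRadius,
                   corticalThickness = pc@corticalThickness,
                   gapHalfwidth = pc@gapHalfwidth,
                   plateThickness = pc@plateThickness,
                   plateWidth = pc@plateWidth, plateZ = pc@plateZ,
                   screwRadius = pc@screwRadius, screwZ = pc@screwZ,
                   noiseSD = pc@noiseSD),
    diffusion = list(iterations = 5L, kappa = 150, dt = 1 / 6),
    segmentation = list(thresholds = c(150, 800, 1950, 3300)),
    nonunion = list(zRange = c(gc - pc@gapHalfwidth, gc + pc@gapHalfwidth)),
    coarsening = list(level = 2L),
    crop = list(proximalFraction = 0.15, distalFraction = 0.15),
    load = list(bodyMass = 80),
    solver = list(tol = 1e-8, solver = "auto"),
    optimize = list(threshold = 0.2, stopCap = 84, maxSteps = 10L,
                    perStepMax = TRUE)
  )
}

.readConfigFile <- function(path) {
  if (!file.exists(path)) .formatError(sprintf("no such config file: '%s'", path))
  txt <- tryCatch(
    if (grepl("\\.ya?ml$", tolower(path))) yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) .formatError(sprintf(
      "config file '%s' could not be parsed: %s", path, conditionMessage(e))))
  txt
}

## Overlay user values on the defaults, recursively.
.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Validate a pipeline configuration
#'
#' Checks every stage's invariants and returns all violations at once as a
#' character vector of diagnostics (empty when the configuration is valid).
#' An unreadable file raises a format error, distinct from invalid content.
#'
#' @param config a configuration list, or a path to a YAML/JSON file whose
#'   fields overlay \code{\link{defaultPipelineConfig}}.
#' @return character vector of diagnostics, each naming the offending field.
#' @export
validateConfig <- function(config = defaultPipelineConfig()) {
  if (is.character(config))
    config <- .mergeConfig(defaultPipelineConfig(), .readConfigFile(config))
  d <- character()
  chk <- function(ok, msg) if (!isTRUE(all(ok))) d <<- c(d, msg)
  ph <- config$phantom
  chk(all(ph$spacing > 0), "phantom$spacing: must be positive")
  chk(all(ph$gridDims >= 2), "phantom$gridDims: must be >= 2 voxels per axis")
  chk(ph$corticalThickness < ph$outerRadius,
      "phantom$corticalThickness: must be < outerRadius")
  chk(ph$noiseSD >= 0, "phantom$noiseSD: must be >= 0")
  df <- config$diffusion
  chk(df$iterations >= 0, "diffusion$iterations: must be >= 0")
  chk(df$kappa > 0, "diffusion$kappa: must be > 0")
  chk(df$dt > 0 && df$dt <= 1 / 6, "diffusion$dt: must lie in (0, 1/6]")
  th <- config$segmentation$thresholds
  chk(length(th) == 4 && !is.unsorted(th, strictly = TRUE),
      "segmentation$thresholds: must be 4 strictly increasing cut points")
  chk(diff(config$nonunion$zRange) > 0,
      "nonunion$zRange: must be an increasing mm interval")
  chk(config$coarsening$level >= 1, "coarsening$level: must be >= 1")
  cr <- config$crop
  chk(cr$proximalFraction >= 0 && cr$distalFraction >= 0 &&
      cr$proximalFraction + cr$distalFraction < 1,
      "crop$proximalFraction/distalFraction: must be >= 0 and sum to < 1")
  chk(config$load$bodyMass > 0, "load$bodyMass: must be > 0")
  chk(config$solver$tol > 0, "solver$tol: must be > 0")
  op <- config$optimize
  chk(op$threshold > 0 && op$threshold < 1,
      "optimize$threshold: must lie in (0, 1)")
  chk(op$stopCap > 0 && op$stopCap <= 100,
      "optimize$stopCap: must lie in (0, 100]")
  chk(op$maxSteps >= 1, "optimize$maxSteps: must be >= 1")
  d
}

#' Run the full pipeline
#'
#' Executes phantom generation, diffusion + segmentation + nonunion marking,
#' coarsening, epiphysis cropping, the worst-case solve, and the fusion-area
#' optimization, writing every intermediate artifact plus a manifest to
#' \code{outputDir}.  Fixing \code{config$seed} makes the whole run
#' deterministic.
#'
#' @param config a configuration list (see
#'   \code{\link{defaultPipelineConfig}}) or a YAML/JSON path.
#' @param outputDir directory for artifacts (created if missing).
#' @param verbose print per-stage progress and timings.
#' @return the run manifest (a list), invisibly written to
#'   \code{manifest.json}.
#' @export
runPipeline <- function(config = defaultPipelineConfig(),
                        outputDir = tempfile("nonunionFE-run-"),
                        verbose = TRUE) {
  if (is.character(config))
    config <- .mergeConfig(defaultPipelineConfig(), .readConfigFile(config))
  diag <- validateConfig(config)
  if (length(diag))
    stop("invalid pipeline config:\n  ", paste(diag, collapse = "\n  "))
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  cfgPath <- file.path(outputDir, "config.json")
  jsonlite::write_json(config, cfgPath, auto_unbox = TRUE, digits = NA)

  stages <- list()
  files <- character()
  state <- new.env(parent = emptyenv())
  runStage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({ fn(); TRUE }, error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    if (!isTRUE(ok)) {
      .writeManifest(outputDir, cfgPath, config, stages, files,
                     status = sprintf("failed at stage '%s'", name))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(ok)))
    }
    stages[[length(stages) + 1L]] <<- list(name = name, seconds = round(dt, 3))
    if (verbose) message(sprintf("[%s] done in %.1f s", name, dt))
  }
  addFile <- function(...) files <<- c(files, basename(c(...)))

  runStage("phantom", function() {
    ph <- do.call(phantomConfig, c(config$phantom, list(seed = config$seed)))
    state$stack <- generatePhantom(ph)
    addFile(writeStack(state$stack, file.path(outputDir, "stack.mhd")),
            file.path(outputDir, "stack.raw"))
  })
  runStage("segment", function() {
    sm <- anisotropicDiffusion(state$stack,
                               do.call(diffusionParams, config$diffusion))
    lv <- segmentStack(sm, config$segmentation$thresholds)
    state$labels <- markNonunion(lv, config$nonunion$zRange)
    addFile(writeLabels(state$labels, file.path(outputDir, "labels.nii.gz")),
            file.path(outputDir, "labels.nii.gz.json"))
  })
  runStage("coarsen", function() {
    spec <- coarseningSpec(config$coarsening$level,
                           config$segmentation$thresholds)
    state$coarse <- coarsen(state$labels, spec)
    addFile(writeLabels(state$coarse,
                        file.path(outputDir, "labels-coarse.nii.gz")),
            file.path(outputDir, "labels-coarse.nii.gz.json"))
  })
  runStage("crop", function() {
    state$cropped <- cropEpiphyses(state$coarse,
                                   config$crop$proximalFraction,
                                   config$crop$distalFraction)
  })
  runStage("solve", function() {
    wc <- worstCaseReference(state$cropped, calibrationModel(),
                             bodyMass = config$load$bodyMass,
                             tol = config$solver$tol,
                             solver = config$solver$solver)
    state$worstCase <- wc
    addFile(writeVTK(wc$mesh, file.path(outputDir, "worst-case.vtk"),
                     cellData = list(von_mises = vonMises(wc$field),
                                     scaled = scaledStress(wc$field))))
    jsonlite::write_json(list(referenceMax_Pa = wc$referenceMax,
                              dof = linearHexDOF(nodeCount(wc$mesh)),
                              elements = elementCount(wc$mesh)),
                         file.path(outputDir, "worst-case.json"),
                         auto_unbox = TRUE, digits = NA)
    addFile(file.path(outputDir, "worst-case.json"))
  })
  runStage("optimize", function() {
    oc <- do.call(optimizationConfig, config$optimize)
    res <- minimalFusion(state$cropped, calibrationModel(), oc,
                         bodyMass = config$load$bodyMass,
                         tol = config$solver$tol,
                         solver = config$solver$solver)
    state$result <- res
    summarizeOptimization(res, file.path(outputDir, "trajectory"))
    addFile(file.path(outputDir, "trajectory.csv"),
            file.path(outputDir, "trajectory.json"))
    msh <- state$worstCase$mesh
    addFile(writeVTK(msh, file.path(outputDir, "fusion-mask.vtk"),
                     cellData = list(
                       surviving = as.numeric(res@survivingMask[
                         cbind(msh@voxel[, 1], msh@voxel[, 2],
                               msh@voxel[, 3])]))))
  })

  manifest <- .writeManifest(outputDir, cfgPath, config, stages, files,
                             status = "complete")
  invisible(manifest)
}

.writeManifest <- function(outputDir, cfgPath, config, stages, files, status) {
  manifest <- list(
    package = "nonunionFE",
    version = as.character(utils::packageVersion("nonunionFE")),
    r_version = R.version.string,
    status = status,
    seed = config$seed,
    config_file = basename(cfgPath),
    config_md5 = unname(tools::md5sum(cfgPath)),
    stages = stages,
    files = unique(c(basename(cfgPath), files, "manifest.json")))
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
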