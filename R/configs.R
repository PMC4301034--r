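#' Phantom configuration
#'
#' Geometry and imaging parameters for the synthetic CT-like stack of a plated
#' fractured long bone.  All lengths are mm; gray levels are 12-bit.  The
#' defaults describe a desk-scale diaphysis: a hollow cortical cylinder with
#' cancellous core, a transverse fracture gap filled with soft-tissue gray,
#' and a lateral plate with four locking screws bridging the gap.
#'
#' @slot gridDims integer(3), voxels per axis (long axis third).
#' @slot spacing numeric(3), voxel spacing in mm.
#' @slot outerRadius,corticalThickness shaft outer radius and cortical wall
#'   thickness, mm.
#' @slot gapHalfwidth half of the fracture-gap width along z, mm.
#' @slot gapCenter z position of the gap center, mm (NA = mid-height).
#' @slot plateOffset gap between bone surface and plate inner face, mm.
#' @slot plateThickness,plateWidth plate cross-section, mm.
#' @slot plateZ numeric(2), z extent of the plate, mm.
#' @slot screwRadius screw radius, mm.
#' @slot screwZ numeric vector, z positions of the screw axes, mm.
#' @slot grayLevels named numeric(5): grayscale per tissue class.
#' @slot noiseSD Gaussian noise standard deviation, grayscale units.
#' @slot seed integer RNG seed for the noise.
#' @export
setClass("PhantomConfig",
  representation(gridDims = "integer", spacing = "numeric",
                 outerRadius = "numeric", corticalThickness = "numeric",
                 gapHalfwidth = "numeric", gapCenter = "numeric",
                 plateOffset = "numeric", plateThickness = "numeric",
                 plateWidth = "numeric", plateZ = "numeric",
                 screwRadius = "numeric", screwZ = "numeric",
                 grayLevels = "numeric", noiseSD = "numeric",
                 seed = "integer"))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  g <- object@grayLevels
  if (length(object@gridDims) != 3L || any(object@gridDims < 2L))
    msg <- c(msg, "gridDims must be three integers >= 2")
  if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be positive")
  for (f in c("outerRadius", "corticalThickness", "gapHalfwidth",
              "plateThickness", "plateWidth", "screwRadius"))
    if (slot(object, f) <= 0) msg <- c(msg, paste(f, "must be > 0"))
  if (object@plateOffset < 0) msg <- c(msg, "plateOffset must be >= 0")
  if (object@corticalThickness >= object@outerRadius)
    msg <- c(msg, "corticalThickness must be < outerRadius")
  if (!all(TISSUE_CLASSES %in% names(g)))
    msg <- c(msg, "grayLevels must name all five tissue classes")
  if (any(g < 0 | g > GRAY_MAX))
    msg <- c(msg, sprintf("gray levels must lie in [0, %d]", GRAY_MAX))
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  zlen <- object@gridDims[3] * object@spacing[3]
  gc <- if (is.na(object@gapCenter)) zlen / 2 else object@gapCenter
  if (gc - object@gapHalfwidth <= 0 || gc + object@gapHalfwidth >= zlen)
    msg <- c(msg, "gap must lie inside the shaft extent")
  if (length(msg)) msg else TRUE
})

#' Create a phantom configuration
#'
#' @param gridDims integer(3) voxel counts; default \code{c(48, 48, 120)}.
#' @param spacing numeric(3) mm; default \code{c(0.5, 0.5, 1.0)}.
#' @param outerRadius,corticalThickness,gapHalfwidth,gapCenter,plateOffset,plateThickness,plateWidth,plateZ,screwRadius,screwZ
#'   geometry in mm, see \linkS4class{PhantomConfig}.
#' @param grayLevels named numeric(5); defaults separate the classes cleanly:
#'   background 0, soft 300, cancellous 1300, cortical 2600, implant 4000.
#' @param noiseSD Gaussian noise sd in grayscale units (default 50).
#' @param seed integer seed (default 1).
#' @return a validated \linkS4class{PhantomConfig}.
#' @export
phantomConfig <- function(gridDims = c(48L, 48L, 120L),
                          spacing = c(0.5, 0.5, 1.0),
                          outerRadius = 6, corticalThickness = 2.5,
                          gapHalfwidth = 2.5, gapCenter = NA_real_,
                          plateOffset = 0, plateThickness = 3, plateWidth = 8,
                          plateZ = c(20, 100), screwRadius = 1.5,
                          screwZ = c(40, 50, 70, 80),
                          grayLevels = c(background = 0, soft = 300,
                                         cancellous = 1300, cortical = 2600,
                                         implant = 4000),
                          noiseSD = 50, seed = 1L) {
  new("PhantomConfig", gridDims = as.integer(gridDims),
      spacing = as.numeric(spacing), outerRadius = outerRadius,
      corticalThickness = corticalThickness, gapHalfwidth = gapHalfwidth,
      gapCenter = as.numeric(gapCenter), plateOffset = plateOffset,
      plateThickness = plateThickness, plateWidth = plateWidth,
      plateZ = as.numeric(plateZ), screwRadius = screwRadius,
      screwZ = as.numeric(screwZ), grayLevels = grayLevels,
      noiseSD = noiseSD, seed = as.integer(seed))
}

#' Anisotropic-diffusion parameters
#'
#' Explicit Perona-Malik smoothing with exponential conductance
#' \eqn{g(s) = \exp(-(s/\kappa)^2)}.  The explicit 3D scheme is stable for
#' \code{dt <= 1/6}.
#'
#' @slot iterations non-negative integer step count.
#' @slot kappa gradient scale in grayscale units (> 0).
#' @slot dt dimensionless step size in (0, 1/6].
#' @export
setClass("DiffusionParams",
  representation(iterations = "integer", kappa = "numeric", dt = "numeric"))

setValidity("DiffusionParams", function(object) {
  msg <- character()
  if (object@iterations < 0L) msg <- c(msg, "iterations must be >= 0")
  if (object@kappa <= 0) msg <- c(msg, "kappa must be > 0")
  if (object@dt <= 0 || object@dt > 1 / 6)
    msg <- c(msg, "dt must lie in (0, 1/6] for 3D explicit stability")
  if (length(msg)) msg else TRUE
})

#' @rdname DiffusionParams-class
#' @param iterations,kappa,dt see slots.
#' @return a validated \linkS4class{DiffusionParams}.
#' @export
diffusionParams <- function(iterations = 5L, kappa = 150, dt = 1 / 6) {
  new("DiffusionParams", iterations = as.integer(iterations),
      kappa = kappa, dt = dt)
}

#' Coarsening specification
#'
#' A level-k coarsening moves a k x k pixel window over each image plane,
#' replaces the window by the arithmetic mean of its pixels, and re-classifies
#' the averaged grayscale with the class thresholds.  An N-pixel width becomes
#' \code{floor(N / level)}; remainder pixels are dropped from the high-index
#' edge.
#'
#' @slot level integer >= 1, window side length.
#' @slot classThresholds numeric(4), strictly increasing grayscale cut points
#'   applied after averaging.
#' @slot zBin logical; also bin \code{level} slices along z (default FALSE:
#'   coarsening acts in-plane only).
#' @export
setClass("CoarseningSpec",
  representation(level = "integer", classThresholds = "numeric",
                 zBin = "logical"))

setValidity("CoarseningSpec", function(object) {
  msg <- character()
  if (object@level < 1L) msg <- c(msg, "level must be >= 1")
  if (length(object@classThresholds) != 4L ||
      is.unsorted(object@classThresholds, strictly = TRUE))
    msg <- c(msg, "classThresholds must be 4 strictly increasing values")
  if (length(msg)) msg else TRUE
})

#' @rdname CoarseningSpec-class
#' @param level,classThresholds,zBin see slots.
#' @return a validated \linkS4class{CoarseningSpec}.
#' @export
coarseningSpec <- function(level, classThresholds = c(150, 800, 1950, 3300),
                           zBin = FALSE) {
  new("CoarseningSpec", level = as.integer(level),
      classThresholds = as.numeric(classThresholds), zBin = zBin)
}

#' Calibration model: grayscale to elastic constants
#'
#' Chains three maps: 12-bit grayscale to Hounsfield units (affine), HU to
#' apparent density in g/cm^3 (affine), and density to Young's modulus by a
#' power law \eqn{E = a \rho^b} (a in MPa).  Class constants override the
#' chain for soft tissue and the titanium implant, and bone moduli are clamped
#' to \code{[EMin, ECortical]}.
#'
#' @slot huSlope,huIntercept grayscale -> HU affine map.
#' @slot rhoSlope,rhoIntercept HU -> apparent density (g/cm^3) affine map.
#' @slot powerA power-law coefficient, MPa per (g/cm^3)^powerB.
#' @slot powerB dimensionless power-law exponent.
#' @slot ECortical,ESoft,EImplant,EMin class moduli and floor, Pa.
#' @slot nuBone,nuSoft,nuImplant Poisson ratios.
#' @export
setClass("CalibrationModel",
  representation(huSlope = "numeric", huIntercept = "numeric",
                 rhoSlope = "numeric", rhoIntercept = "numeric",
                 powerA = "numeric", powerB = "numeric",
                 ECortical = "numeric", ESoft = "numeric",
                 EImplant = "numeric", EMin = "numeric",
                 nuBone = "numeric", nuSoft = "numeric",
                 nuImplant = "numeric"))

setValidity("CalibrationModel", function(object) {
  msg <- character()
  if (object@powerA <= 0) msg <- c(msg, "powerA must be > 0")
  if (object@powerB <= 0) msg <- c(msg, "powerB must be > 0")
  for (f in c("nuBone", "nuSoft", "nuImplant"))
    if (slot(object, f) <= 0 || slot(object, f) >= 0.5)
      msg <- c(msg, paste(f, "must lie in (0, 0.5)"))
  for (f in c("ECortical", "ESoft", "EImplant", "EMin"))
    if (slot(object, f) <= 0) msg <- c(msg, paste(f, "must be > 0 (Pa)"))
  if (length(msg)) msg else TRUE
})

#' Create a calibration model
#'
#' Defaults use the conventional CT offset (grayscale 1024 -> 0 HU), a
#' two-point density calibration placing the phantom's cancellous and cortical
#' gray levels at 0.5 and 1.8 g/cm^3, the power law E = 6850 MPa x rho^1.49,
#' cortical E 16.7 GPa (nu 0.3), titanium 105 GPa (nu 0.34), soft tissue
#' 1 MPa (nu 0.45), and a 0.1 MPa modulus floor.
#'
#' @param huSlope,huIntercept,rhoSlope,rhoIntercept,powerA,powerB,ECortical,ESoft,EImplant,EMin,nuBone,nuSoft,nuImplant
#'   see \linkS4class{CalibrationModel}.
#' @return a validated \linkS4class{CalibrationModel}.
#' @export
calibrationModel <- function(huSlope = 1, huIntercept = -1024,
                             rhoSlope = 0.001, rhoIntercept = 0.224,
                             powerA = 6850, powerB = 1.49,
                             ECortical = 16.7e9, ESoft = 1e6,
                             EImplant = 105e9, EMin = 0.1e6,
                             nuBone = 0.3, nuSoft = 0.45, nuImplant = 0.34) {
  new("CalibrationModel", huSlope = huSlope, huIntercept = huIntercept,
      rhoSlope = rhoSlope, rhoIntercept = rhoIntercept,
      powerA = powerA, powerB = powerB, ECortical = ECortical,
      ESoft = ESoft, EImplant = EImplant, EMin = EMin,
      nuBone = nuBone, nuSoft = nuSoft, nuImplant = nuImplant)
}

#' Optimization configuration
#'
#' @slot threshold fraction of the worst-case maximum stress below which an
#'   active nonunion cell is demoted to soft tissue (default 0.2).
#' @slot stopCap scaled-stress ceiling on the 0-100 scale terminating the loop
#'   (default 84); a sweep whose post-demotion solve exceeds the cap is rolled
#'   back.
#' @slot maxSteps iteration cap (>= 1).
#' @slot perStepMax logical; if TRUE (default) the per-cell demotion test uses
#'   the current step's maximum stress; if FALSE it uses the fixed worst-case
#'   reference.  The stop cap is always checked on the worst-case scale.
#' @export
setClass("OptimizationConfig",
  representation(threshold = "numeric", stopCap = "numeric",
                 maxSteps = "integer", perStepMax = "logical"))

setValidity("OptimizationConfig", function(object) {
  msg <- character()
  if (object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "threshold must lie in (0, 1)")
  if (object@stopCap <= 0 || object@stopCap > 100)
    msg <- c(msg, "stopCap must lie in (0, 100]")
  if (object@maxSteps < 1L) msg <- c(msg, "maxSteps must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname OptimizationConfig-class
#' @param threshold,stopCap,maxSteps,perStepMax see slots.
#' @return a validated \linkS4class{OptimizationConfig}.
#' @export
optimizationConfig <- function(threshold = 0.2, stopCap = 84,
                               maxSteps = 10L, perStepMax = TRUE) {
  new("OptimizationConfig", threshold = threshold, stopCap = stopCap,
      maxSteps = as.integer(maxSteps), perStepMax = perStepMax)
}
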