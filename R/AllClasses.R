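#' @import methods
#' @importFrom stats rnorm runif setNames
#' @importFrom utils write.csv
#' @importFrom jsonlite write_json read_json
NULL

## Tissue-class coding shared across the package.  Integer codes index into
## TISSUE_CLASSES; 12-bit grayscale throughout.
TISSUE_CLASSES <- c("background", "soft", "cancellous", "cortical", "implant")
GRAY_MAX <- 4095

#' ImageStack: a 3D grayscale volume with physical spacing
#'
#' The raw pipeline input and every coarsened derivative.  Values are on the
#' 12-bit CT-like scale \eqn{[0, 4095]}; the third array axis is the bone's
#' long axis by convention, and voxel centers sit at
#' \code{origin + (i + 0.5) * spacing} (0-based voxel index \code{i}).
#'
#' @slot values 3D numeric array of grayscale values in \eqn{[0, 4095]}.
#' @slot spacing numeric(3), voxel spacing in mm (all > 0).
#' @slot origin numeric(3), position of the volume corner in mm.
#' @export
setClass("ImageStack",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("ImageStack", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive finite numbers (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be three finite numbers (mm)")
  rng <- suppressWarnings(range(object@values))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > GRAY_MAX))
    msg <- c(msg, sprintf("values must lie in [0, %d]", GRAY_MAX))
  if (length(msg)) msg else TRUE
})

#' LabelVolume: per-voxel tissue class plus a nonunion mask
#'
#' Output of segmentation, input to material assignment.  Carries the source
#' grayscale so that block coarsening can re-average intensities and re-apply
#' the classification thresholds, and so the density power law can act on the
#' (diffused) grayscale of bone voxels.
#'
#' @slot labels 3D integer array with codes 0..4 for background, soft,
#'   cancellous, cortical, implant.
#' @slot nonunion 3D logical array, same shape; TRUE only on soft, cancellous
#'   or cortical voxels (never implant or background).
#' @slot grayscale 3D numeric array: the (diffused) grayscale the labels were
#'   cut from.
#' @slot thresholds numeric(4), the strictly increasing grayscale cut points.
#' @slot spacing,origin physical geometry, as in \linkS4class{ImageStack}.
#' @export
setClass("LabelVolume",
  representation(labels = "array", nonunion = "array", grayscale = "array",
                 thresholds = "numeric", spacing = "numeric",
                 origin = "numeric"))

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@labels), dim(object@nonunion)) ||
      !identical(dim(object@labels), dim(object@grayscale)))
    msg <- c(msg, "labels, nonunion and grayscale must share one shape")
  if (any(!(object@labels %in% 0:4)))
    msg <- c(msg, "labels must be integer codes 0..4")
  if (!is.logical(object@nonunion))
    msg <- c(msg, "nonunion must be logical")
  bad <- object@nonunion & (object@labels == 0L | object@labels == 4L)
  if (any(bad))
    msg <- c(msg, "nonunion mask may not cover background or implant voxels")
  if (length(object@thresholds) != 4L || is.unsorted(object@thresholds, strictly = TRUE))
    msg <- c(msg, "thresholds must be 4 strictly increasing cut points")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive numbers (mm)")
  if (length(msg)) msg else TRUE
})

#' MaterialMap: per-voxel elastic constants
#'
#' Young's modulus in Pa and Poisson ratio per voxel, derived from the
#' calibration/power-law chain with class overrides, ready for meshing.
#'
#' @slot E 3D numeric array, Young's modulus in Pa (0 marks background).
#' @slot nu 3D numeric array, Poisson ratio in (0, 0.5).
#' @slot labels the \linkS4class{LabelVolume} the map was derived from.
#' @slot scenario character, one of \code{"worst_case"}, \code{"full_fusion"},
#'   \code{"mask"} or \code{"as_segmented"}.
#' @export
setClass("MaterialMap",
  representation(E = "array", nu = "array", labels = "LabelVolume",
                 scenario = "character"))

setValidity("MaterialMap", function(object) {
  msg <- character()
  if (!identical(dim(object@E), dim(object@nu)))
    msg <- c(msg, "E and nu must share one shape")
  fg <- object@labels@labels != 0L
  if (any(object@E[fg] <= 0))
    msg <- c(msg, "E must be > 0 on every non-background voxel")
  if (any(object@nu[fg] <= 0 | object@nu[fg] >= 0.5))
    msg <- c(msg, "nu must lie in (0, 0.5) on non-background voxels")
  if (length(msg)) msg else TRUE
})

#' VoxelMesh: hexahedral discretization of the foreground voxels
#'
#' One trilinear 8-node hexahedron per non-background voxel; shared nodes are
#' deduplicated so that the number of unknowns is 3 x node count.
#'
#' @slot nodes numeric matrix (n x 3), node coordinates in mm.
#' @slot elems integer matrix (m x 8), node indices per element (VTK order).
#' @slot E,nu numeric(m), per-element elastic constants.
#' @slot implant,nonunion logical(m), per-element flags.
#' @slot voxel integer matrix (m x 3), 1-based voxel index of each element.
#' @slot spacing numeric(3), voxel size in mm.
#' @slot dims integer(3), voxel-grid dimensions of the source volume.
#' @export
setClass("VoxelMesh",
  representation(nodes = "matrix", elems = "matrix", E = "numeric",
                 nu = "numeric", implant = "logical", nonunion = "logical",
                 voxel = "matrix", spacing = "numeric", dims = "integer"))

setValidity("VoxelMesh", function(object) {
  msg <- character()
  m <- nrow(object@elems)
  if (ncol(object@elems) != 8L) msg <- c(msg, "elems must have 8 columns")
  if (length(object@E) != m || length(object@nu) != m)
    msg <- c(msg, "E and nu must have one value per element")
  if (m && any(object@E <= 0)) msg <- c(msg, "every element must have E > 0")
  if (m && max(object@elems) > nrow(object@nodes))
    msg <- c(msg, "connectivity references missing nodes")
  if (length(msg)) msg else TRUE
})

#' LoadCase: boundary conditions for a static solve
#'
#' @slot fixedNodes integer vector, nodes with all three components fixed.
#' @slot loadedNodes integer vector, nodes carrying applied force.
#' @slot nodalForces numeric matrix (length(loadedNodes) x 3), N per node;
#'   rows sum to \code{totalForce} exactly.
#' @slot totalForce numeric(3), resultant in N.
#' @export
setClass("LoadCase",
  representation(fixedNodes = "integer", loadedNodes = "integer",
                 nodalForces = "matrix", totalForce = "numeric"))

setValidity("LoadCase", function(object) {
  msg <- character()
  if (!length(object@fixedNodes)) msg <- c(msg, "fixedNodes must be nonempty")
  if (!length(object@loadedNodes)) msg <- c(msg, "loadedNodes must be nonempty")
  if (length(intersect(object@fixedNodes, object@loadedNodes)))
    msg <- c(msg, "fixed and loaded node sets must be disjoint")
  if (sqrt(sum(object@totalForce^2)) <= 0)
    msg <- c(msg, "total force magnitude must be > 0")
  if (nrow(object@nodalForces) != length(object@loadedNodes))
    msg <- c(msg, "one force row per loaded node required")
  if (max(abs(colSums(object@nodalForces) - object@totalForce)) > 1e-9 * (1 + max(abs(object@totalForce))))
    msg <- c(msg, "nodal forces must sum to totalForce")
  if (length(msg)) msg else TRUE
})

#' StressField: per-element stress state
#'
#' @slot tensor numeric matrix (m x 6): xx, yy, zz, xy, yz, zx components, Pa.
#' @slot vonMises numeric(m), von Mises equivalent stress, Pa.
#' @slot scaled numeric(m), dimensionless: \code{100 * vonMises / referenceMax}.
#' @slot referenceMax numeric(1), the scaling reference in Pa (NA before
#'   scaling).
#' @export
setClass("StressField",
  representation(tensor = "matrix", vonMises = "numeric", scaled = "numeric",
                 referenceMax = "numeric"))

setValidity("StressField", function(object) {
  msg <- character()
  if (ncol(object@tensor) != 6L) msg <- c(msg, "tensor needs 6 columns")
  if (length(object@vonMises) != nrow(object@tensor))
    msg <- c(msg, "vonMises must have one value per element")
  if (length(object@vonMises) && min(object@vonMises) < -1e-9)
    msg <- c(msg, "vonMises must be non-negative")
  if (length(msg)) msg else TRUE
})

#' OptimizationResult: trajectory of the fusion-area reduction
#'
#' @slot steps data.frame with one row per committed demotion sweep: columns
#'   \code{step}, \code{removed} (cells demoted), \code{reduction} (percent of
#'   the initial nonunion cells demoted this step), \code{cumReduction}
#'   (running total, percent), \code{scaledMax} (global scaled von Mises after
#'   the sweep).  Step 0 is the full-fusion state with reduction NA.
#' @slot survivingMask 3D logical array over the voxel grid: the nonunion
#'   cells still fused when the loop stopped.
#' @slot totalReduction numeric(1), percent of initial nonunion cells demoted.
#' @slot remainingFraction numeric(1), \code{100 - totalReduction}.
#' @slot referenceMax numeric(1), worst-case maximum von Mises (Pa).
#' @slot initialCells integer(1), size of the initial nonunion set.
#' @slot status character: \code{"stop_cap"}, \code{"no_demotion"},
#'   \code{"max_steps"} or \code{"solver_failure"}.
#' @export
setClass("OptimizationResult",
  representation(steps = "data.frame", survivingMask = "array",
                 totalReduction = "numeric", remainingFraction = "numeric",
                 referenceMax = "numeric", initialCells = "integer",
                 status = "character"))

setValidity("OptimizationResult", function(object) {
  msg <- character()
  cum <- object@steps$cumReduction
  cum <- cum[!is.na(cum)]
  if (length(cum) > 1 && any(diff(cum) < -1e-9))
    msg <- c(msg, "cumulative reduction must be non-decreasing")
  if (abs(object@remainingFraction + object@totalReduction - 100) > 1e-9)
    msg <- c(msg, "remaining % + total reduction % must equal 100")
  if (length(msg)) msg else TRUE
})
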