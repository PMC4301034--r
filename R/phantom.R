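#' @include AllClasses.R configs.R
NULL

## Voxel-center coordinate vectors (mm) for a grid. 0-based voxel i has its
## center at origin + (i + 0.5) * spacing.
.voxelCenters <- function(dims, spacing, origin = c(0, 0, 0)) {
  lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 0.5) * spacing[a])
}

## Boolean construction masks for each phantom structure, on the voxel grid.
## Returned in paint order: later masks override earlier ones.
.phantomMasks <- function(config) {
  d <- config@gridDims
  sp <- config@spacing
  ext <- d * sp
  cx <- ext[1] / 2
  cy <- ext[2] / 2
  gapC <- if (is.na(config@gapCenter)) ext[3] / 2 else config@gapCenter
  r0 <- config@outerRadius
  ri <- r0 - config@corticalThickness
  plateX0 <- cx + r0 + config@plateOffset
  plateX1 <- plateX0 + config@plateThickness

  ## reject geometry that does not fit inside the grid, naming the dimension
  if (cx - r0 < 0 || cy - r0 < 0 || cx + r0 > ext[1] || cy + r0 > ext[2])
    stop(errorCondition(sprintf(
      "bone of outer radius %.3g mm does not fit the %.3g x %.3g mm in-plane extent (outerRadius)",
      r0, ext[1], ext[2]), class = c("nonunionFE_geometry_error", "error")))
  if (plateX1 > ext[1])
    stop(errorCondition(sprintf(
      "plate outer face at x = %.3g mm exceeds the %.3g mm x extent (plateThickness/plateOffset)",
      plateX1, ext[1]), class = c("nonunionFE_geometry_error", "error")))
  if (cy + config@plateWidth / 2 > ext[2] || cy - config@plateWidth / 2 < 0)
    stop(errorCondition(sprintf(
      "plate width %.3g mm exceeds the %.3g mm y extent (plateWidth)",
      config@plateWidth, ext[2]), class = c("nonunionFE_geometry_error", "error")))
  if (any(config@plateZ < 0) || any(config@plateZ > ext[3]))
    stop(errorCondition(sprintf(
      "plate z extent [%.3g, %.3g] mm exceeds the %.3g mm z extent (plateZ)",
      config@plateZ[1], config@plateZ[2], ext[3]),
      class = c("nonunionFE_geometry_error", "error")))
  if (any(config@screwZ < 0) || any(config@screwZ > ext[3]))
    stop(errorCondition(
      "a screw z position lies outside the z extent (screwZ)",
      class = c("nonunionFE_geometry_error", "error")))

  cc <- .voxelCenters(d, sp)
  x <- cc[[1]]; y <- cc[[2]]; z <- cc[[3]]
  ## in-plane squared radius from the bone axis, d1 x d2
  r2 <- outer((x - cx)^2, (y - cy)^2, `+`)
  inBone <- r2 <= r0^2
  inCore <- r2 <= ri^2
  zAll <- rep(TRUE, d[3])
  gapZ <- abs(z - gapC) <= config@gapHalfwidth

  expand <- function(planeMask, zMask) {
    array(planeMask, dim = d) & rep(zMask, each = d[1] * d[2])
  }
  cortical <- expand(inBone & !inCore, zAll & !gapZ)
  cancellous <- expand(inCore, zAll & !gapZ)
  soft <- expand(inBone, gapZ)

  plateXY <- outer(x >= plateX0 & x <= plateX1,
                   abs(y - cy) <= config@plateWidth / 2, `&`)
  plate <- expand(plateXY, z >= config@plateZ[1] & z <= config@plateZ[2])
  screws <- array(FALSE, dim = d)
  for (zs in config@screwZ) {
    ## cylinder along x from the far cortex to the plate outer face
    axial <- x >= cx - r0 & x <= plateX1
    ryz <- outer((y - cy)^2, (z - zs)^2, `+`) <= config@screwRadius^2
    screws <- screws | outer(axial, ryz, `&`)
  }
  list(cancellous = cancellous, cortical = cortical, soft = soft,
       implant = plate | screws)
}

#' Generate a synthetic CT-like stack of a plated fractured long bone
#'
#' Builds a hollow cortical cylinder with a cancellous core, a transverse
#' fracture gap filled with soft-tissue gray values, and a lateral plate with
#' cylindrical screws crossing the bone above and below the gap.  Gaussian
#' noise of standard deviation \code{noiseSD} is added and the result clipped
#' to the 12-bit range.  Output is identical for identical seeds.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @return an \linkS4class{ImageStack}.
#' @examples
#' stk <- generatePhantom(phantomConfig(gridDims = c(24, 24, 40),
#'                                      spacing = c(1, 1, 1),
#'                                      plateZ = c(5, 35),
#'                                      screwZ = c(12, 28), noiseSD = 0))
#' @export
generatePhantom <- function(config) {
  validObject(config)
  masks <- .phantomMasks(config)
  g <- config@grayLevels
  vals <- array(g[["background"]], dim = config@gridDims)
  vals[masks$cancellous] <- g[["cancellous"]]
  vals[masks$cortical] <- g[["cortical"]]
  vals[masks$soft] <- g[["soft"]]
  vals[masks$implant] <- g[["implant"]]
  if (config@noiseSD > 0) {
    hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (hadSeed) get(".Random.seed", envir = globalenv())
    on.exit(if (hadSeed) assign(".Random.seed", old, envir = globalenv())
            else rm(".Random.seed", envir = globalenv()))
    set.seed(config@seed)
    vals <- vals + rnorm(length(vals), sd = config@noiseSD)
    vals[vals < 0] <- 0
    vals[vals > GRAY_MAX] <- GRAY_MAX
  }
  new("ImageStack", values = vals, spacing = config@spacing,
      origin = c(0, 0, 0))
}
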