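#' @include AllClasses.R configs.R
NULL

## Shift a 3D array by one voxel along an axis with edge replication, so that
## boundary differences vanish (zero-flux / Neumann condition).
.shift3 <- function(a, axis, dir) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  i <- idx[[axis]]
  idx[[axis]] <- if (dir > 0) pmin(i + 1L, d[axis]) else pmax(i - 1L, 1L)
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

#' Edge-preserving smoothing by Perona-Malik anisotropic diffusion
#'
#' Explicit forward-Euler scheme on the 6-neighborhood with zero-flux
#' boundaries and exponential conductance
#' \eqn{g(s) = \exp(-(s/\kappa)^2)}: flat regions diffuse, strong edges
#' (gradient magnitude well above \code{kappa}) are preserved.  With zero
#' iterations the input is returned unchanged; the scheme conserves the
#' global gray-value sum.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param params a \linkS4class{DiffusionParams}.
#' @return the smoothed \linkS4class{ImageStack} (same shape and spacing).
#' @export
anisotropicDiffusion <- function(stack, params) {
  validObject(params)
  v <- stack@values
  k2 <- params@kappa^2
  for (it in seq_len(params@iterations)) {
    acc <- 0
    for (axis in 1:3) for (dir in c(-1L, 1L)) {
      d <- .shift3(v, axis, dir) - v
      acc <- acc + exp(-(d * d) / k2) * d
    }
    v <- v + params@dt * acc
  }
  new("ImageStack", values = v, spacing = stack@spacing,
      origin = stack@origin)
}

#' Segment a stack into five tissue classes by thresholding
#'
#' Four strictly increasing grayscale cut points define five bins mapped to
#' background, soft tissue, cancellous bone, cortical bone and implant.
#' Typically applied after \code{\link{anisotropicDiffusion}}.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param thresholds numeric(4), strictly increasing cut points; the defaults
#'   bracket the phantom's default gray levels.
#' @return a \linkS4class{LabelVolume} with an empty nonunion mask.
#' @export
segmentStack <- function(stack, thresholds = c(150, 800, 1950, 3300)) {
  if (length(thresholds) != 4L || is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be 4 strictly increasing cut points")
  lab <- array(findInterval(stack@values, thresholds),
               dim = dim(stack@values))
  new("LabelVolume", labels = lab,
      nonunion = array(FALSE, dim = dim(lab)),
      grayscale = stack@values, thresholds = as.numeric(thresholds),
      spacing = stack@spacing, origin = stack@origin)
}

#' Mark the nonunion region as an axis-aligned slab
#'
#' Replaces interactive nonunion delineation with a declarative slab given in
#' physical coordinates along the bone's long axis.  The mask covers exactly
#' the soft, cancellous and cortical voxels whose centers fall inside the
#' slab; implant and background voxels are never marked.
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param zRange numeric(2), slab extent \code{c(lo, hi)} in mm.
#' @return the \linkS4class{LabelVolume} with its nonunion mask set.
#' @export
markNonunion <- function(labels, zRange) {
  stopifnot(length(zRange) == 2L)
  d <- dim(labels@labels)
  mask <- array(FALSE, dim = d)
  if (diff(zRange) > 0) {
    zc <- labels@origin[3] + (seq_len(d[3]) - 0.5) * labels@spacing[3]
    inZ <- zc >= zRange[1] & zc <= zRange[2]
    mask <- array(rep(inZ, each = d[1] * d[2]), dim = d) &
      labels@labels %in% 1:3
  }
  if (!any(mask))
    warning(warningCondition("nonunion slab selects no voxels",
                             class = "nonunionFE_empty_mask"))
  labels@nonunion <- mask
  validObject(labels)
  labels
}

## Block-average the in-plane dimensions of a 3D array by a level x level
## window; trailing remainder pixels are dropped from the high-index edge.
.blockMean <- function(v, level, zBin = FALSE) {
  d <- dim(v)
  n1 <- d[1] %/% level
  n2 <- d[2] %/% level
  if (n1 < 1L || n2 < 1L)
    stop("coarsening level exceeds the in-plane image width")
  v <- v[seq_len(n1 * level), seq_len(n2 * level), , drop = FALSE]
  d <- dim(v)
  m1 <- colMeans(array(v, c(level, n1, d[2] * d[3])))     # average x-blocks
  m1 <- array(m1, c(n1, d[2], d[3]))
  p <- aperm(m1, c(2, 1, 3))
  m2 <- colMeans(array(p, c(level, n2, n1 * d[3])))       # average y-blocks
  out <- aperm(array(m2, c(n2, n1, d[3])), c(2, 1, 3))
  if (zBin) {
    n3 <- dim(out)[3] %/% level
    if (n3 < 1L) stop("coarsening level exceeds the slice count")
    out <- out[, , seq_len(n3 * level), drop = FALSE]
    q <- aperm(out, c(3, 1, 2))
    m3 <- colMeans(array(q, c(level, n3, n1 * n2)))
    out <- aperm(array(m3, c(n3, n1, n2)), c(2, 3, 1))
  }
  out
}

#' @describeIn coarsen block-average the grayscale values; in-plane spacing is
#'   multiplied by the level.
#' @export
setMethod("coarsen", "ImageStack", function(x, spec) {
  validObject(spec)
  if (spec@level == 1L && !spec@zBin) return(x)
  vals <- .blockMean(x@values, spec@level, spec@zBin)
  sp <- x@spacing * c(spec@level, spec@level,
                      if (spec@zBin) spec@level else 1)
  new("ImageStack", values = vals, spacing = sp, origin = x@origin)
})

#' @describeIn coarsen block-average the stored grayscale, re-classify the
#'   averaged values with \code{spec@classThresholds}, and carry the nonunion
#'   mask to windows where it covers at least half the pixels (and the new
#'   class is neither implant nor background).
#' @export
setMethod("coarsen", "LabelVolume", function(x, spec) {
  validObject(spec)
  if (spec@level == 1L && !spec@zBin) return(x)
  gray <- .blockMean(x@grayscale, spec@level, spec@zBin)
  lab <- array(findInterval(gray, spec@classThresholds), dim = dim(gray))
  frac <- .blockMean(x@nonunion + 0, spec@level, spec@zBin)
  mask <- frac >= 0.5 & lab %in% 1:3
  sp <- x@spacing * c(spec@level, spec@level,
                      if (spec@zBin) spec@level else 1)
  new("LabelVolume", labels = lab, nonunion = mask, grayscale = gray,
      thresholds = spec@classThresholds, spacing = sp, origin = x@origin)
})

.cropIdx <- function(nz, proximalFraction, distalFraction) {
  if (proximalFraction < 0 || distalFraction < 0 ||
      proximalFraction + distalFraction >= 1)
    stop("crop fractions must be >= 0 and sum to < 1")
  nProx <- floor(proximalFraction * nz)
  nDist <- floor(distalFraction * nz)
  list(keep = seq.int(nDist + 1L, nz - nProx), nDist = nDist)
}

#' @describeIn cropEpiphyses drop slices from both ends of a grayscale stack.
#' @export
setMethod("cropEpiphyses", "ImageStack",
  function(x, proximalFraction = 0.15, distalFraction = 0.15) {
    ci <- .cropIdx(dim(x@values)[3], proximalFraction, distalFraction)
    org <- x@origin
    org[3] <- org[3] + ci$nDist * x@spacing[3]
    new("ImageStack", values = x@values[, , ci$keep, drop = FALSE],
        spacing = x@spacing, origin = org)
  })

#' @describeIn cropEpiphyses drop slices from both ends of a label volume.
#' @export
setMethod("cropEpiphyses", "LabelVolume",
  function(x, proximalFraction = 0.15, distalFraction = 0.15) {
    ci <- .cropIdx(dim(x@labels)[3], proximalFraction, distalFraction)
    org <- x@origin
    org[3] <- org[3] + ci$nDist * x@spacing[3]
    new("LabelVolume", labels = x@labels[, , ci$keep, drop = FALSE],
        nonunion = x@nonunion[, , ci$keep, drop = FALSE],
        grayscale = x@grayscale[, , ci$keep, drop = FALSE],
        thresholds = x@thresholds, spacing = x@spacing, origin = org)
  })
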