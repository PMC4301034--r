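# Fixtures are built in code; nothing is stored on disk.

# Uniform cortical bar as a LabelVolume (1 mm voxels unless stated).
barLabels <- function(d, gray = 2600, spacing = c(1, 1, 1)) {
  lab <- array(3L, dim = d)
  new("LabelVolume", labels = lab, nonunion = array(FALSE, d),
      grayscale = array(gray, d), thresholds = c(150, 800, 1950, 3300),
      spacing = spacing, origin = c(0, 0, 0))
}

# Uniform-material bar mesh with prescribed constants.
barMesh <- function(d, E, nu, spacing = c(1, 1, 1)) {
  mesh <- buildMesh(assignMaterials(barLabels(d, spacing = spacing)))
  mesh@E[] <- E
  mesh@nu[] <- nu
  mesh
}

# Small plated-phantom configuration used by the optimizer tests.
toyPhantomConfig <- function(noiseSD = 0, ...) {
  args <- list(gridDims = c(24L, 24L, 60L), spacing = c(1, 1, 2),
               outerRadius = 6, corticalThickness = 2.5, gapHalfwidth = 3,
               plateZ = c(20, 100), screwZ = c(40, 50, 70, 80),
               noiseSD = noiseSD)
  args[names(list(...))] <- list(...)
  do.call(phantomConfig, args)
}

toyLabels <- function(noiseSD = 0, ...) {
  stk <- generatePhantom(toyPhantomConfig(noiseSD = noiseSD, ...))
  markNonunion(segmentStack(stk), c(57, 63))
}

# Naive reference implementation of the explicit Perona-Malik scheme
# (triple loop, zero-flux boundaries) -- the independent oracle for the
# vectorized diffusion.
referenceDiffusion <- function(v, iterations, kappa, dt) {
  d <- dim(v)
  g <- function(s) exp(-(s / kappa)^2)
  for (it in seq_len(iterations)) {
    out <- v
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      acc <- 0
      for (nb in list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                      c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))) {
        if (all(nb >= 1) && all(nb <= d)) {
          dv <- v[nb[1], nb[2], nb[3]] - v[i, j, k]
          acc <- acc + g(abs(dv)) * dv
        }
      }
      out[i, j, k] <- v[i, j, k] + dt * acc
    }
    v <- out
  }
  v
}

# Desk-scale pipeline products shared by the heavy tests; computed once.
.deskCache <- new.env(parent = emptyenv())
deskRun <- function() {
  if (!is.null(.deskCache$res)) return(.deskCache$res)
  cfg <- defaultPipelineConfig()
  ph <- do.call(phantomConfig, c(cfg$phantom, list(seed = 1L)))
  stk <- generatePhantom(ph)
  lv <- markNonunion(
    segmentStack(anisotropicDiffusion(stk, diffusionParams()),
                 cfg$segmentation$thresholds),
    cfg$nonunion$zRange)
  lvc <- cropEpiphyses(coarsen(lv, coarseningSpec(2L)), 0.15, 0.15)
  wc <- worstCaseReference(lvc)
  opt <- minimalFusion(lvc)
  .deskCache$res <- list(labels = lvc, wc = wc, opt = opt)
  .deskCache$res
}
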