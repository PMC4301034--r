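test_that("diffusion identity cases hold", {
  stk <- generatePhantom(toyPhantomConfig(noiseSD = 30,
                                          gridDims = c(12L, 12L, 16L),
                                          spacing = c(2, 2, 4),
                                          plateZ = c(10, 55),
                                          screwZ = c(20, 45)))
  expect_identical(anisotropicDiffusion(stk, diffusionParams(iterations = 0)),
                   stk)
  flat <- new("ImageStack", values = array(1234, dim = c(6, 5, 4)),
              spacing = c(1, 1, 1), origin = c(0, 0, 0))
  out <- anisotropicDiffusion(flat, diffusionParams(iterations = 8))
  expect_equal(stackValues(out), stackValues(flat))
})

test_that("diffusion matches the naive reference scheme on a small stack", {
  set.seed(7)
  v <- array(runif(8^3, 0, 4095), dim = c(8, 8, 8))
  stk <- new("ImageStack", values = v, spacing = c(1, 1, 1),
             origin = c(0, 0, 0))
  got <- stackValues(anisotropicDiffusion(stk,
           diffusionParams(iterations = 3, kappa = 400, dt = 1 / 6)))
  want <- referenceDiffusion(v, 3, 400, 1 / 6)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("diffusion conserves the gray-value sum and respects kappa", {
  set.seed(11)
  v <- array(runif(16^3, 0, 2000), dim = c(16, 16, 16))
  # step edge of height 1000 halfway along x
  v[9:16, , ] <- v[9:16, , ] + 1000
  stk <- new("ImageStack", values = v, spacing = c(1, 1, 1),
             origin = c(0, 0, 0))
  smoothLarge <- anisotropicDiffusion(stk, diffusionParams(10, kappa = 1e4))
  smoothSmall <- anisotropicDiffusion(stk, diffusionParams(10, kappa = 50))
  expect_equal(sum(stackValues(smoothLarge)), sum(v), tolerance = 1e-6)
  expect_equal(sum(stackValues(smoothSmall)), sum(v), tolerance = 1e-6)
  # edge contrast: kappa >> step height smooths the edge away, kappa << keeps it
  edgeJump <- function(s) mean(abs(stackValues(s)[9, , ] - stackValues(s)[8, , ]))
  expect_lt(edgeJump(smoothLarge), 0.5 * edgeJump(smoothSmall))
})

test_that("segmentation reproduces the noiseless construction masks", {
  pc <- toyPhantomConfig(noiseSD = 0)
  lv <- segmentStack(generatePhantom(pc))
  masks <- nonunionFE:::.phantomMasks(pc)
  want <- array(0L, dim = gridDims(lv))
  want[masks$cancellous] <- 2L
  want[masks$cortical] <- 3L
  want[masks$soft] <- 1L
  want[masks$implant] <- 4L
  expect_identical(tissueLabels(lv), want)

  zero <- new("ImageStack", values = array(0, c(4, 4, 4)),
              spacing = c(1, 1, 1), origin = c(0, 0, 0))
  expect_true(all(tissueLabels(segmentStack(zero)) == 0L))
  expect_error(segmentStack(zero, thresholds = c(3, 2, 1, 0)), "increasing")
})

test_that("noise at sd 50 misclassifies under 1% of voxels", {
  clean <- tissueLabels(segmentStack(generatePhantom(toyPhantomConfig(0))))
  noisy <- tissueLabels(segmentStack(generatePhantom(
    toyPhantomConfig(noiseSD = 50, seed = 3L))))
  expect_gte(mean(clean == noisy), 0.99)
})

test_that("nonunion slab marks exactly the non-implant tissue inside it", {
  pc <- toyPhantomConfig(noiseSD = 0)
  lv <- segmentStack(generatePhantom(pc))
  g <- pc@grayLevels
  lv2 <- markNonunion(lv, c(57, 63))
  nSoft <- sum(stackValues(generatePhantom(pc)) == g[["soft"]])
  expect_identical(sum(nonunionMask(lv2)), nSoft)
  expect_true(all(tissueLabels(lv2)[nonunionMask(lv2)] %in% 1:3))

  # slab over an implant-only region and a zero-thickness slab: empty masks
  onlyImplant <- new("LabelVolume",
    labels = array(rep(c(0L, 4L), each = 8), c(4, 2, 2)),
    nonunion = array(FALSE, c(4, 2, 2)),
    grayscale = array(4000, c(4, 2, 2)),
    thresholds = c(150, 800, 1950, 3300), spacing = c(1, 1, 1),
    origin = c(0, 0, 0))
  expect_warning(m <- markNonunion(onlyImplant, c(0, 2)),
                 class = "nonunionFE_empty_mask")
  expect_false(any(nonunionMask(m)))
  expect_warning(m0 <- markNonunion(lv, c(60, 60)),
                 class = "nonunionFE_empty_mask")
  expect_false(any(nonunionMask(m0)))
})

test_that("coarsened widths follow floor(N / level)", {
  stk <- new("ImageStack", values = array(runif(10 * 10 * 3, 0, 100),
                                          dim = c(10, 10, 3)),
             spacing = c(1, 1, 2), origin = c(0, 0, 0))
  for (lev in c(1L, 2L, 3L, 4L, 7L)) {
    out <- coarsen(stk, coarseningSpec(lev))
    expect_identical(dim(stackValues(out))[1:2], rep(10L %/% lev, 2))
    expect_identical(dim(stackValues(out))[3], 3L)
    expect_equal(voxelSpacing(out), c(lev, lev, 2))
  }
  expect_identical(coarsen(stk, coarseningSpec(1L)), stk)
  expect_error(coarsen(stk, coarseningSpec(11L)), "level")
})

test_that("block averaging preserves the mean when level divides the width", {
  v <- array(runif(12 * 12 * 4, 0, 4095), dim = c(12, 12, 4))
  stk <- new("ImageStack", values = v, spacing = c(1, 1, 1),
             origin = c(0, 0, 0))
  for (lev in c(2L, 3L, 4L, 6L))
    expect_equal(mean(stackValues(coarsen(stk, coarseningSpec(lev)))),
                 mean(v), tolerance = 1e-12)
})

test_that("segment and coarsen commute at level 1", {
  stk <- generatePhantom(toyPhantomConfig(noiseSD = 40))
  spec <- coarseningSpec(1L)
  a <- coarsen(segmentStack(stk), spec)
  b <- segmentStack(coarsen(stk, spec))
  expect_identical(tissueLabels(a), tissueLabels(b))
})

test_that("coarsening a label volume re-thresholds the averaged grayscale", {
  lv <- markNonunion(segmentStack(generatePhantom(toyPhantomConfig())),
                     c(57, 63))
  out <- coarsen(lv, coarseningSpec(2L))
  expect_identical(dim(tissueLabels(out))[1:2], c(12L, 12L))
  expect_identical(array(findInterval(out@grayscale, out@thresholds),
                         dim = gridDims(out)), tissueLabels(out))
  # mask survives inside the gap, never lands on implant/background
  expect_gt(sum(nonunionMask(out)), 0)
  expect_true(all(tissueLabels(out)[nonunionMask(out)] %in% 1:3))
})

test_that("epiphysis cropping removes the requested slice fractions", {
  stk <- generatePhantom(toyPhantomConfig())
  expect_identical(cropEpiphyses(stk, 0, 0), stk)
  cropped <- cropEpiphyses(stk, 0.15, 0.15)
  expect_identical(dim(stackValues(cropped))[3], 42L)  # 60 - 2*9
  expect_equal(stackOrigin(cropped)[3], 9 * 2)
  expect_error(cropEpiphyses(stk, 0.6, 0.5), "fractions")

  # mesh-cell reduction equals the removed-slice fraction on a uniform bar
  lv <- barLabels(c(3, 3, 20))
  full <- elementCount(buildMesh(assignMaterials(lv)))
  part <- elementCount(buildMesh(assignMaterials(cropEpiphyses(lv, 0.2, 0.1))))
  expect_equal(1 - part / full, 6 / 20)
})
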