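# Small plated phantom shared by the optimizer tests (built once).
.optCache <- new.env(parent = emptyenv())
optFixture <- function() {
  if (!is.null(.optCache$fx)) return(.optCache$fx)
  pc <- phantomConfig(gridDims = c(16L, 16L, 40L), spacing = c(1.5, 1.5, 2),
                      outerRadius = 6, corticalThickness = 2.5,
                      gapHalfwidth = 2, plateZ = c(16, 64),
                      screwZ = c(28, 36, 44, 52), noiseSD = 0)
  lv <- markNonunion(segmentStack(generatePhantom(pc)), c(38, 42))
  model <- calibrationModel()
  .optCache$fx <- list(labels = lv, model = model,
                       result = minimalFusion(lv, model))
  .optCache$fx
}

test_that("the worst-case scenario defines the stress scale", {
  fx <- optFixture()
  wc <- worstCaseReference(fx$labels, fx$model)
  sc <- scaledStress(wc$field)
  expect_equal(max(sc), 100)
  # the implant absorbs the stress; the unfused gap is (near-)stress-free
  expect_true(wc$mesh@implant[which.max(sc)])
  expect_lte(max(sc[wc$mesh@nonunion]), 1)
  # an empty nonunion mask is rejected
  expect_error(worstCaseReference(segmentStack(generatePhantom(
    toyPhantomConfig())), fx$model), "mask")
})

test_that("a vanishing demotion threshold stops the loop with 0% reduction", {
  fx <- optFixture()
  res <- minimalFusion(fx$labels, fx$model,
                       optimizationConfig(threshold = 1e-9))
  expect_identical(res@status, "no_demotion")
  expect_equal(res@totalReduction, 0)
  expect_equal(res@remainingFraction, 100)
  expect_identical(sum(res@survivingMask), sum(nonunionMask(fx$labels)))
})

test_that("the trajectory is monotone and the active set shrinks", {
  fx <- optFixture()
  tr <- trajectory(fx$result)
  expect_gte(nrow(tr), 2)                      # at least one committed sweep
  expect_true(all(tr$removed[-1] > 0))         # strict shrink per sweep
  cum <- tr$cumReduction
  expect_true(all(diff(cum) >= 0))
  sm <- tr$scaledMax
  expect_true(all(diff(sm) >= -1e-6 * sm[1]))  # non-decreasing within tol
  # bounds: full fusion <= final <= 100 (+ tolerance)
  expect_lte(sm[1], sm[length(sm)] + 1e-9)
  expect_lte(sm[length(sm)], 100 + 1e-6)
  # bookkeeping ties the rows to the totals
  expect_equal(sum(tr$reduction, na.rm = TRUE), fx$result@totalReduction)
  expect_equal(fx$result@remainingFraction, 100 - fx$result@totalReduction)
  expect_identical(sum(fx$result@survivingMask),
                   as.integer(round(fx$result@initialCells *
                                      fx$result@remainingFraction / 100)))
})

test_that("the optimizer is deterministic", {
  fx <- optFixture()
  again <- minimalFusion(fx$labels, fx$model)
  expect_identical(trajectory(again), trajectory(fx$result))
  expect_identical(again@survivingMask, fx$result@survivingMask)
})

test_that("surviving cells are the mechanically relevant ones", {
  fx <- optFixture()
  res <- fx$result
  model <- fx$model
  mesh <- buildMesh(assignMaterials(fx$labels, model, "full_fusion"))
  lc <- applyLoadCase(mesh)
  vmFull <- vonMises(elementStress(mesh, solveDisplacements(mesh, lc)$u))
  base <- max(vmFull)
  nnE <- which(mesh@nonunion)
  surv <- res@survivingMask[mesh@voxel[nnE, , drop = FALSE]]
  expect_gt(sum(!surv), sum(surv))  # more than half the gap was demoted

  solveMax <- function(softIdx) {
    m2 <- mesh
    m2@E[softIdx] <- model@ESoft
    m2@nu[softIdx] <- model@nuSoft
    max(vonMises(elementStress(m2, solveDisplacements(m2, lc)$u)))
  }
  # removing the (larger) demoted set perturbs the peak stress less than
  # removing the (smaller) surviving set in its place
  riseFinal <- solveMax(nnE[!surv]) - base
  riseComplement <- solveMax(nnE[surv]) - base
  expect_gt(riseComplement, riseFinal)
  # survivors carry the load in the fused state
  expect_gt(mean(vmFull[nnE[surv]]), 1.5 * mean(vmFull[nnE[!surv]]))

  # exhaustive single-cell-removal oracle: the cell whose removal raises the
  # peak stress most is among the survivors
  impact <- vapply(nnE, function(e) solveMax(e), numeric(1)) - base
  expect_true(surv[which.max(impact)])
})

test_that("summarize reports per-step and total reductions consistently", {
  s <- summarizeOptimization(c(50.7, 3.4, 21.9, 12.2, 5.5, 2.7))
  expect_equal(s$totalReduction, 96.4)
  expect_equal(s$remainingFraction, 3.6)
  expect_equal(s$totalReduction + s$remainingFraction, 100)

  s0 <- summarizeOptimization(0)
  expect_equal(s0$totalReduction, 0)
  expect_equal(s0$remainingFraction, 100)

  fx <- optFixture()
  stem <- file.path(tempdir(), "traj")
  s2 <- summarizeOptimization(fx$result, path = stem)
  expect_equal(s2$totalReduction, fx$result@totalReduction)
  csv <- utils::read.csv(paste0(stem, ".csv"))
  expect_equal(csv$scaledMax, trajectory(fx$result)$scaledMax)
  js <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  expect_equal(js$totalReduction + js$remainingFraction, 100)
})
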