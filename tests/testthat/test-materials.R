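test_that("grayscale maps affinely to the Hounsfield scale", {
  expect_equal(grayToHounsfield(1024), 0)
  expect_equal(grayToHounsfield(0), -1024)
  m <- calibrationModel(huSlope = 0.5, huIntercept = -200)
  a <- 120; b <- 340
  expect_equal(grayToHounsfield(a, m) + grayToHounsfield(b, m) -
                 grayToHounsfield(0, m), grayToHounsfield(a + b, m))
  expect_error(grayToHounsfield(5000), "12-bit")
})

test_that("the density power law evaluates and scales as E = a rho^b", {
  m <- calibrationModel(powerA = 6850, powerB = 1.49)
  expect_equal(densityToModulus(1, m), 6.85e9)
  expect_equal(densityToModulus(0, m), 0)
  expect_equal(densityToModulus(2, m) / densityToModulus(1, m), 2^1.49)
  expect_error(densityToModulus(-0.1, m), "negative")
  rho <- seq(0.1, 2, by = 0.1)
  expect_true(all(diff(densityToModulus(rho, m)) > 0))
})

test_that("scenario overrides set nonunion cells and only nonunion cells", {
  lv <- toyLabels()
  model <- calibrationModel()
  base <- assignMaterials(lv, model, "as_segmented")
  worst <- assignMaterials(lv, model, "worst_case")
  full <- assignMaterials(lv, model, "full_fusion")
  nn <- nonunionMask(lv)
  expect_true(all(youngsModulus(worst)[nn] == model@ESoft))
  expect_true(all(youngsModulus(full)[nn] == model@ECortical))
  expect_true(all(poissonRatio(full)[nn] == model@nuBone))
  # untouched elsewhere, bitwise
  expect_identical(youngsModulus(worst)[!nn], youngsModulus(base)[!nn])
  expect_identical(youngsModulus(full)[!nn], youngsModulus(base)[!nn])
  # implant voxels carry the titanium constants exactly
  imp <- tissueLabels(lv) == 4L
  expect_true(all(youngsModulus(base)[imp] == model@EImplant))
  expect_true(all(poissonRatio(base)[imp] == model@nuImplant))
})

test_that("an empty nonunion mask makes all scenarios coincide", {
  lv <- segmentStack(generatePhantom(toyPhantomConfig()))
  expect_identical(youngsModulus(assignMaterials(lv, scenario = "worst_case")),
                   youngsModulus(assignMaterials(lv, scenario = "full_fusion")))
})

test_that("explicit fusion masks split nonunion cells into cortical and soft", {
  lv <- toyLabels()
  model <- calibrationModel()
  nn <- nonunionMask(lv)
  keep <- array(FALSE, dim = gridDims(lv))
  keep[which(nn)[1:10]] <- TRUE
  mm <- assignMaterials(lv, model, "mask", fusedMask = keep)
  expect_true(all(youngsModulus(mm)[nn & keep] == model@ECortical))
  expect_true(all(youngsModulus(mm)[nn & !keep] == model@ESoft))
  expect_error(assignMaterials(lv, model, "mask",
                               fusedMask = array(TRUE, c(2, 2, 2))),
               "shape")
})

test_that("bone modulus is monotone in grayscale and clamped to valid range", {
  d <- c(8, 1, 1)
  gray <- array(seq(900, 1900, length.out = 8), dim = d)  # cancellous band
  lv <- new("LabelVolume", labels = array(2L, d),
            nonunion = array(FALSE, d), grayscale = gray,
            thresholds = c(150, 800, 1950, 3300),
            spacing = c(1, 1, 1), origin = c(0, 0, 0))
  model <- calibrationModel()
  E <- as.vector(youngsModulus(assignMaterials(lv, model)))
  expect_true(all(diff(E) > 0))
  expect_true(all(E >= model@EMin & E <= model@ECortical))
  nu <- poissonRatio(assignMaterials(lv, model))
  expect_true(all(nu > 0 & nu < 0.5))
})
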