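test_that("element stiffness is symmetric, rank-18, and linear in E", {
  K <- elementStiffness(17e9, 0.3, c(0.5, 0.5, 1))
  expect_equal(max(abs(K - t(K))) / max(abs(K)), 0, tolerance = 1e-10)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_identical(sum(abs(ev) < 1e-8 * max(ev)), 6L)  # rigid-body modes
  expect_gte(min(ev), -1e-8 * max(ev))                 # PSD
  for (comp in 1:3) {
    u <- rep(as.numeric(1:3 == comp), 8)               # rigid translation
    expect_lte(max(abs(K %*% u)), 1e-8 * norm(K, "F"))
  }
  expect_equal(elementStiffness(2 * 17e9, 0.3, c(0.5, 0.5, 1)), 2 * K)
  expect_error(elementStiffness(-1, 0.3, c(1, 1, 1)), "E")
  expect_error(elementStiffness(1e9, 0.5, c(1, 1, 1)), "nu")
  expect_error(elementStiffness(1e9, 0.3, c(0, 1, 1)), "size")
})

test_that("mesh construction deduplicates shared nodes", {
  one <- buildMesh(assignMaterials(barLabels(c(1, 1, 1))))
  expect_identical(nodeCount(one), 8L)
  expect_identical(dofCount(one), 24L)
  two <- buildMesh(assignMaterials(barLabels(c(2, 1, 1))))
  expect_identical(nodeCount(two), 12L)
  expect_identical(dofCount(two), 36L)
  empty <- segmentStack(new("ImageStack", values = array(0, c(2, 2, 2)),
                            spacing = c(1, 1, 1), origin = c(0, 0, 0)))
  expect_error(buildMesh(assignMaterials(empty)), "non-background")
})

test_that("von Mises identities hold", {
  s <- 3.7e6
  expect_equal(vonMisesStress(c(s, 0, 0, 0, 0, 0)), s)       # uniaxial
  expect_equal(vonMisesStress(c(-s, 0, 0, 0, 0, 0)), s)
  expect_equal(vonMisesStress(c(s, s, s, 0, 0, 0)), 0)       # hydrostatic
  expect_equal(vonMisesStress(c(0, 0, 0, s, 0, 0)), sqrt(3) * s)  # shear
})

test_that("the solver reproduces the uniaxial closed form", {
  E <- 1e9
  mesh <- barMesh(c(4, 4, 8), E, 0)
  lc <- applyLoadCase(mesh, 80, weights = "area")
  sol <- solveDisplacements(mesh, lc)
  F <- 80 * 9.81; A <- 16e-6; L <- 8e-3
  tip <- mean(sol$u[lc@loadedNodes, 3])
  expect_equal(tip, -F * L / (E * A), tolerance = 0.005)
  # stress field is uniform uniaxial compression
  sf <- elementStress(mesh, sol$u)
  expect_equal(unname(sf@tensor[, 3]), rep(-F / A, elementCount(mesh)),
               tolerance = 1e-8)
  expect_equal(vonMises(sf), rep(F / A, elementCount(mesh)), tolerance = 1e-8)
  # reactions balance the applied load
  expect_equal(sol$reaction, -lc@totalForce, tolerance = 1e-6)
  # refinement sanity: halved voxels, same bar, same tip displacement
  fine <- barMesh(c(8, 8, 16), E, 0, spacing = c(0.5, 0.5, 0.5))
  lcF <- applyLoadCase(fine, 80, weights = "area")
  tipF <- mean(solveDisplacements(fine, lcF)$u[lcF@loadedNodes, 3])
  expect_equal(tipF, tip, tolerance = 0.005)
})

test_that("a two-material series bar matches the springs-in-series form", {
  mesh <- barMesh(c(4, 4, 8), 2e9, 0)
  mesh@E[mesh@voxel[, 3] > 4] <- 0.5e9
  lc <- applyLoadCase(mesh, 80, weights = "area")
  sol <- solveDisplacements(mesh, lc)
  F <- 80 * 9.81; A <- 16e-6
  iface <- which(abs(mesh@nodes[, 3] - 4) < 1e-9)
  expect_equal(mean(sol$u[iface, 3]), -F * 4e-3 / (2e9 * A), tolerance = 0.01)
  tip <- mean(sol$u[lc@loadedNodes, 3])
  expect_equal(tip, -F * 4e-3 / A * (1 / 2e9 + 1 / 0.5e9), tolerance = 0.01)
})

test_that("CG and direct solvers agree", {
  mesh <- barMesh(c(3, 3, 6), 5e9, 0.3)
  lc <- applyLoadCase(mesh, 80)
  ud <- solveDisplacements(mesh, lc, solver = "direct")$u
  uc <- solveDisplacements(mesh, lc, solver = "cg", tol = 1e-10)$u
  expect_equal(uc, ud, tolerance = 1e-6)
})

test_that("zero force gives zero displacement", {
  mesh <- barMesh(c(2, 2, 4), 1e9, 0.25)
  lc <- applyLoadCase(mesh, 80)
  lc@nodalForces[] <- 0
  lc@totalForce <- c(0, 0, 0)
  sol <- solveDisplacements(mesh, lc)
  expect_true(all(sol$u == 0))
})

test_that("the axial load case carries body weight along -z", {
  mesh <- barMesh(c(3, 3, 5), 1e9, 0.3)
  lc <- applyLoadCase(mesh, 80)
  expect_equal(sqrt(sum(lc@totalForce^2)), 784.8)
  expect_equal(lc@totalForce, c(0, 0, -784.8))
  expect_equal(colSums(lc@nodalForces), lc@totalForce)
  expect_error(applyLoadCase(mesh, 0), "mass")
  # fixed and loaded sets live on the bottom and top faces
  expect_true(all(mesh@nodes[lc@fixedNodes, 3] == 0))
  expect_true(all(mesh@nodes[lc@loadedNodes, 3] == 5))
})

test_that("stress scaling maps the reference maximum to 100", {
  mesh <- barMesh(c(2, 2, 4), 1e9, 0)
  lc <- applyLoadCase(mesh, 80, weights = "area")
  sf <- elementStress(mesh, solveDisplacements(mesh, lc)$u)
  own <- scaleStresses(sf)
  expect_equal(max(scaledStress(own)), 100)
  half <- scaleStresses(sf, 2 * max(vonMises(sf)))
  expect_equal(max(scaledStress(half)), 50)
  z <- sf; z@vonMises[1] <- 0
  expect_equal(scaleStresses(z, 1e6)@scaled[1], 0)
  expect_error(scaleStresses(sf, 0), "positive")
})

test_that("a disconnected load path raises a solver diagnostic", {
  lv <- barLabels(c(2, 2, 5))
  lv@labels[, , 3] <- 0L  # sever the bar
  expect_error({
    mesh <- buildMesh(assignMaterials(lv))
    lc <- applyLoadCase(mesh, 80)
    solveDisplacements(mesh, lc)
  }, class = "nonunionFE_solver_error")
})
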