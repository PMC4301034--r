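#' @include AllClasses.R configs.R
#' @importFrom Matrix sparseMatrix forceSymmetric Diagonal colSums norm solve crossprod
NULL

## Local node sign pattern of the trilinear hexahedron (VTK ordering):
## node a sits at natural coordinates (xi, eta, zeta) = .HEX_SIGNS[a, ].
.HEX_SIGNS <- matrix(c(
  -1, -1, -1,   1, -1, -1,   1,  1, -1,  -1,  1, -1,
  -1, -1,  1,   1, -1,  1,   1,  1,  1,  -1,  1,  1), ncol = 3, byrow = TRUE)

## 6x24 strain-displacement matrix at natural point (xi, eta, zeta) for a
## hexahedron of edge lengths h (mm). Engineering strain ordering:
## xx, yy, zz, xy, yz, zx.
.hexB <- function(xi, h) {
  B <- matrix(0, 6, 24)
  for (a in 1:8) {
    s <- .HEX_SIGNS[a, ]
    dN <- c(s[1] * (1 + s[2] * xi[2]) * (1 + s[3] * xi[3]),
            s[2] * (1 + s[1] * xi[1]) * (1 + s[3] * xi[3]),
            s[3] * (1 + s[1] * xi[1]) * (1 + s[2] * xi[2])) / 8 * (2 / h)
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- dN[1]
    B[2, c0 + 2] <- dN[2]
    B[3, c0 + 3] <- dN[3]
    B[4, c0 + 1] <- dN[2]; B[4, c0 + 2] <- dN[1]
    B[5, c0 + 2] <- dN[3]; B[5, c0 + 3] <- dN[2]
    B[6, c0 + 1] <- dN[3]; B[6, c0 + 3] <- dN[1]
  }
  B
}

## Material-independent stiffness parts for a voxel of size h (mm):
## K_e = lambda * Kl + mu * Km, integrated by 2x2x2 Gauss quadrature.
## Units: h in mm, so K carries a 1e-3 m/mm factor handled here -> with E in
## Pa and lengths converted to m, K is in N/m.
.hexKparts <- function(h) {
  hm <- h * 1e-3                       # mm -> m
  g <- 1 / sqrt(3)
  Kl <- matrix(0, 24, 24)
  Km <- matrix(0, 24, 24)
  m <- c(1, 1, 1, 0, 0, 0)
  Dm <- diag(c(2, 2, 2, 1, 1, 1))
  detJ <- prod(hm) / 8
  for (i in c(-g, g)) for (j in c(-g, g)) for (k in c(-g, g)) {
    B <- .hexB(c(i, j, k), hm)
    Kl <- Kl + detJ * crossprod(B, (m %o% m) %*% B)
    Km <- Km + detJ * crossprod(B, Dm %*% B)
  }
  list(Kl = Kl, Km = Km)
}

.lame <- function(E, nu) {
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)), mu = E / (2 * (1 + nu)))
}

#' Stiffness matrix of a trilinear voxel hexahedron
#'
#' Isotropic Hooke's law, 2x2x2 Gauss quadrature.  The result is symmetric,
#' positive semi-definite with a 6-dimensional nullspace (the rigid-body
#' modes), and linear in E.
#'
#' @param E Young's modulus, Pa.
#' @param nu Poisson ratio in (-1, 0.5).
#' @param voxelSize numeric(3), edge lengths in mm.
#' @return a 24 x 24 numeric matrix (N/m), DOF ordered (ux, uy, uz) per node.
#' @export
elementStiffness <- function(E, nu, voxelSize) {
  if (E <= 0) stop("E must be > 0")
  if (nu <= -1 || nu >= 0.5) stop("nu must lie in (-1, 0.5)")
  if (any(voxelSize <= 0)) stop("voxel sizes must be > 0")
  parts <- .hexKparts(voxelSize)
  lm <- .lame(E, nu)
  lm$lambda * parts$Kl + lm$mu * parts$Km
}

#' Build a hexahedral voxel mesh from a material map
#'
#' One trilinear hexahedron per non-background voxel; nodes shared between
#' adjacent voxels are deduplicated, so the system has 3 unknowns per unique
#' node.
#'
#' @param materials a \linkS4class{MaterialMap}.
#' @return a \linkS4class{VoxelMesh}.
#' @export
buildMesh <- function(materials) {
  lab <- materials@labels@labels
  d <- dim(lab)
  fg <- which(lab != 0L)
  if (!length(fg)) stop("material map has no non-background voxel to mesh")
  vi <- arrayInd(fg, d)
  nx1 <- d[1] + 1L; ny1 <- d[2] + 1L
  nid <- function(i, j, k) i + (j - 1L) * nx1 + (k - 1L) * (nx1 * ny1)
  i <- vi[, 1]; j <- vi[, 2]; k <- vi[, 3]
  conn <- cbind(nid(i,      j,      k),      nid(i + 1L, j,      k),
                nid(i + 1L, j + 1L, k),      nid(i,      j + 1L, k),
                nid(i,      j,      k + 1L), nid(i + 1L, j,      k + 1L),
                nid(i + 1L, j + 1L, k + 1L), nid(i,      j + 1L, k + 1L))
  usedNodes <- sort(unique(as.vector(conn)))
  renum <- integer(nid(d[1] + 1L, d[2] + 1L, d[3] + 1L))
  renum[usedNodes] <- seq_along(usedNodes)
  elems <- matrix(renum[conn], ncol = 8)
  gi <- arrayInd(usedNodes, d + 1L)
  sp <- materials@labels@spacing
  nodes <- sweep(sweep(gi - 1L, 2, sp, `*`), 2,
                 materials@labels@origin, `+`)
  new("VoxelMesh", nodes = nodes, elems = elems,
      E = as.numeric(materials@E[fg]), nu = as.numeric(materials@nu[fg]),
      implant = as.vector(lab[fg] == 4L),
      nonunion = as.vector(materials@labels@nonunion[fg]),
      voxel = vi, spacing = sp, dims = as.integer(d))
}

#' Axial load case for a long-bone mesh
#'
#' Applies the static equivalent of body weight in the cranio-caudal
#' direction: total force of magnitude \code{bodyMass * 9.81} N along -z,
#' distributed over the top-face nodes of the non-implant elements in the
#' highest occupied voxel slice.  All bottom-face nodes of elements in the
#' lowest occupied slice are fully fixed.
#'
#' @param mesh a \linkS4class{VoxelMesh}.
#' @param bodyMass body mass in kg (> 0).
#' @param direction numeric(3) load direction (normalized internally).
#' @param weights \code{"equal"} splits the force equally over the loaded
#'   nodes; \code{"area"} uses tributary face areas (consistent with a
#'   uniform traction).
#' @return a \linkS4class{LoadCase}.
#' @export
applyLoadCase <- function(mesh, bodyMass = 80, direction = c(0, 0, -1),
                          weights = c("equal", "area")) {
  if (bodyMass <= 0) stop("body mass must be > 0")
  weights <- match.arg(weights)
  kTop <- max(mesh@voxel[, 3])
  kBot <- min(mesh@voxel[, 3])
  topE <- which(mesh@voxel[, 3] == kTop & !mesh@implant)
  if (!length(topE))
    stop(errorCondition("no bone elements in the highest occupied slice",
                        class = c("nonunionFE_geometry_error", "error")))
  botE <- which(mesh@voxel[, 3] == kBot)
  loaded <- sort(unique(as.vector(mesh@elems[topE, 5:8])))  # top faces
  fixed <- sort(unique(as.vector(mesh@elems[botE, 1:4])))   # bottom faces
  loaded <- setdiff(loaded, fixed)
  dirUnit <- direction / sqrt(sum(direction^2))
  total <- bodyMass * 9.81 * dirUnit
  w <- if (weights == "equal") {
    rep(1 / length(loaded), length(loaded))
  } else {
    cnt <- table(factor(as.vector(mesh@elems[topE, 5:8]), levels = loaded))
    as.numeric(cnt) / sum(cnt)
  }
  forces <- outer(w, total)
  ## make the rows sum to the resultant exactly
  forces <- sweep(forces, 2, colSums(forces) - total, function(a, b) a - b / length(w))
  new("LoadCase", fixedNodes = as.integer(fixed),
      loadedNodes = as.integer(loaded), nodalForces = forces,
      totalForce = total)
}

## Assemble the global stiffness matrix (dgCMatrix, N/m).
.assembleK <- function(mesh) {
  parts <- .hexKparts(mesh@spacing)
  lm <- .lame(mesh@E, mesh@nu)
  m <- nrow(mesh@elems)
  ## per-element dof ids, columns (node1 x, node1 y, node1 z, node2 x, ...)
  idx24 <- matrix(0L, m, 24)
  for (a in 1:8) {
    base <- 3L * (mesh@elems[, a] - 1L)
    idx24[, 3 * a - 2] <- base + 1L
    idx24[, 3 * a - 1] <- base + 2L
    idx24[, 3 * a]     <- base + 3L
  }
  rowpat <- rep(1:24, times = 24)
  colpat <- rep(1:24, each = 24)
  vals <- outer(lm$lambda, as.vector(parts$Kl)) +
          outer(lm$mu, as.vector(parts$Km))
  ndof <- 3L * nrow(mesh@nodes)
  Matrix::sparseMatrix(i = as.vector(idx24[, rowpat]),
                       j = as.vector(idx24[, colpat]),
                       x = as.vector(vals), dims = c(ndof, ndof))
}

## Jacobi-preconditioned conjugate gradients on a sparse SPD system.
.pcg <- function(A, b, tol, maxIter) {
  Minv <- 1 / Matrix::diag(A)
  x <- numeric(length(b))
  r <- b
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b * b))
  for (it in seq_len(maxIter)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r * r)) <= tol * bnorm)
      return(list(x = x, iterations = it,
                  residual = sqrt(sum(r * r)) / bnorm))
    z <- Minv * r
    rzNew <- sum(r * z)
    p <- z + (rzNew / rz) * p
    rz <- rzNew
  }
  stop(errorCondition(sprintf(
    "conjugate gradients did not converge in %d iterations (residual %.3e)",
    maxIter, sqrt(sum(r * r)) / bnorm),
    class = c("nonunionFE_solver_error", "error")))
}

#' Solve the linear-elastic equilibrium of a voxel mesh
#'
#' Assembles the global sparse stiffness matrix, eliminates the fixed DOFs,
#' and solves for the free displacements.  The default \code{"auto"} solver
#' uses a sparse Cholesky factorization up to 200,000 DOF and
#' Jacobi-preconditioned conjugate gradients beyond; both are checked against
#' the relative residual tolerance, and the reactions at the fixed nodes are
#' verified to balance the applied load.
#'
#' @param mesh a \linkS4class{VoxelMesh}.
#' @param load a \linkS4class{LoadCase}.
#' @param tol relative residual tolerance (default 1e-8).
#' @param solver \code{"auto"}, \code{"direct"} or \code{"cg"}.
#' @param maxIter CG iteration cap (default 20000).
#' @return a list with \code{u} (node displacement matrix, m), \code{residual}
#'   (relative), \code{reaction} (force resultant at the fixed nodes, N) and
#'   \code{solver}.
#' @export
solveDisplacements <- function(mesh, load, tol = 1e-8,
                               solver = c("auto", "direct", "cg"),
                               maxIter = 20000L) {
  solver <- match.arg(solver)
  ndof <- 3L * nrow(mesh@nodes)
  K <- .assembleK(mesh)
  f <- numeric(ndof)
  ld <- 3L * (load@loadedNodes - 1L)
  f[ld + 1L] <- f[ld + 1L] + load@nodalForces[, 1]
  f[ld + 2L] <- f[ld + 2L] + load@nodalForces[, 2]
  f[ld + 3L] <- f[ld + 3L] + load@nodalForces[, 3]
  fixedDof <- as.vector(outer(1:3, 3L * (load@fixedNodes - 1L), `+`))
  free <- setdiff(seq_len(ndof), fixedDof)
  Kff <- K[free, free, drop = FALSE]
  ff <- f[free]
  if (solver == "auto")
    solver <- if (length(free) <= 200000L) "direct" else "cg"
  if (all(ff == 0)) {
    uf <- numeric(length(free))
    res <- 0
  } else if (solver == "direct") {
    uf <- tryCatch(
      as.numeric(Matrix::solve(Matrix::forceSymmetric(Kff), ff)),
      error = function(e) stop(errorCondition(paste(
        "direct solve failed (singular system: is the load path connected",
        "between fixed and loaded nodes?):", conditionMessage(e)),
        class = c("nonunionFE_solver_error", "error"))))
    res <- sqrt(sum((as.numeric(Kff %*% uf) - ff)^2)) / sqrt(sum(ff^2))
    if (!is.finite(res) || res > max(tol, 1e-6))
      stop(errorCondition(sprintf(
        "direct solve residual %.3e exceeds tolerance (ill-conditioned or disconnected system)",
        res), class = c("nonunionFE_solver_error", "error")))
  } else {
    cg <- .pcg(Kff, ff, tol, maxIter)
    uf <- cg$x
    res <- cg$residual
  }
  u <- matrix(0, nrow(mesh@nodes), 3)
  u[cbind((free - 1L) %/% 3L + 1L, (free - 1L) %% 3L + 1L)] <- uf
  uFull <- numeric(ndof)
  uFull[free] <- uf
  rFixed <- as.numeric(K[fixedDof, , drop = FALSE] %*% uFull)
  reaction <- c(sum(rFixed[seq(1, length(rFixed), 3)]),
                sum(rFixed[seq(2, length(rFixed), 3)]),
                sum(rFixed[seq(3, length(rFixed), 3)]))
  list(u = u, residual = res, reaction = reaction, solver = solver)
}

#' Per-element stress and von Mises equivalent
#'
#' Evaluates the strain-displacement operator at the element centroid,
#' applies Hooke's law, and reduces the stress tensor to the von Mises
#' scalar
#' \deqn{\sigma_{vm} = \sqrt{\tfrac12[(\sigma_{11}-\sigma_{22})^2 +
#'   (\sigma_{22}-\sigma_{33})^2 + (\sigma_{33}-\sigma_{11})^2] +
#'   3(\sigma_{12}^2+\sigma_{23}^2+\sigma_{31}^2)}.}
#'
#' @param mesh a \linkS4class{VoxelMesh}.
#' @param u node displacement matrix (nodes x 3, m), from
#'   \code{\link{solveDisplacements}}.
#' @return a \linkS4class{StressField} (unscaled; see
#'   \code{\link{scaleStresses}}).
#' @export
elementStress <- function(mesh, u) {
  if (!is.matrix(u) || nrow(u) != nrow(mesh@nodes) || ncol(u) != 3L)
    stop("displacement field shape does not match the mesh")
  B0 <- .hexB(c(0, 0, 0), mesh@spacing * 1e-3)
  m <- nrow(mesh@elems)
  Ue <- matrix(0, m, 24)
  for (a in 1:8) {
    Ue[, 3 * a - 2] <- u[mesh@elems[, a], 1]
    Ue[, 3 * a - 1] <- u[mesh@elems[, a], 2]
    Ue[, 3 * a]     <- u[mesh@elems[, a], 3]
  }
  eps <- Ue %*% t(B0)                 # m x 6 engineering strain
  lm <- .lame(mesh@E, mesh@nu)
  tr <- rowSums(eps[, 1:3, drop = FALSE])
  sig <- cbind(lm$lambda * tr + 2 * lm$mu * eps[, 1],
               lm$lambda * tr + 2 * lm$mu * eps[, 2],
               lm$lambda * tr + 2 * lm$mu * eps[, 3],
               lm$mu * eps[, 4], lm$mu * eps[, 5], lm$mu * eps[, 6])
  colnames(sig) <- c("xx", "yy", "zz", "xy", "yz", "zx")
  new("StressField", tensor = sig, vonMises = vonMisesStress(sig),
      scaled = rep(NA_real_, m), referenceMax = NA_real_)
}

#' Von Mises equivalent stress from tensor components
#'
#' @param sig numeric matrix (m x 6) with columns xx, yy, zz, xy, yz, zx, or
#'   a length-6 vector.
#' @return numeric vector of von Mises stresses.
#' @export
vonMisesStress <- function(sig) {
  if (is.null(dim(sig))) sig <- matrix(sig, nrow = 1)
  sqrt(0.5 * ((sig[, 1] - sig[, 2])^2 + (sig[, 2] - sig[, 3])^2 +
              (sig[, 3] - sig[, 1])^2) +
       3 * (sig[, 4]^2 + sig[, 5]^2 + sig[, 6]^2))
}

#' Scale a stress field to a reference maximum
#'
#' The reference maximum (the worst-case scenario's global maximum von Mises
#' stress) maps to 100; all other stresses scale linearly.
#'
#' @param field a \linkS4class{StressField}.
#' @param referenceMax reference stress in Pa (> 0); default: the field's own
#'   maximum, which then maps exactly to 100.
#' @return the field with \code{scaled} and \code{referenceMax} set.
#' @export
scaleStresses <- function(field, referenceMax = max(vonMises(field))) {
  if (!is.finite(referenceMax) || referenceMax <= 0)
    stop("referenceMax must be a positive stress in Pa")
  field@scaled <- 100 * field@vonMises / referenceMax
  field@referenceMax <- referenceMax
  field
}
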