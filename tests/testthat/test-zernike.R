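# Zernike basis construction and deformation-field algebra.

test_that("index set enumerates exactly the admissible (l, n, m) triples", {
  idx <- zernikeIndexSet(2, 2)
  # brute-force enumeration
  want <- list()
  for (l in 0:2) for (n in 0:2) if (n >= l && (n - l) %% 2 == 0)
    for (m in -l:l) want[[length(want) + 1]] <- c(l, n, m)
  expect_equal(nrow(idx), length(want))  # 1 + 3 + 5 + 1 = 10
  expect_equal(nrow(idx), 10L)
  got <- unname(split(as.matrix(idx), seq_len(nrow(idx))))
  expect_setequal(lapply(got, as.numeric), want)
  expect_error(zernikeIndexSet(3, 2), "lMax")
})

test_that("radial polynomials match their closed forms and normalization", {
  rho <- seq(0, 1, by = 0.05)
  expect_equal(zernikeRadial(0, 0, rho), rep(1, length(rho)))
  expect_equal(zernikeRadial(1, 1, rho), rho)
  # P1^(0, 1/2)(2 rho^2 - 1) = 2.5 rho^2 - 1.5, max |.| on [0,1] is 1.5
  expect_equal(zernikeRadial(2, 0, rho), (2.5 * rho^2 - 1.5) / 1.5)
  for (nl in list(c(2, 2), c(3, 1), c(4, 0))) {
    r <- zernikeRadial(nl[1], nl[2], seq(0, 1, length.out = 2001))
    expect_equal(max(abs(r)), 1, tolerance = 1e-6)
  }
})

test_that("degree-1 real spherical harmonics match the Cartesian forms", {
  set.seed(4)
  theta <- stats::runif(20, 0, pi)
  phi <- stats::runif(20, -pi, pi)
  y <- realSphericalHarmonics(1, theta, phi)
  c0 <- sqrt(3 / (4 * pi))
  expect_equal(y[, 1], c0 * sin(theta) * sin(phi))  # m = -1
  expect_equal(y[, 2], c0 * cos(theta))             # m = 0
  expect_equal(y[, 3], c0 * sin(theta) * cos(phi))  # m = +1
})

test_that("basis has constant degree-zero column and zero rows outside support", {
  set.seed(5)
  pts <- rbind(matrix(stats::rnorm(60, sd = 2), 20, 3), c(12, 0, 0))
  b <- buildBasis(pts, c(0, 0, 0), radius = 6, lMax = 2, nMax = 2)
  expect_equal(basisSize(b), 10L)
  z <- basisMatrix(b)
  inside <- sqrt(rowSums(pts^2)) <= 6
  expect_equal(diff(range(z[inside, 1])), 0)
  expect_true(all(z[!inside, ] == 0))
  expect_error(buildBasis(pts, c(0, 0, 0), -1, 2, 2), "radius")
  expect_error(buildBasis(pts, c(0, 0, 0), 6, 3, 2), "lMax")
})

test_that("basis columns are near-orthogonal under ball quadrature", {
  ax <- seq(-1, 1, length.out = 32)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  b <- buildBasis(g, c(0, 0, 0), 1, 2, 2)
  z <- basisMatrix(b)
  gram <- crossprod(z)
  ndot <- gram / sqrt(tcrossprod(diag(gram)))
  expect_lt(max(abs(ndot[upper.tri(ndot)])), 0.05)
})

test_that("evaluateField matches a brute-force per-point triple-loop sum", {
  set.seed(6)
  pts <- matrix(stats::rnorm(15, sd = 2), 5, 3)
  b <- buildBasis(pts, c(0, 0, 0), 6, 2, 2)
  A <- matrix(stats::rnorm(30), 3, 10)
  co <- ZernikeCoefficients(A, 2, 2, 6)
  f <- evaluateField(b, co)
  idx <- basisIndexSet(b)
  for (i in 1:5) {
    r <- sqrt(sum(pts[i, ]^2))
    th <- acos(pts[i, 3] / r)
    ph <- atan2(pts[i, 2], pts[i, 1])
    u <- c(0, 0, 0)
    for (col in seq_len(nrow(idx))) {
      l <- idx$l[col]; n <- idx$n[col]; m <- idx$m[col]
      zval <- zernikeRadial(n, l, r / 6) *
        realSphericalHarmonics(l, th, ph)[1, m + l + 1]
      u <- u + zval * A[, col]
    }
    expect_equal(displacements(f)[i, ], u, tolerance = 1e-12)
  }
})

test_that("field evaluation is linear and degree-zero gives pure translation", {
  set.seed(7)
  pts <- matrix(stats::rnorm(90, sd = 2), 30, 3)
  b <- buildBasis(pts, c(0, 0, 0), 8, 2, 2)
  a1 <- makeRandomCoeffs(2, 2, 8, seed = 1)
  a2 <- makeRandomCoeffs(2, 2, 8, seed = 2)
  sum12 <- ZernikeCoefficients(coefArray(a1) + coefArray(a2), 2, 2, 8)
  expect_equal(displacements(evaluateField(b, sum12)),
               displacements(evaluateField(b, a1)) +
                 displacements(evaluateField(b, a2)),
               tolerance = 1e-12)
  zero <- ZernikeCoefficients(matrix(0, 3, 10), 2, 2, 8)
  expect_true(all(displacements(evaluateField(b, zero)) == 0))
  # (0,0,0) column only: uniform translation proportional to (cx, cy, cz)
  A <- matrix(0, 3, 10)
  A[, 1] <- c(2, -1, 0.5)
  u <- displacements(evaluateField(b, ZernikeCoefficients(A, 2, 2, 8)))
  expect_equal(u, matrix(c(2, -1, 0.5) / sqrt(4 * pi), 30, 3, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("coefficient fitting inverts evaluation and matches normal equations", {
  set.seed(8)
  pts <- matrix(stats::rnorm(120, sd = 2.5), 40, 3)
  b <- buildBasis(pts, c(0, 0, 0), 8, 2, 2)
  aTrue <- makeRandomCoeffs(2, 2, 8, seed = 3)
  f <- evaluateField(b, aTrue)
  fit <- fitCoefficients(f, b)
  expect_equal(coefArray(fit), coefArray(aTrue), tolerance = 1e-8)
  # zero field -> zero coefficients
  z <- fitCoefficients(DeformationField(matrix(0, 40, 3), pts), b)
  expect_equal(max(abs(coefArray(z))), 0, tolerance = 1e-12)
  # noisy field: dense normal-equations oracle per component
  d <- displacements(f) + matrix(stats::rnorm(120, sd = 0.2), 40, 3)
  fit2 <- fitCoefficients(DeformationField(d, pts), b)
  expect_equal(t(coefArray(fit2)), normalEquationsSolve(basisMatrix(b), d),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("fit-evaluate composition is an orthogonal projection", {
  set.seed(9)
  pts <- matrix(stats::rnorm(150, sd = 3), 50, 3)
  b <- buildBasis(pts, c(0, 0, 0), 9, 2, 2)
  d <- matrix(stats::rnorm(150), 50, 3)
  fit1 <- fitCoefficients(DeformationField(d, pts), b)
  proj1 <- displacements(evaluateField(b, fit1))
  fit2 <- fitCoefficients(DeformationField(proj1, pts), b)
  proj2 <- displacements(evaluateField(b, fit2))
  expect_equal(proj2, proj1, tolerance = 1e-10)
  resid <- d - proj1
  expect_lt(max(abs(crossprod(basisMatrix(b), resid))),
            1e-8 * sqrt(sum(d^2)))
})

test_that("rank-deficient fits warn and return the minimum-norm solution", {
  pts <- matrix(stats::rnorm(12), 4, 3)  # P = 4 < B = 10
  b <- buildBasis(pts, c(0, 0, 0), 6, 2, 2)
  d <- matrix(stats::rnorm(12), 4, 3)
  expect_warning(fit <- fitCoefficients(DeformationField(d, pts), b),
                 "rank deficient")
  # reproduces the field (consistent underdetermined system)
  expect_equal(basisMatrix(b) %*% t(coefArray(fit)), d,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("fields move atoms additively and invert exactly", {
  atoms <- connectedBlob(15)
  pts <- atomCoords(atoms)
  u <- matrix(stats::rnorm(45), 15, 3)
  f <- DeformationField(u, pts)
  moved <- applyFieldToAtoms(atoms, f)
  expect_equal(atomCoords(moved), pts + u, ignore_attr = TRUE)
  expect_identical(atomLabels(moved), atomLabels(atoms))
  back <- applyFieldToAtoms(moved, DeformationField(-u, atomCoords(moved)))
  expect_equal(atomCoords(back), pts, tolerance = 1e-12, ignore_attr = TRUE)
  uniform <- applyFieldToAtoms(atoms,
    DeformationField(matrix(rep(c(1, 0, 0), each = 15), 15), pts))
  expect_equal(atomCoords(uniform)[, 1], pts[, 1] + 1)
  expect_error(applyFieldToAtoms(atoms, DeformationField(u[1:4, ], pts[1:4, ])),
               "atom count")
})

test_that("map warping is identity at zero coefficients and conserves mass", {
  atoms <- connectedBlob(12)
  map <- makeMapFromAtoms(atoms, voxelSize = 1.5, sigma = 2, box = 24)
  ctr <- colMeans(atomCoords(atoms))
  zero <- ZernikeCoefficients(matrix(0, 3, 10), 2, 2, radius = 40,
                              center = ctr)
  expect_identical(mapGrid(applyCoeffsToMap(map, zero)), mapGrid(map))
  # interior motion: small rotation-like field keeps mass inside the box
  co <- makeRandomCoeffs(2, 2, radius = 40, center = ctr, magnitude = 0.8,
                         seed = 5)
  warped <- applyCoeffsToMap(map, co)
  expect_lte(sum(mapGrid(warped)), sum(mapGrid(map)) + 1e-9)
  expect_equal(sum(mapGrid(warped)), sum(mapGrid(map)),
               tolerance = 1e-3)
})

test_that("one-voxel translation warp equals the integer shift oracle", {
  atoms <- connectedBlob(12)
  map <- makeMapFromAtoms(atoms, voxelSize = 1.5, sigma = 2, box = 24)
  ctr <- colMeans(atomCoords(atoms))
  A <- matrix(0, 3, 10)
  A[1, 1] <- 1.5 * sqrt(4 * pi)  # degree-0 harmonic is 1/sqrt(4 pi)
  co <- ZernikeCoefficients(A, 2, 2, radius = 60, center = ctr)
  warped <- applyCoeffsToMap(map, co)
  g0 <- mapGrid(map)
  g1 <- mapGrid(warped)
  expect_equal(g1[2:24, , ], g0[1:23, , ], tolerance = 1e-12)
  expect_error(applyCoeffsToMap(map, co,
    mask = VoxelMap(array(1, dim = c(8, 8, 8)), 1.5)), "geometry|mask")
})
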