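checkBasisCompatible <- function(basis, coeffs) {
  if (basis@lMax != coeffs@lMax || basis@nMax != coeffs@nMax)
    stop("basis and coefficients disagree on degree bounds (lMax/nMax)")
  if (!isTRUE(all.equal(basis@radius, coeffs@radius)) ||
      !isTRUE(all.equal(basis@center, coeffs@center)))
    stop("basis and coefficients disagree on support-ball geometry")
  invisible(TRUE)
}

#' Evaluate a Zernike deformation field at the basis points
#'
#' The displacement at point i is the linear combination
#' sum over (l,n,m) of Z_(l,n,m)(r_i) * alpha_(l,n,m), i.e. Z A^T, one
#' Cartesian component per coefficient row. The map is linear in the
#' coefficients.
#'
#' @param basis a [ZernikeBasis-class].
#' @param coeffs a [ZernikeCoefficients-class] sharing the basis metadata.
#' @return a [DeformationField-class] bound to the basis points.
#' @export
evaluateField <- function(basis, coeffs) {
  checkBasisCompatible(basis, coeffs)
  DeformationField(basis@Z %*% t(coeffs@A), basis@points)
}

#' Fit Zernike coefficients to a displacement field
#'
#' Solves, independently for each Cartesian component, the (optionally
#' ridge-regularized) least-squares problem min ||Z a - d||^2 +
#' lambda ||a||^2 over the basis columns. With lambda = 0 and a
#' full-column-rank basis this is the ordinary normal-equations solution;
#' a rank-deficient basis yields the minimum-norm solution with a warning.
#'
#' @param field a [DeformationField-class] bound to the basis points.
#' @param basis a [ZernikeBasis-class].
#' @param lambda ridge penalty, >= 0 (default 0).
#' @param referenceId reference label recorded on the result.
#' @return a [ZernikeCoefficients-class].
#' @export
fitCoefficients <- function(field, basis, lambda = 0, referenceId = "reference") {
  if (lambda < 0) stop("regularization must be non-negative")
  if (nrow(field@displacements) != nrow(basis@Z))
    stop("field and basis must share the same point count")
  a <- lsSolve(basis@Z, field@displacements, lambda = lambda)
  ZernikeCoefficients(t(a), lMax = basis@lMax, nMax = basis@nMax,
                      radius = basis@radius, center = basis@center,
                      referenceId = referenceId)
}

#' Displace an atom set by a deformation field
#'
#' @param atoms an [AtomSet-class].
#' @param field a [DeformationField-class] bound to the atom coordinates.
#' @return a new [AtomSet-class] with coords + displacements; labels and
#'   selection unchanged.
#' @export
applyFieldToAtoms <- function(atoms, field) {
  if (nrow(field@displacements) != atomCount(atoms))
    stop("field and atom set must share the same atom count")
  new("AtomSet", coords = atoms@coords + field@displacements,
      labels = atoms@labels, selection = atoms@selection)
}

#' Warp a density map with a Zernike deformation field
#'
#' Forward-splat warping: the density of each source voxel moves with the
#' field and is deposited with trilinear weights at its displaced position.
#' Total density is conserved up to mass splatted past the box boundary,
#' and a zero coefficient set reproduces the input exactly. The field is
#' evaluated at voxels selected by `mask` (values > 0.5) when given,
#' otherwise at all voxels inside the support ball of the coefficients;
#' voxels outside carry zero displacement.
#'
#' @param map a [VoxelMap-class].
#' @param coeffs a [ZernikeCoefficients-class]; its center/radius define the
#'   support ball in the map's coordinate frame.
#' @param mask optional [VoxelMap-class] of the same geometry marking the
#'   valid positions (> 0.5 = inside).
#' @return a [VoxelMap-class] with the warped grid.
#' @export
applyCoeffsToMap <- function(map, coeffs, mask = NULL) {
  if (!is.null(mask) && !sameMapGeometry(map, mask))
    stop("map and mask must share grid dimensions, voxel size and origin")
  d <- dim(map@grid)
  n <- prod(d)
  xyz <- voxelCoordinates(map)
  if (is.null(mask)) {
    valid <- sqrt(rowSums(sweep(xyz, 2, coeffs@center)^2)) <= coeffs@radius
  } else {
    valid <- as.vector(mask@grid) > 0.5
  }

  dens <- as.vector(map@grid)
  out <- numeric(n)
  # fractional 0-based voxel index of each voxel's destination
  ix <- rep(seq_len(d[1]) - 1, times = d[2] * d[3])
  iy <- rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3])
  iz <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  fx <- as.numeric(ix)
  fy <- as.numeric(iy)
  fz <- as.numeric(iz)
  if (any(valid)) {
    basis <- buildBasis(xyz[valid, , drop = FALSE], coeffs@center,
                        coeffs@radius, coeffs@lMax, coeffs@nMax)
    disp <- basis@Z %*% t(coeffs@A) / map@voxelSize
    fx[valid] <- fx[valid] + disp[, 1]
    fy[valid] <- fy[valid] + disp[, 2]
    fz[valid] <- fz[valid] + disp[, 3]
  }

  x0 <- floor(fx); y0 <- floor(fy); z0 <- floor(fz)
  rx <- fx - x0; ry <- fy - y0; rz <- fz - z0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    jx <- x0 + cx; jy <- y0 + cy; jz <- z0 + cz
    w <- (if (cx == 1) rx else 1 - rx) *
         (if (cy == 1) ry else 1 - ry) *
         (if (cz == 1) rz else 1 - rz)
    ok <- jx >= 0 & jx < d[1] & jy >= 0 & jy < d[2] & jz >= 0 & jz < d[3] & w > 0
    if (any(ok)) {
      lin <- jx[ok] + d[1] * (jy[ok] + d[2] * jz[ok]) + 1
      out <- out + accumulateAt(w[ok] * dens[ok], lin, n)
    }
  }
  VoxelMap(array(out, dim = d), map@voxelSize, map@origin)
}
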