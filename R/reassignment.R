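#' Reassign Zernike coefficients to a new reference conformation
#'
#' Given coefficients A_RX (reference R to conformation X) and A_RR' (R to
#' the new reference R'), the field R' must apply to reach X is the
#' difference of the two fields. It is evaluated at the old reference's
#' valid positions (the points of `basisOld`), and the difference field is
#' re-fitted onto the new reference's basis `basisNew` by least squares.
#' When both bases are the identical matrix (same mask) the fit is exact
#' and the result reduces to the coefficient difference A_RX - A_RR'.
#'
#' @param coeffsRX [ZernikeCoefficients-class], reference R to state X.
#' @param coeffsRRp [ZernikeCoefficients-class], reference R to the new
#'   reference R'.
#' @param basisOld [ZernikeBasis-class] at the valid positions of R.
#' @param basisNew [ZernikeBasis-class] at the valid positions of R'
#'   (defaults to `basisOld`: the shared-mask case).
#' @param lambda ridge penalty for the re-fit, >= 0.
#' @param referenceId label for the new reference recorded on the result.
#' @return [ZernikeCoefficients-class] expressing R' -> X.
#' @export
reassignReference <- function(coeffsRX, coeffsRRp, basisOld,
                              basisNew = basisOld, lambda = 0,
                              referenceId = "reassigned") {
  if (coeffsRX@lMax != coeffsRRp@lMax || coeffsRX@nMax != coeffsRRp@nMax)
    stop("coefficient sets disagree on degree bounds (lMax/nMax)")
  checkBasisCompatible(basisOld, coeffsRX)
  if (identical(basisOld@Z, basisNew@Z) &&
      isTRUE(all.equal(basisOld@points, basisNew@points))) {
    # shared mask: the least-squares re-fit is exact and reduces to the
    # plain coefficient difference
    return(ZernikeCoefficients(coeffsRX@A - coeffsRRp@A,
                               lMax = coeffsRX@lMax, nMax = coeffsRX@nMax,
                               radius = coeffsRX@radius, center = coeffsRX@center,
                               referenceId = referenceId))
  }
  diffField <- DeformationField(
    basisOld@Z %*% t(coeffsRX@A) - basisOld@Z %*% t(coeffsRRp@A),
    basisOld@points
  )
  # the difference field lives on the old reference's points; fit it with
  # the new basis evaluated at those same positions
  basisNewAtOld <- buildBasis(basisOld@points, basisNew@center,
                              basisNew@radius, basisNew@lMax, basisNew@nMax)
  fitCoefficients(diffField, basisNewAtOld, lambda = lambda,
                  referenceId = referenceId)
}

#' Reassign every row of a coefficient table to a new reference
#'
#' Row-wise [reassignReference()]: particle ids, Euler angles and shifts
#' are untouched, so no particle is lost; only the coefficient vectors and
#' the header reference change.
#'
#' @param table a [CoefficientTable-class].
#' @param coeffsRRp shift coefficients R -> R' shared by all rows.
#' @param basisOld,basisNew,lambda as in [reassignReference()].
#' @param referenceId new reference label for the table header.
#' @return a [CoefficientTable-class] with the same rows, reassigned.
#' @export
reassignTable <- function(table, coeffsRRp, basisOld, basisNew = basisOld,
                          lambda = 0, referenceId = "reassigned") {
  m <- particleCount(table)
  out <- matrix(0, m, ncol(table@coeffs))
  for (i in seq_len(m)) {
    ri <- reassignReference(tableRowCoefficients(table, i), coeffsRRp,
                            basisOld, basisNew, lambda = lambda,
                            referenceId = referenceId)
    out[i, ] <- as.vector(t(ri@A))
  }
  new("CoefficientTable", particles = table@particles, coeffs = out,
      lMax = table@lMax, nMax = table@nMax, radius = basisNew@radius,
      center = basisNew@center, referenceId = referenceId)
}

#' Focus a coefficient landscape on a masked region
#'
#' For every table row, the full-model deformation field is evaluated at
#' the points selected by the mask only, and coefficients are re-fitted
#' there. By default the basis is rebuilt with the masked region's bounding
#' sphere as support (recentered and rescaled), maximizing basis resolution
#' inside the region; with `recenter = FALSE` the original support is kept
#' and only the evaluation points are restricted. The focused landscape
#' reflects only motion inside the region.
#'
#' @param table a [CoefficientTable-class].
#' @param basisFull [ZernikeBasis-class] of the full model (points = all
#'   valid positions).
#' @param focusMask logical vector over the basis points, or a
#'   [VoxelMap-class] mask (> 0.5 = inside) sampled at the basis points.
#' @param recenter rebuild the basis on the masked region's bounding
#'   sphere (default TRUE).
#' @param lambda ridge penalty for the re-fit.
#' @return a [CoefficientTable-class] over the focused basis.
#' @export
focusLandscape <- function(table, basisFull, focusMask, recenter = TRUE,
                           lambda = 0) {
  if (is(focusMask, "VoxelMap")) {
    frac <- sweep(basisFull@points, 2, focusMask@origin) / focusMask@voxelSize
    focusMask <- trilinearSample(focusMask@grid, frac) > 0.5
  }
  focusMask <- as.logical(focusMask)
  if (length(focusMask) != nrow(basisFull@points))
    stop("focus mask length must equal the basis point count")
  b <- basisSize(basisFull)
  if (sum(focusMask) < b)
    stop(sprintf("mask selects %d points but the basis has %d functions; lower lMax/nMax or enlarge the mask",
                 sum(focusMask), b))
  pts <- basisFull@points[focusMask, , drop = FALSE]
  if (recenter) {
    center <- (apply(pts, 2, min) + apply(pts, 2, max)) / 2
    radius <- max(sqrt(rowSums(sweep(pts, 2, center)^2)))
    if (radius == 0) stop("masked region is degenerate (single point)")
    # small margin keeps boundary points strictly inside the support
    radius <- radius * 1.05
  } else {
    center <- basisFull@center
    radius <- basisFull@radius
  }
  basisFocus <- buildBasis(pts, center, radius, basisFull@lMax, basisFull@nMax)
  zMasked <- basisFull@Z[focusMask, , drop = FALSE]
  m <- particleCount(table)
  out <- matrix(0, m, 3L * b)
  for (i in seq_len(m)) {
    a <- tableRowCoefficients(table, i)@A
    field <- DeformationField(zMasked %*% t(a), pts)
    fit <- fitCoefficients(field, basisFocus, lambda = lambda,
                           referenceId = table@referenceId)
    out[i, ] <- as.vector(t(fit@A))
  }
  new("CoefficientTable", particles = table@particles, coeffs = out,
      lMax = table@lMax, nMax = table@nMax, radius = radius,
      center = center, referenceId = paste0(table@referenceId, "_focused"))
}
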