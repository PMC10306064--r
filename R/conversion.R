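#' Stack a deformation field into a 3P vector
#'
#' Atom-major order: atom i contributes (dx_i, dy_i, dz_i) consecutively —
#' the same layout as the ANM Hessian's 3x3 block rows and ANM/PCA mode
#' columns.
#'
#' @param field a [DeformationField-class] or P x 3 matrix.
#' @return numeric vector of length 3P.
#' @export
stackField <- function(field) {
  d <- if (is(field, "DeformationField")) field@displacements else as.matrix(field)
  as.vector(t(d))
}

#' Unstack a 3P vector into a P x 3 displacement matrix
#'
#' Inverse of [stackField()].
#'
#' @param v numeric vector of length 3P (atom-major).
#' @param points optional P x 3 point set to bind the result to; when given
#'   a [DeformationField-class] is returned instead of a matrix.
#' @return P x 3 matrix, or a [DeformationField-class] when `points` given.
#' @export
unstackField <- function(v, points = NULL) {
  if (length(v) %% 3L != 0L) stop("vector length must be a multiple of 3")
  d <- matrix(v, ncol = 3, byrow = TRUE)
  if (is.null(points)) d else DeformationField(d, points)
}

#' Convert Zernike coefficients to normal-mode amplitudes
#'
#' Evaluates the Zernike deformation field at the mode atoms, stacks it
#' atom-major into a 3P vector d, and solves the least-squares problem
#' g = argmin ||U g - d||^2 over the mode matrix U. For orthonormal U this
#' reduces to g = U^T d. The residual d - U g (orthogonal to the mode span)
#' is reported through its norm as a diagnostic.
#'
#' @param coeffs a [ZernikeCoefficients-class].
#' @param basis a [ZernikeBasis-class] evaluated at the mode atom positions.
#' @param modes a [NormalModeSet-class] of kind ANM or PCA (3P rows).
#' @return a [ModeAmplitudes-class].
#' @export
zernikeToNma <- function(coeffs, basis, modes) {
  if (modes@kind == "GNM")
    stop("conversion requires 3P-dimensional modes (ANM or PCA)")
  if (modes@nAtoms != nrow(basis@points))
    stop("basis points and mode atom set must agree")
  kk <- ncol(modes@modes)
  if (kk > 3L * modes@nAtoms) stop("more modes than degrees of freedom")
  d <- stackField(evaluateField(basis, coeffs))
  g <- as.numeric(lsSolve(modes@modes, d))
  res <- d - as.numeric(modes@modes %*% g)
  new("ModeAmplitudes", g = g, modesRef = modes@kind,
      residualNorm = sqrt(sum(res^2)))
}

#' Convert normal-mode amplitudes to Zernike coefficients
#'
#' Synthesizes the displacement field d = U g at the mode atoms, reshapes
#' it to P x 3 and fits Zernike coefficients by per-component least
#' squares (see [fitCoefficients()]).
#'
#' @param g a [ModeAmplitudes-class] or numeric amplitude vector.
#' @param modes a [NormalModeSet-class] of kind ANM or PCA.
#' @param basis a [ZernikeBasis-class] at the mode atom positions.
#' @param lambda ridge penalty passed to [fitCoefficients()].
#' @return a [ZernikeCoefficients-class].
#' @export
nmaToZernike <- function(g, modes, basis, lambda = 0) {
  if (modes@kind == "GNM")
    stop("conversion requires 3P-dimensional modes (ANM or PCA)")
  if (is(g, "ModeAmplitudes")) g <- g@g
  if (length(g) != ncol(modes@modes))
    stop("amplitude count must match the number of modes")
  if (modes@nAtoms != nrow(basis@points))
    stop("basis points and mode atom set must agree")
  field <- unstackField(as.numeric(modes@modes %*% g), basis@points)
  fitCoefficients(field, basis, lambda = lambda)
}
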