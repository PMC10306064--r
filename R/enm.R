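#' Anisotropic network model Hessian
#'
#' Uniform-spring ANM super-element Hessian: for each pair of atoms within
#' the cutoff, the off-diagonal 3x3 block is -gamma * (dr dr^T) / |dr|^2
#' and diagonal blocks are minus the sum of the off-diagonal blocks of
#' their block-row, so each block-row sums to zero.
#'
#' @param atoms an [AtomSet-class] (typically a C-alpha selection).
#' @param cutoff contact cutoff distance (Angstrom); default 15.
#' @param gamma uniform spring constant; default 1 (mode shapes are
#'   independent of its value).
#' @return symmetric 3P x 3P numeric matrix.
#' @export
anmHessian <- function(atoms, cutoff = 15, gamma = 1) {
  xyz <- atomCoords(atoms)
  p <- nrow(xyz)
  if (p < 2L) stop("at least two atoms required")
  if (cutoff <= 0) stop("cutoff must be positive")
  h <- matrix(0, 3 * p, 3 * p)
  dmat <- as.matrix(stats::dist(xyz))
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      dij <- dmat[i, j]
      if (dij > cutoff) next
      if (dij == 0) stop(sprintf("coincident atoms %d and %d in a contact pair", i, j))
      dr <- xyz[j, ] - xyz[i, ]
      blk <- -gamma * tcrossprod(dr) / dij^2
      ri <- (3 * i - 2):(3 * i)
      rj <- (3 * j - 2):(3 * j)
      h[ri, rj] <- blk
      h[rj, ri] <- blk
      h[ri, ri] <- h[ri, ri] - blk
      h[rj, rj] <- h[rj, rj] - blk
    }
  }
  h
}

#' Gaussian network model Kirchhoff matrix
#'
#' Graph Laplacian of the contact network: Gamma_ij = -1 for distinct atoms
#' within the cutoff, diagonal = contact degree; rows sum to zero.
#'
#' @param atoms an [AtomSet-class].
#' @param cutoff contact cutoff distance (Angstrom); default 10.
#' @return symmetric P x P numeric matrix.
#' @export
gnmKirchhoff <- function(atoms, cutoff = 10) {
  xyz <- atomCoords(atoms)
  p <- nrow(xyz)
  if (p < 2L) stop("at least two atoms required")
  if (cutoff <= 0) stop("cutoff must be positive")
  dmat <- as.matrix(stats::dist(xyz))
  adj <- (dmat > 0 & dmat <= cutoff) * 1
  diag(adj) <- 0
  k <- -adj
  diag(k) <- rowSums(adj)
  k
}

#' Lowest nonzero modes of an elastic-network matrix
#'
#' Symmetric eigendecomposition; eigenvalues below `zeroTol` times the
#' largest eigenvalue are flagged as null-space (rigid-body / constant)
#' modes, counted and excluded, and the k lowest remaining eigenpairs are
#' returned with eigenvalues ascending.
#'
#' @param matrix symmetric PSD matrix (ANM Hessian or GNM Kirchhoff).
#' @param k number of nonzero modes to return.
#' @param kind `"ANM"` or `"GNM"`; governs the mode dimension bookkeeping.
#' @param zeroTol relative zero-eigenvalue tolerance (default 1e-6).
#' @return a [NormalModeSet-class].
#' @export
computeModes <- function(matrix, k, kind = c("ANM", "GNM"), zeroTol = 1e-6) {
  kind <- match.arg(kind)
  dd <- nrow(matrix)
  eig <- eigen(matrix, symmetric = TRUE)
  vals <- rev(eig$values)
  vecs <- eig$vectors[, rev(seq_len(dd)), drop = FALSE]
  nzero <- sum(vals < zeroTol * max(vals))
  if (k > dd - nzero)
    stop(sprintf("requested %d modes but only %d nonzero modes exist", k, dd - nzero))
  keep <- (nzero + 1L):(nzero + k)
  nAtoms <- if (kind == "GNM") dd else dd %/% 3L
  new("NormalModeSet", modes = vecs[, keep, drop = FALSE],
      eigenvalues = vals[keep], kind = kind, nAtoms = as.integer(nAtoms),
      zeroModeCount = as.integer(nzero))
}

#' GNM covariance from the Kirchhoff pseudo-inverse
#'
#' Sum over the P - 1 nonzero modes of (1/lambda_k) v_k v_k^T, i.e. the
#' Moore-Penrose pseudo-inverse of the Kirchhoff matrix of a connected
#' contact graph. Its diagonal gives mean-square fluctuations (MSFs).
#'
#' @param kirchhoff symmetric P x P Kirchhoff matrix.
#' @param zeroTol relative zero-eigenvalue tolerance.
#' @return symmetric PSD P x P covariance matrix (rows sum to zero).
#' @export
gnmCovariance <- function(kirchhoff, zeroTol = 1e-6) {
  p <- nrow(kirchhoff)
  eig <- eigen(kirchhoff, symmetric = TRUE)
  zero <- eig$values < zeroTol * max(eig$values)
  if (sum(zero) > 1L)
    stop(sprintf("contact graph is disconnected (%d components); covariance undefined", sum(zero)))
  keep <- which(!zero)
  v <- eig$vectors[, keep, drop = FALSE]
  v %*% (t(v) / eig$values[keep])
}

#' Cross-correlations from a GNM covariance
#'
#' @param covariance P x P covariance (e.g. from [gnmCovariance()]).
#' @param normalized when TRUE, C_ij = Sigma_ij / sqrt(Sigma_ii Sigma_jj)
#'   (unit diagonal, values in \[-1, 1\]); when FALSE the raw covariance is
#'   returned.
#' @return P x P matrix.
#' @export
crossCorrelations <- function(covariance, normalized = TRUE) {
  if (!normalized) return(covariance)
  msf <- diag(covariance)
  if (any(msf <= 0))
    stop("zero mean-square fluctuation on the diagonal; cannot normalize")
  covariance / sqrt(tcrossprod(msf))
}

#' Slice or extend a normal-mode set over an atom selection
#'
#' `slice` keeps the rows of the selected atoms and re-normalizes each
#' column to unit norm; `extend` zero-pads rows for unselected atoms of a
#' larger target structure. The selection refers to atoms (each atom owning
#' three rows for ANM/PCA modes, one for GNM).
#'
#' @param modes a [NormalModeSet-class].
#' @param selection logical mask over the source atoms (slice) or the
#'   target atoms (extend).
#' @param action `"slice"` or `"extend"`.
#' @return a [NormalModeSet-class] over the selected / padded atoms.
#' @export
editModes <- function(modes, selection, action = c("slice", "extend")) {
  action <- match.arg(action)
  selection <- as.logical(selection)
  if (!any(selection)) stop("empty atom selection")
  perAtom <- if (modes@kind == "GNM") 1L else 3L
  if (action == "slice") {
    if (length(selection) != modes@nAtoms)
      stop("selection length must equal the source atom count")
    rows <- rep(selection, each = perAtom)
    u <- modes@modes[rows, , drop = FALSE]
    norms <- sqrt(colSums(u^2))
    if (any(norms == 0)) stop("a sliced mode column is identically zero")
    u <- sweep(u, 2, norms, "/")
    newAtoms <- sum(selection)
  } else {
    if (sum(selection) != modes@nAtoms)
      stop("extend: selection must pick exactly the source atoms within the target")
    u <- matrix(0, length(selection) * perAtom, ncol(modes@modes))
    rows <- rep(selection, each = perAtom)
    u[rows, ] <- modes@modes
    newAtoms <- length(selection)
  }
  new("NormalModeSet", modes = u, eigenvalues = modes@eigenvalues,
      kind = modes@kind, nAtoms = as.integer(newAtoms),
      zeroModeCount = modes@zeroModeCount)
}
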