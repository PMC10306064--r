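#' Iterative superposition of an ensemble
#'
#' Repeats \{compute the mean structure; Kabsch-fit every member to it\}
#' until the mean structure moves by less than `tol` RMSD between
#' iterations. The standard way to remove rigid-body differences before
#' covariance analysis.
#'
#' @param ensemble an [Ensemble-class].
#' @param tol convergence threshold on the mean-structure RMSD (Angstrom).
#' @param maxIter iteration cap.
#' @return list with `ensemble` (aligned), `iterations`, and `meanShift`
#'   (the final mean-structure RMSD step).
#' @export
iterativeSuperpose <- function(ensemble, tol = 1e-6, maxIter = 100) {
  arr <- ensemble@coords
  m <- dim(arr)[1]
  meanStruct <- apply(arr, c(2, 3), mean)
  if (max(apply(arr, 1, function(x) stats::sd(as.vector(x)))) == 0 &&
      stats::sd(as.vector(meanStruct)) == 0)
    stop("degenerate ensemble: all coordinates coincide")
  iter <- 0L
  shift <- Inf
  while (iter < maxIter) {
    iter <- iter + 1L
    for (i in seq_len(m)) {
      arr[i, , ] <- applyRigid(arr[i, , ], kabsch(arr[i, , ], meanStruct))
    }
    newMean <- apply(arr, c(2, 3), mean)
    shift <- sqrt(mean(rowSums((newMean - meanStruct)^2)))
    meanStruct <- newMean
    if (shift < tol) break
  }
  list(
    ensemble = new("Ensemble", coords = arr, memberIds = ensemble@memberIds,
                   referenceIndex = ensemble@referenceIndex),
    iterations = iter,
    meanShift = shift
  )
}

#' Principal component analysis of a structural ensemble
#'
#' Eigendecomposition of the 3P x 3P positional covariance of the stacked
#' (atom-major) coordinates about the ensemble mean. For M < 3P the
#' decomposition goes through the M x M Gram matrix, which shares the
#' nonzero spectrum. Components are unit-norm and variance-descending.
#'
#' @param ensemble an aligned [Ensemble-class] with M >= 2 members.
#' @param nComponents number of components to return; default all nonzero
#'   (at most M - 1).
#' @return list with `modes` (a [NormalModeSet-class], kind PCA, eigenvalues
#'   = variances) and `fractionalVariances` (lambda_i / sum lambda over all
#'   nonzero components).
#' @export
ensemblePCA <- function(ensemble, nComponents = NULL) {
  arr <- ensemble@coords
  m <- dim(arr)[1]
  p <- dim(arr)[2]
  if (m < 2L) stop("PCA requires at least two members")
  X <- t(vapply(seq_len(m), function(i) stackField(arr[i, , ]),
                numeric(3L * p)))
  Xc <- sweep(X, 2, colMeans(X))
  # covariance normalized by M (population convention); only fractional
  # variances and component directions are consumed downstream
  gram <- tcrossprod(Xc) / m
  eig <- eigen(gram, symmetric = TRUE)
  tol <- max(eig$values) * 1e-12
  nz <- sum(eig$values > tol)
  if (is.null(nComponents)) nComponents <- nz
  if (nComponents > nz)
    stop(sprintf("only %d nonzero components available", nz))
  lam <- eig$values[seq_len(nComponents)]
  # lift Gram eigenvectors to 3P space and normalize
  v <- crossprod(Xc, eig$vectors[, seq_len(nComponents), drop = FALSE])
  v <- sweep(v, 2, sqrt(colSums(v^2)), "/")
  modes <- new("NormalModeSet", modes = v, eigenvalues = lam, kind = "PCA",
               nAtoms = as.integer(p), zeroModeCount = 0L)
  list(modes = modes,
       fractionalVariances = lam / sum(eig$values[seq_len(nz)]))
}

#' Project an ensemble onto components or normal modes
#'
#' Row m is the vector of dot products of member m's centered, stacked
#' coordinates with each component column, divided by sqrt(P) so the
#' projections read on the scale of RMSDs (Angstrom).
#'
#' @param ensemble an [Ensemble-class].
#' @param components a [NormalModeSet-class] with 3P rows (PCA or ANM).
#' @return M x K numeric matrix of projection coordinates.
#' @export
projectEnsemble <- function(ensemble, components) {
  arr <- ensemble@coords
  m <- dim(arr)[1]
  p <- dim(arr)[2]
  if (components@nAtoms != p)
    stop("component atom count must match the ensemble")
  if (components@kind == "GNM") stop("projection requires 3P-dimensional modes")
  X <- t(vapply(seq_len(m), function(i) stackField(arr[i, , ]),
                numeric(3L * p)))
  Xc <- sweep(X, 2, colMeans(X))
  (Xc %*% components@modes) / sqrt(p)
}

#' Deformation vector between two corresponding structures
#'
#' Atom-major stacked difference of the coordinates (b - a). Its norm is
#' sqrt(P) times the (unfitted) RMSD between the structures.
#'
#' @param a,b [AtomSet-class] objects with corresponding atoms.
#' @return numeric vector of length 3P.
#' @export
deformationVector <- function(a, b) {
  if (atomCount(a) != atomCount(b))
    stop("structures must share the same atom count")
  stackField(atomCoords(b) - atomCoords(a))
}

#' Overlap between a deformation vector and a mode
#'
#' Signed normalized dot product of the two vectors, in \[-1, 1\].
#'
#' @param v numeric vector (e.g. from [deformationVector()]).
#' @param mode numeric vector of the same length (a mode column).
#' @return scalar overlap.
#' @export
modeOverlap <- function(v, mode) {
  nv <- sqrt(sum(v^2))
  nm <- sqrt(sum(mode^2))
  if (nv == 0 || nm == 0) stop("overlap undefined for a zero vector")
  sum(v * mode) / (nv * nm)
}

#' Cumulative overlap of a vector over a mode set
#'
#' Square root of the sum of squared normalized overlaps; equals 1 for any
#' vector against a complete orthonormal basis (Parseval).
#'
#' @param v numeric vector.
#' @param modes a [NormalModeSet-class] or matrix of mode columns.
#' @return scalar in \[0, 1\] for orthonormal modes.
#' @export
cumulativeOverlap <- function(v, modes) {
  u <- if (is(modes, "NormalModeSet")) modes@modes else as.matrix(modes)
  sqrt(sum(vapply(seq_len(ncol(u)), function(k) modeOverlap(v, u[, k])^2,
                  numeric(1))))
}

#' Pairwise overlap matrix between two mode sets
#'
#' Entry (i, j) is the unsigned correlation cosine |u_i . w_j| between mode
#' i of A and mode j of B (columns assumed unit-norm up to normalization,
#' which is applied).
#'
#' @param a,b [NormalModeSet-class] objects (or matrices) sharing their row
#'   dimension.
#' @return K_A x K_B matrix with entries in \[0, 1\].
#' @export
overlapMatrix <- function(a, b) {
  ua <- if (is(a, "NormalModeSet")) a@modes else as.matrix(a)
  ub <- if (is(b, "NormalModeSet")) b@modes else as.matrix(b)
  if (nrow(ua) != nrow(ub)) stop("mode sets must share their row dimension")
  ua <- sweep(ua, 2, sqrt(colSums(ua^2)), "/")
  ub <- sweep(ub, 2, sqrt(colSums(ub^2)), "/")
  abs(crossprod(ua, ub))
}
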