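#' Labelled 3D point cloud of atoms or pseudoatoms
#'
#' Carrier of per-atom information for all structure-level operations:
#' coordinates in Angstrom, one PDB-style label record per atom, and an
#' optional selection mask.
#'
#' @slot coords P x 3 numeric matrix of positions (Angstrom).
#' @slot labels data.frame with one row per atom: `chain`, `resno`, `resid`,
#'   `atom`, `element`, `insert`, `altloc`.
#' @slot selection logical vector of length P, or length 0 when no selection
#'   is attached.
#' @export
setClass("AtomSet", representation(
  coords = "matrix",
  labels = "data.frame",
  selection = "logical"
))

setValidity("AtomSet", function(object) {
  p <- nrow(object@coords)
  if (is.null(p) || p < 1L) return("coords must have at least one row")
  if (ncol(object@coords) != 3L) return("coords must be P x 3")
  if (!all(is.finite(object@coords))) return("coords must be finite")
  if (nrow(object@labels) != p) return("labels must have one row per atom")
  if (length(object@selection) > 0L && length(object@selection) != p)
    return("selection mask length must equal atom count")
  TRUE
})

#' Construct an AtomSet
#'
#' @param coords P x 3 numeric matrix (Angstrom).
#' @param labels optional data.frame of per-atom records; a minimal C-alpha
#'   style label set is generated when omitted.
#' @param selection optional logical mask of length P.
#' @return an [AtomSet-class] object.
#' @examples
#' a <- AtomSet(matrix(rnorm(30), 10, 3))
#' atomCount(a)
#' @export
AtomSet <- function(coords, labels = NULL, selection = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  p <- nrow(coords)
  if (is.null(labels)) {
    labels <- data.frame(
      chain = rep("A", p), resno = seq_len(p), resid = rep("ALA", p),
      atom = rep("CA", p), element = rep("C", p),
      insert = rep("", p), altloc = rep("", p),
      stringsAsFactors = FALSE
    )
  }
  new("AtomSet", coords = coords, labels = labels,
      selection = if (is.null(selection)) logical(0) else as.logical(selection))
}

#' Density map on a regular isotropic grid
#'
#' @slot grid 3D numeric array of densities (Nx x Ny x Nz).
#' @slot voxelSize scalar voxel edge length (Angstrom), isotropic.
#' @slot origin 3-vector: real-space position (Angstrom) of the center of
#'   voxel (0, 0, 0).
#' @export
setClass("VoxelMap", representation(
  grid = "array",
  voxelSize = "numeric",
  origin = "numeric"
))

setValidity("VoxelMap", function(object) {
  if (length(dim(object@grid)) != 3L) return("grid must be a 3D array")
  if (!all(is.finite(object@grid))) return("grid values must be finite")
  if (length(object@voxelSize) != 1L || object@voxelSize <= 0)
    return("voxelSize must be a positive scalar")
  if (length(object@origin) != 3L) return("origin must be a 3-vector")
  TRUE
})

#' Construct a VoxelMap
#'
#' @param grid 3D numeric array.
#' @param voxelSize voxel edge (Angstrom), isotropic.
#' @param origin 3-vector (Angstrom), position of voxel (0,0,0); default 0.
#' @return a [VoxelMap-class].
#' @export
VoxelMap <- function(grid, voxelSize = 1, origin = c(0, 0, 0)) {
  storage.mode(grid) <- "double"
  new("VoxelMap", grid = grid, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' Zernike basis evaluated at a fixed point set
#'
#' Holds the P x B matrix of 3D Zernike basis functions
#' Z_(l,n,m)(r) = R_(n,l)(rho) * y_(l,m)(theta, phi) evaluated at `points`
#' inside the support ball of radius `radius` about `center`, together with
#' the ordered (l, n, m) index set.
#'
#' @slot points P x 3 matrix (Angstrom).
#' @slot center 3-vector (Angstrom).
#' @slot radius support-ball radius (Angstrom).
#' @slot lMax,nMax integer degree bounds.
#' @slot indexSet data.frame with columns `l`, `n`, `m` (row order = column
#'   order of `Z`).
#' @slot Z P x B basis matrix.
#' @export
setClass("ZernikeBasis", representation(
  points = "matrix",
  center = "numeric",
  radius = "numeric",
  lMax = "integer",
  nMax = "integer",
  indexSet = "data.frame",
  Z = "matrix"
))

setValidity("ZernikeBasis", function(object) {
  if (ncol(object@points) != 3L) return("points must be P x 3")
  if (object@radius <= 0) return("radius must be positive")
  if (object@lMax > object@nMax) return("lMax must not exceed nMax")
  if (nrow(object@Z) != nrow(object@points))
    return("Z must have one row per point")
  if (ncol(object@Z) != nrow(object@indexSet))
    return("Z columns must match the index set")
  if (!all(is.finite(object@Z))) return("basis values must be finite")
  TRUE
})

#' Zernike deformation-field coefficients
#'
#' A 3 x B array `A` (one row per Cartesian component) expanding a
#' deformation field in the Zernike basis identified by the attached
#' metadata, and bound to a named reference conformation.
#'
#' @slot A 3 x B numeric matrix.
#' @slot lMax,nMax integer degree bounds of the basis.
#' @slot radius,center support-ball geometry (Angstrom).
#' @slot referenceId identity of the reference the field deforms.
#' @export
setClass("ZernikeCoefficients", representation(
  A = "matrix",
  lMax = "integer",
  nMax = "integer",
  radius = "numeric",
  center = "numeric",
  referenceId = "character"
))

setValidity("ZernikeCoefficients", function(object) {
  if (nrow(object@A) != 3L) return("A must be 3 x B")
  if (!all(is.finite(object@A))) return("coefficients must be finite")
  if (ncol(object@A) != zernikeBasisSize(object@lMax, object@nMax))
    return("A column count inconsistent with (lMax, nMax)")
  TRUE
})

#' Construct ZernikeCoefficients
#'
#' @param A 3 x B matrix (rows: x, y, z coefficient vectors).
#' @param lMax,nMax degree bounds of the basis the coefficients refer to.
#' @param radius,center support-ball geometry (Angstrom).
#' @param referenceId label of the reference conformation.
#' @return a [ZernikeCoefficients-class].
#' @export
ZernikeCoefficients <- function(A, lMax, nMax, radius, center = c(0, 0, 0),
                                referenceId = "reference") {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  new("ZernikeCoefficients", A = A, lMax = as.integer(lMax),
      nMax = as.integer(nMax), radius = as.numeric(radius),
      center = as.numeric(center), referenceId = referenceId)
}

#' Per-point displacement field
#'
#' @slot displacements P x 3 matrix (Angstrom).
#' @slot points the P x 3 point set the field is bound to.
#' @export
setClass("DeformationField", representation(
  displacements = "matrix",
  points = "matrix"
))

setValidity("DeformationField", function(object) {
  if (ncol(object@displacements) != 3L) return("displacements must be P x 3")
  if (nrow(object@displacements) != nrow(object@points))
    return("field and bound point set must share P")
  if (!all(is.finite(object@displacements)))
    return("displacements must be finite")
  TRUE
})

#' Construct a DeformationField
#'
#' @param displacements P x 3 matrix of displacement vectors (Angstrom).
#' @param points P x 3 matrix of the points the field is bound to.
#' @return a [DeformationField-class].
#' @export
DeformationField <- function(displacements, points) {
  displacements <- as.matrix(displacements)
  points <- as.matrix(points)
  storage.mode(displacements) <- "double"
  storage.mode(points) <- "double"
  new("DeformationField", displacements = displacements, points = points)
}

#' Set of normal modes or principal components
#'
#' Columns are unit-norm, mutually orthogonal mode vectors: 3P-dimensional
#' for ANM and PCA, P-dimensional for GNM. Eigenvalues are sorted ascending
#' for ANM/GNM and variance-descending for PCA.
#'
#' @slot modes D x K matrix, orthonormal columns.
#' @slot eigenvalues numeric length K (PCA: variances).
#' @slot kind `"ANM"`, `"GNM"` or `"PCA"`.
#' @slot nAtoms number of atoms P of the underlying structure.
#' @slot zeroModeCount number of null-space modes detected and excluded.
#' @export
setClass("NormalModeSet", representation(
  modes = "matrix",
  eigenvalues = "numeric",
  kind = "character",
  nAtoms = "integer",
  zeroModeCount = "integer"
))

setValidity("NormalModeSet", function(object) {
  k <- ncol(object@modes)
  if (length(object@eigenvalues) != k)
    return("one eigenvalue per mode required")
  if (!object@kind %in% c("ANM", "GNM", "PCA"))
    return("kind must be ANM, GNM or PCA")
  d <- nrow(object@modes)
  expected <- if (object@kind == "GNM") object@nAtoms else 3L * object@nAtoms
  if (d != expected) return("mode dimension inconsistent with kind/nAtoms")
  if (k > 0) {
    norms <- sqrt(colSums(object@modes^2))
    if (max(abs(norms - 1)) > 1e-6)
      return("mode columns must be unit norm")
  }
  TRUE
})

#' Amplitudes of a normal-mode expansion
#'
#' Weights g of a deformation field expressed as a linear combination of the
#' columns of a mode set, with the least-squares residual norm kept as a
#' diagnostic of how much of the field the modes could absorb.
#'
#' @slot g numeric length K.
#' @slot modesRef identity label of the mode set used.
#' @slot residualNorm Euclidean norm of the unexplained part of the field.
#' @export
setClass("ModeAmplitudes", representation(
  g = "numeric",
  modesRef = "character",
  residualNorm = "numeric"
))

#' Structural ensemble of corresponding atoms
#'
#' @slot coords M x P x 3 array (Angstrom); member m is `coords[m, , ]`.
#' @slot memberIds character labels, length M.
#' @slot referenceIndex index of the member defining the frame (0 = mean).
#' @export
setClass("Ensemble", representation(
  coords = "array",
  memberIds = "character",
  referenceIndex = "integer"
))

setValidity("Ensemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L) return("coords must be M x P x 3")
  if (!all(is.finite(object@coords))) return("coords must be finite")
  if (length(object@memberIds) != d[1])
    return("one member id per member required")
  TRUE
})

#' Construct an Ensemble
#'
#' @param coords M x P x 3 array, or a list of P x 3 matrices.
#' @param memberIds optional labels.
#' @param referenceIndex member defining the frame; 0 means the mean.
#' @return an [Ensemble-class].
#' @export
Ensemble <- function(coords, memberIds = NULL, referenceIndex = 0L) {
  if (is.list(coords)) {
    m <- length(coords)
    p <- nrow(coords[[1]])
    arr <- array(0, dim = c(m, p, 3))
    for (i in seq_len(m)) arr[i, , ] <- as.matrix(coords[[i]])
    coords <- arr
  }
  if (is.null(memberIds)) memberIds <- paste0("member_", seq_len(dim(coords)[1]))
  new("Ensemble", coords = coords, memberIds = as.character(memberIds),
      referenceIndex = as.integer(referenceIndex))
}

#' Per-particle Zernike coefficient table
#'
#' One row per particle: identifier, Euler angles (ZYZ, degrees), in-plane
#' shifts (pixels) and the flattened 3 x B coefficient vector in
#' component-major layout (all x coefficients, then y, then z). The header
#' metadata makes the layout self-describing.
#'
#' @slot particles data.frame: `particle_id`, `rot`, `tilt`, `psi`,
#'   `shift_x`, `shift_y`.
#' @slot coeffs M x 3B numeric matrix, component-major.
#' @slot lMax,nMax,radius,center,referenceId basis metadata.
#' @export
setClass("CoefficientTable", representation(
  particles = "data.frame",
  coeffs = "matrix",
  lMax = "integer",
  nMax = "integer",
  radius = "numeric",
  center = "numeric",
  referenceId = "character"
))

setValidity("CoefficientTable", function(object) {
  if (nrow(object@particles) != nrow(object@coeffs))
    return("particle metadata and coefficient rows must align")
  b <- zernikeBasisSize(object@lMax, object@nMax)
  if (ncol(object@coeffs) != 3L * b)
    return(sprintf("coefficient rows must have length 3*B = %d", 3L * b))
  if (!all(is.finite(object@coeffs))) return("coefficients must be finite")
  TRUE
})

#' Construct a CoefficientTable
#'
#' @param coeffs M x 3B matrix (component-major rows).
#' @param particles optional data.frame of particle metadata; generated with
#'   zero angles/shifts when omitted.
#' @param lMax,nMax,radius,center,referenceId basis metadata shared by all
#'   rows.
#' @return a [CoefficientTable-class].
#' @export
CoefficientTable <- function(coeffs, particles = NULL, lMax, nMax, radius,
                             center = c(0, 0, 0), referenceId = "reference") {
  coeffs <- as.matrix(coeffs)
  storage.mode(coeffs) <- "double"
  m <- nrow(coeffs)
  if (is.null(particles)) {
    particles <- data.frame(
      # sprintf (unlike paste0) keeps zero-length inputs zero-length
      particle_id = sprintf("particle_%d", seq_len(m)),
      rot = numeric(m), tilt = numeric(m), psi = numeric(m),
      shift_x = numeric(m), shift_y = numeric(m),
      stringsAsFactors = FALSE
    )
  }
  new("CoefficientTable", particles = particles, coeffs = coeffs,
      lMax = as.integer(lMax), nMax = as.integer(nMax),
      radius = as.numeric(radius), center = as.numeric(center),
      referenceId = referenceId)
}
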