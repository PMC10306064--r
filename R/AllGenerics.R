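#' @import methods
NULL

#' Atom coordinates
#'
#' Accessor for the P x 3 coordinate matrix (in Angstrom) carried by an
#' object.
#'
#' @param x an object with coordinates (e.g. [AtomSet-class]).
#' @return a numeric matrix with one row per atom.
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))

#' Number of atoms / points
#'
#' @param x an object bound to a point set.
#' @return integer count of atoms (or basis points).
#' @export
setGeneric("atomCount", function(x) standardGeneric("atomCount"))

#' Displacement vectors of a deformation field
#'
#' @param x a [DeformationField-class].
#' @return P x 3 numeric matrix of displacements (Angstrom).
#' @export
setGeneric("displacements", function(x) standardGeneric("displacements"))

#' Coefficient array of a Zernike expansion
#'
#' @param x a [ZernikeCoefficients-class] object.
#' @return 3 x B numeric matrix (rows: x, y, z components).
#' @export
setGeneric("coefArray", function(x) standardGeneric("coefArray"))

#' Mode matrix of a normal-mode set
#'
#' @param x a [NormalModeSet-class].
#' @return D x K numeric matrix with orthonormal columns.
#' @export
setGeneric("modeMatrix", function(x) standardGeneric("modeMatrix"))

#' Eigenvalues (or variances) of a normal-mode set
#'
#' @param x a [NormalModeSet-class].
#' @return numeric vector of length K.
#' @export
setGeneric("modeEigenvalues", function(x) standardGeneric("modeEigenvalues"))

#' Kind of a normal-mode set
#'
#' @param x a [NormalModeSet-class].
#' @return one of `"ANM"`, `"GNM"`, `"PCA"`.
#' @export
setGeneric("modeKind", function(x) standardGeneric("modeKind"))

#' Density grid of a voxel map
#'
#' @param x a [VoxelMap-class].
#' @return 3D numeric array of densities.
#' @export
setGeneric("mapGrid", function(x) standardGeneric("mapGrid"))

#' Voxel size of a map
#'
#' @param x a [VoxelMap-class].
#' @return scalar voxel edge length (Angstrom), isotropic.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Coefficient rows of a per-particle table
#'
#' @param x a [CoefficientTable-class].
#' @return M x 3B numeric matrix, component-major layout.
#' @export
setGeneric("coefRows", function(x) standardGeneric("coefRows"))

#' Particle metadata of a coefficient table
#'
#' @param x a [CoefficientTable-class].
#' @return data.frame with particle id, Euler angles (degrees) and shifts.
#' @export
setGeneric("particleInfo", function(x) standardGeneric("particleInfo"))

#' Basis metadata of a table or coefficient object
#'
#' @param x an object carrying Zernike basis metadata.
#' @return list with `lMax`, `nMax`, `radius`, `center`, `referenceId`.
#' @export
setGeneric("basisMeta", function(x) standardGeneric("basisMeta"))

#' Basis matrix of a Zernike basis
#'
#' @param x a [ZernikeBasis-class].
#' @return P x B matrix of basis function values.
#' @export
setGeneric("basisMatrix", function(x) standardGeneric("basisMatrix"))

#' Size (number of functions) of a Zernike basis
#'
#' @param x a [ZernikeBasis-class] (or basis metadata).
#' @return integer B, the number of (l, n, m) triples.
#' @export
setGeneric("basisSize", function(x) standardGeneric("basisSize"))

#' Ensemble member coordinates
#'
#' @param x an [Ensemble-class].
#' @return M x P x 3 numeric array.
#' @export
setGeneric("memberCoords", function(x) standardGeneric("memberCoords"))
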