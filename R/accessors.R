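#' @describeIn AtomSet coordinate matrix accessor
#' @param x object to access.
#' @export
setMethod("atomCoords", "AtomSet", function(x) x@coords)

#' @describeIn AtomSet number of atoms
#' @export
setMethod("atomCount", "AtomSet", function(x) nrow(x@coords))

#' Per-atom label records
#'
#' @param x an [AtomSet-class].
#' @return data.frame of per-atom PDB-style labels.
#' @export
atomLabels <- function(x) x@labels

#' Selection mask of an AtomSet
#'
#' @param x an [AtomSet-class].
#' @return logical vector of length P, or NULL when none is attached.
#' @export
atomSelection <- function(x) {
  if (length(x@selection) == 0L) NULL else x@selection
}

#' @describeIn DeformationField displacement matrix accessor
#' @param x object to access.
#' @export
setMethod("displacements", "DeformationField", function(x) x@displacements)

#' @describeIn DeformationField number of bound points
#' @export
setMethod("atomCount", "DeformationField", function(x) nrow(x@points))

#' @describeIn ZernikeCoefficients the 3 x B coefficient array
#' @param x object to access.
#' @export
setMethod("coefArray", "ZernikeCoefficients", function(x) x@A)

#' @describeIn ZernikeCoefficients basis metadata list
#' @export
setMethod("basisMeta", "ZernikeCoefficients", function(x) {
  list(lMax = x@lMax, nMax = x@nMax, radius = x@radius, center = x@center,
       referenceId = x@referenceId)
})

#' @describeIn ZernikeBasis the P x B matrix of basis values
#' @param x object to access.
#' @export
setMethod("basisMatrix", "ZernikeBasis", function(x) x@Z)

#' @describeIn ZernikeBasis number of basis functions B
#' @export
setMethod("basisSize", "ZernikeBasis", function(x) ncol(x@Z))

#' @describeIn ZernikeBasis number of evaluation points
#' @export
setMethod("atomCount", "ZernikeBasis", function(x) nrow(x@points))

#' @describeIn ZernikeBasis basis metadata list
#' @export
setMethod("basisMeta", "ZernikeBasis", function(x) {
  list(lMax = x@lMax, nMax = x@nMax, radius = x@radius, center = x@center)
})

#' Index set of a Zernike basis
#'
#' @param x a [ZernikeBasis-class].
#' @return data.frame with columns `l`, `n`, `m` in basis-column order.
#' @export
basisIndexSet <- function(x) x@indexSet

#' @describeIn NormalModeSet mode matrix accessor
#' @param x object to access.
#' @export
setMethod("modeMatrix", "NormalModeSet", function(x) x@modes)

#' @describeIn NormalModeSet eigenvalue / variance accessor
#' @export
setMethod("modeEigenvalues", "NormalModeSet", function(x) x@eigenvalues)

#' @describeIn NormalModeSet provenance kind (ANM, GNM, PCA)
#' @export
setMethod("modeKind", "NormalModeSet", function(x) x@kind)

#' @describeIn NormalModeSet number of atoms of the underlying structure
#' @export
setMethod("atomCount", "NormalModeSet", function(x) x@nAtoms)

#' Number of detected null-space modes
#'
#' @param x a [NormalModeSet-class].
#' @return integer: 6 for a connected non-collinear ANM system, 1 for a
#'   connected GNM graph.
#' @export
zeroModeCount <- function(x) x@zeroModeCount

#' @describeIn VoxelMap density grid accessor
#' @param x object to access.
#' @export
setMethod("mapGrid", "VoxelMap", function(x) x@grid)

#' @describeIn VoxelMap voxel edge length (Angstrom)
#' @export
setMethod("voxelSize", "VoxelMap", function(x) x@voxelSize)

#' Origin of a voxel map
#'
#' @param x a [VoxelMap-class].
#' @return 3-vector (Angstrom): real-space center of voxel (0,0,0).
#' @export
mapOrigin <- function(x) x@origin

#' @describeIn CoefficientTable coefficient row matrix (component-major)
#' @param x object to access.
#' @export
setMethod("coefRows", "CoefficientTable", function(x) x@coeffs)

#' @describeIn CoefficientTable particle metadata accessor
#' @export
setMethod("particleInfo", "CoefficientTable", function(x) x@particles)

#' @describeIn CoefficientTable basis metadata list
#' @export
setMethod("basisMeta", "CoefficientTable", function(x) {
  list(lMax = x@lMax, nMax = x@nMax, radius = x@radius, center = x@center,
       referenceId = x@referenceId)
})

#' Number of particles in a coefficient table
#'
#' @param x a [CoefficientTable-class].
#' @return integer row count.
#' @export
particleCount <- function(x) nrow(x@coeffs)

#' Extract one table row as ZernikeCoefficients
#'
#' Reshapes the component-major flattened row back into a 3 x B array.
#'
#' @param x a [CoefficientTable-class].
#' @param i row index.
#' @return a [ZernikeCoefficients-class].
#' @export
tableRowCoefficients <- function(x, i) {
  b <- ncol(x@coeffs) / 3L
  ZernikeCoefficients(matrix(x@coeffs[i, ], nrow = 3, byrow = TRUE),
                      lMax = x@lMax, nMax = x@nMax, radius = x@radius,
                      center = x@center, referenceId = x@referenceId)
}

#' @describeIn Ensemble member coordinate array accessor
#' @param x object to access.
#' @export
setMethod("memberCoords", "Ensemble", function(x) x@coords)

#' @describeIn Ensemble number of atoms per member
#' @export
setMethod("atomCount", "Ensemble", function(x) dim(x@coords)[2])

#' Number of members in an ensemble
#'
#' @param x an [Ensemble-class].
#' @return integer M.
#' @export
memberCount <- function(x) dim(x@coords)[1]

#' Amplitude vector accessor
#'
#' @param x a [ModeAmplitudes-class].
#' @return numeric vector g of mode weights.
#' @export
amplitudes <- function(x) x@g

#' Residual norm of an amplitude fit
#'
#' @param x a [ModeAmplitudes-class].
#' @return Euclidean norm of the field component outside the mode span.
#' @export
residualNorm <- function(x) x@residualNorm

setMethod("show", "AtomSet", function(object) {
  cat("AtomSet with", atomCount(object), "atoms\n")
  sel <- atomSelection(object)
  if (!is.null(sel)) cat("  selection: ", sum(sel), " atoms selected\n", sep = "")
})

setMethod("show", "VoxelMap", function(object) {
  d <- dim(object@grid)
  cat(sprintf("VoxelMap %dx%dx%d, voxel %.3f A, origin (%.2f, %.2f, %.2f)\n",
              d[1], d[2], d[3], object@voxelSize,
              object@origin[1], object@origin[2], object@origin[3]))
})

setMethod("show", "ZernikeBasis", function(object) {
  cat(sprintf("ZernikeBasis: %d points, B = %d (lMax = %d, nMax = %d), R = %.2f A\n",
              atomCount(object), basisSize(object), object@lMax, object@nMax,
              object@radius))
})

setMethod("show", "ZernikeCoefficients", function(object) {
  cat(sprintf("ZernikeCoefficients: 3 x %d (lMax = %d, nMax = %d), reference '%s'\n",
              ncol(object@A), object@lMax, object@nMax, object@referenceId))
})

setMethod("show", "DeformationField", function(object) {
  mags <- sqrt(rowSums(object@displacements^2))
  cat(sprintf("DeformationField on %d points; |u| mean %.3f A, max %.3f A\n",
              atomCount(object), mean(mags), max(mags)))
})

setMethod("show", "NormalModeSet", function(object) {
  cat(sprintf("%s NormalModeSet: %d modes x %d atoms (%d zero modes excluded)\n",
              object@kind, ncol(object@modes), object@nAtoms,
              object@zeroModeCount))
})

setMethod("show", "CoefficientTable", function(object) {
  cat(sprintf("CoefficientTable: %d particles, 3 x %d coefficients (lMax = %d, nMax = %d), reference '%s'\n",
              particleCount(object), ncol(object@coeffs) / 3L, object@lMax,
              object@nMax, object@referenceId))
})

setMethod("show", "Ensemble", function(object) {
  cat(sprintf("Ensemble: %d members x %d atoms\n", memberCount(object),
              atomCount(object)))
})

setMethod("show", "ModeAmplitudes", function(object) {
  cat(sprintf("ModeAmplitudes: %d modes (ref '%s'), residual norm %.4g\n",
              length(object@g), object@modesRef, object@residualNorm))
})
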