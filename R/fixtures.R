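# Seeded generators for every input class the toolkit consumes: toy
# structures, Gaussian-splatted maps, random coefficient sets, landscape
# tables and mode-displaced ensembles. All are pure functions of their
# parameters and seed; ground truth (labels, amplitudes) is returned in a
# separate side channel from the data objects.

#' Generate a toy structure
#'
#' Shapes: `helix` — ideal alpha-helical C-alpha trace (rise 1.5 A per
#' residue, 100 degree twist, radius 2.3 A, giving consecutive CA-CA
#' distances of ~3.8 A); `blob` — isotropic Gaussian cloud of width
#' `sigma`; `two_domain` — two Gaussian blobs with centroids `separation`
#' apart along x.
#'
#' @param nAtoms number of atoms, >= 2.
#' @param shape `"helix"`, `"blob"` or `"two_domain"`.
#' @param seed RNG seed (helix is deterministic regardless).
#' @param sigma blob width (Angstrom), default 5.
#' @param separation two-domain centroid distance (Angstrom), default 20.
#' @return an [AtomSet-class].
#' @export
makeToyStructure <- function(nAtoms, shape = c("helix", "blob", "two_domain"),
                             seed = 1, sigma = 5, separation = 20) {
  shape <- match.arg(shape)
  if (nAtoms < 2L) stop("at least two atoms required")
  set.seed(seed)
  coords <- switch(shape,
    helix = {
      i <- seq_len(nAtoms) - 1
      ang <- i * 100 * pi / 180
      cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
    },
    blob = matrix(stats::rnorm(nAtoms * 3, sd = sigma), ncol = 3),
    two_domain = {
      n1 <- nAtoms %/% 2L
      n2 <- nAtoms - n1
      s <- sigma / 3
      a <- matrix(stats::rnorm(n1 * 3, sd = s), ncol = 3)
      b <- matrix(stats::rnorm(n2 * 3, sd = s), ncol = 3)
      a <- sweep(a, 2, colMeans(a))
      b <- sweep(b, 2, colMeans(b))
      rbind(sweep(a, 2, c(-separation / 2, 0, 0), "+"),
            sweep(b, 2, c(separation / 2, 0, 0), "+"))
    }
  )
  AtomSet(coords)
}

#' Gaussian-splat a structure into a density map
#'
#' Sum of isotropic Gaussians of width `sigma` at the atom positions,
#' sampled on a cubic `box`^3 grid centered on the atoms' bounding-box
#' center. Atoms falling outside the box are truncated with a warning.
#'
#' @param atoms an [AtomSet-class].
#' @param voxelSize grid sampling (Angstrom per voxel).
#' @param sigma Gaussian width (Angstrom).
#' @param box grid edge length in voxels.
#' @return a [VoxelMap-class].
#' @export
makeMapFromAtoms <- function(atoms, voxelSize = 1, sigma = 1.5, box = 32) {
  xyz <- atomCoords(atoms)
  ctr <- (apply(xyz, 2, min) + apply(xyz, 2, max)) / 2
  origin <- ctr - (box - 1) / 2 * voxelSize
  half <- (box - 1) / 2 * voxelSize
  outside <- apply(abs(sweep(xyz, 2, ctr)), 1, max) > half
  if (any(outside)) {
    warning(sprintf("%d atoms fall outside the box and are truncated", sum(outside)))
    xyz <- xyz[!outside, , drop = FALSE]
  }
  ax <- seq_len(box) - 1
  grid <- array(0, dim = c(box, box, box))
  for (i in seq_len(nrow(xyz))) {
    gx <- exp(-((ax * voxelSize + origin[1]) - xyz[i, 1])^2 / (2 * sigma^2))
    gy <- exp(-((ax * voxelSize + origin[2]) - xyz[i, 2])^2 / (2 * sigma^2))
    gz <- exp(-((ax * voxelSize + origin[3]) - xyz[i, 3])^2 / (2 * sigma^2))
    grid <- grid + outer(outer(gx, gy), gz)
  }
  VoxelMap(grid, voxelSize = voxelSize, origin = origin)
}

#' Random Zernike coefficients with per-degree decay
#'
#' Entries are i.i.d. Gaussian scaled by `magnitude * decay^n` where n is
#' the radial order of the column — higher-order terms are damped, as in
#' smooth molecular motions. Deterministic per seed; displacements scale
#' linearly with `magnitude`.
#'
#' @param lMax,nMax degree bounds of the target basis.
#' @param radius,center support-ball geometry recorded on the result.
#' @param magnitude overall field scale (Angstrom).
#' @param decay per-order damping factor in (0, 1\]; default 0.7.
#' @param seed RNG seed.
#' @param referenceId reference label.
#' @return a [ZernikeCoefficients-class].
#' @export
makeRandomCoeffs <- function(lMax, nMax, radius, center = c(0, 0, 0),
                             magnitude = 1, decay = 0.7, seed = 1,
                             referenceId = "reference") {
  set.seed(seed)
  idx <- zernikeIndexSet(lMax, nMax)
  b <- nrow(idx)
  scale <- magnitude * decay^idx$n
  A <- matrix(stats::rnorm(3 * b), nrow = 3) * rep(scale, each = 3)
  ZernikeCoefficients(A, lMax = lMax, nMax = nMax, radius = radius,
                      center = center, referenceId = referenceId)
}

#' Synthetic per-particle coefficient landscape
#'
#' Rows are cluster-center coefficient vectors plus isotropic Gaussian
#' noise; Euler angles are drawn uniformly over the sphere (rot uniform on
#' \[0, 360), cos(tilt) uniform on \[-1, 1\], psi uniform). Ground-truth
#' cluster labels are returned separately from the table.
#'
#' @param nParticles number of rows M.
#' @param clusterCoeffs list of [ZernikeCoefficients-class] cluster centers
#'   (shared basis metadata).
#' @param noiseSigma coefficient noise s.d.
#' @param seed RNG seed.
#' @param proportions optional cluster proportions (length = #clusters,
#'   summing to 1); rows are split to match the proportions exactly.
#' @return list with `table` (a [CoefficientTable-class]) and `labels`
#'   (integer ground truth).
#' @export
makeLandscapeTable <- function(nParticles, clusterCoeffs, noiseSigma = 0.1,
                               seed = 1, proportions = NULL) {
  k <- length(clusterCoeffs)
  if (k > nParticles) stop("more clusters than particles")
  set.seed(seed)
  meta <- basisMeta(clusterCoeffs[[1]])
  b <- ncol(coefArray(clusterCoeffs[[1]]))
  if (is.null(proportions)) proportions <- rep(1 / k, k)
  counts <- floor(nParticles * proportions)
  while (sum(counts) < nParticles)
    counts[which.max(nParticles * proportions - counts)] <-
      counts[which.max(nParticles * proportions - counts)] + 1L
  labels <- rep(seq_len(k), times = counts)
  rows <- matrix(0, nParticles, 3L * b)
  for (i in seq_len(nParticles)) {
    center <- as.vector(t(coefArray(clusterCoeffs[[labels[i]]])))
    rows[i, ] <- center + stats::rnorm(3L * b, sd = noiseSigma)
  }
  particles <- data.frame(
    particle_id = paste0("particle_", seq_len(nParticles)),
    rot = stats::runif(nParticles, 0, 360),
    tilt = acos(stats::runif(nParticles, -1, 1)) * 180 / pi,
    psi = stats::runif(nParticles, 0, 360),
    shift_x = numeric(nParticles), shift_y = numeric(nParticles),
    stringsAsFactors = FALSE
  )
  table <- CoefficientTable(rows, particles = particles, lMax = meta$lMax,
                            nMax = meta$nMax, radius = meta$radius,
                            center = meta$center,
                            referenceId = meta$referenceId)
  list(table = table, labels = labels)
}

#' Ensemble displaced along known modes
#'
#' Member m = reference + sum_k a_mk u_k + noise, with amplitudes
#' a_mk ~ N(0, amplitudeSigma_k^2) and isotropic coordinate noise of s.d.
#' `noiseSigma`. The drawn amplitudes are the ground-truth side channel.
#'
#' @param atoms reference [AtomSet-class].
#' @param modes a [NormalModeSet-class] with 3P rows, or a 3P x K matrix.
#' @param amplitudeSigma per-mode amplitude s.d. (recycled to K).
#' @param noiseSigma coordinate noise s.d. (Angstrom).
#' @param nMembers ensemble size M.
#' @param seed RNG seed.
#' @param decorrelate when TRUE, the drawn amplitude columns are centered
#'   and Gram-Schmidt orthogonalized (preserving each mode's sample
#'   variance), so the sample amplitude covariance is exactly diagonal —
#'   the clean substrate for principal-component recovery at small M.
#' @return list with `ensemble` (an [Ensemble-class]) and `amplitudes`
#'   (M x K ground-truth matrix).
#' @export
makeModeEnsemble <- function(atoms, modes, amplitudeSigma = 1,
                             noiseSigma = 0, nMembers = 10, seed = 1,
                             decorrelate = FALSE) {
  u <- if (is(modes, "NormalModeSet")) modeMatrix(modes) else as.matrix(modes)
  p <- atomCount(atoms)
  stopifnot(nrow(u) == 3L * p)
  k <- ncol(u)
  amplitudeSigma <- rep_len(amplitudeSigma, k)
  set.seed(seed)
  amps <- matrix(stats::rnorm(nMembers * k), nMembers, k)
  if (decorrelate) {
    amps <- sweep(amps, 2, colMeans(amps))
    amps <- qr.Q(qr(amps))  # orthonormal columns, then rescale below
    amps <- sweep(amps, 2, apply(amps, 2, stats::sd), "/")
  }
  amps <- amps * rep(amplitudeSigma, each = nMembers)
  arr <- array(0, dim = c(nMembers, p, 3))
  base <- atomCoords(atoms)
  for (m in seq_len(nMembers)) {
    disp <- unstackField(as.numeric(u %*% amps[m, ]))
    noise <- if (noiseSigma > 0)
      matrix(stats::rnorm(3 * p, sd = noiseSigma), p, 3) else 0
    arr[m, , ] <- base + disp + noise
  }
  list(ensemble = Ensemble(arr), amplitudes = amps)
}
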