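#' Per-point motion statistics of a coefficient landscape
#'
#' For every basis point, the mean displacement vector over all table rows
#' and the total standard deviation std_i = sqrt(mean over rows of
#' ||u - u_mean||^2) — a scalar per point, in Angstrom — showing the
#' average direction of motion and which regions deviate most from the
#' reference.
#'
#' @param table a [CoefficientTable-class].
#' @param basis a [ZernikeBasis-class] sharing the table's basis metadata.
#' @return list with `mean` (P x 3 matrix) and `std` (length-P vector).
#' @export
motionStatistics <- function(table, basis) {
  m <- particleCount(table)
  if (m == 0L) stop("empty coefficient table")
  p <- nrow(basis@points)
  # two passes keep the variance exact (zero when all rows agree)
  fields <- lapply(seq_len(m), function(i)
    basis@Z %*% t(tableRowCoefficients(table, i)@A))
  meanU <- Reduce(`+`, fields) / m
  sumSq <- numeric(p)
  for (u in fields) sumSq <- sumSq + rowSums((u - meanU)^2)
  list(mean = meanU, std = sqrt(sumSq / m))
}

#' Greedy RMSD-threshold clustering of conformers
#'
#' Sequentially assigns each structure to the first existing cluster whose
#' representative lies within `cutoff` RMSD after rigid (Kabsch)
#' alignment, seeding a new cluster otherwise; representatives are the
#' aligned member means. Re-assignment passes repeat until the partition
#' is stable (at most `maxPasses`), so at termination every member is
#' within the cutoff of its representative.
#'
#' @param structures list of [AtomSet-class] objects (or P x 3 matrices)
#'   with corresponding atoms.
#' @param cutoff RMSD threshold (Angstrom), > 0.
#' @param maxPasses cap on re-assignment passes (default 10).
#' @return list with `labels` (integer cluster per structure),
#'   `representatives` (list of P x 3 mean structures) and `nClusters`.
#' @export
rmsdCluster <- function(structures, cutoff, maxPasses = 10) {
  if (cutoff <= 0) stop("cutoff must be positive")
  coords <- lapply(structures, function(s)
    if (is(s, "AtomSet")) atomCoords(s) else as.matrix(s))
  m <- length(coords)
  if (m == 0L) stop("no structures supplied")
  labels <- integer(m)
  reps <- list()
  assignAll <- function(labels, reps) {
    for (i in seq_len(m)) {
      placed <- FALSE
      for (k in seq_along(reps)) {
        if (coordRmsd(coords[[i]], reps[[k]]) <= cutoff) {
          labels[i] <- k
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        reps[[length(reps) + 1L]] <- coords[[i]]
        labels[i] <- length(reps)
      }
    }
    list(labels = labels, reps = reps)
  }
  recomputeReps <- function(labels) {
    lapply(seq_len(max(labels)), function(k) {
      members <- which(labels == k)
      ref <- coords[[members[1]]]
      acc <- matrix(0, nrow(ref), 3)
      for (i in members)
        acc <- acc + applyRigid(coords[[i]], kabsch(coords[[i]], ref))
      acc / length(members)
    })
  }
  state <- assignAll(labels, reps)
  labels <- state$labels
  reps <- recomputeReps(labels)
  for (pass in seq_len(maxPasses)) {
    # re-run assignment against the current representatives
    newLabels <- integer(m)
    newReps <- reps
    for (i in seq_len(m)) {
      placed <- FALSE
      for (k in seq_along(newReps)) {
        if (coordRmsd(coords[[i]], newReps[[k]]) <= cutoff) {
          newLabels[i] <- k
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        newReps[[length(newReps) + 1L]] <- coords[[i]]
        newLabels[i] <- length(newReps)
      }
    }
    # drop clusters that lost all members, relabel compactly
    used <- sort(unique(newLabels))
    map <- integer(length(newReps))
    map[used] <- seq_along(used)
    newLabels <- map[newLabels]
    if (identical(newLabels, labels)) {
      labels <- newLabels
      reps <- recomputeReps(labels)
      break
    }
    labels <- newLabels
    reps <- recomputeReps(labels)
  }
  list(labels = labels, representatives = reps, nClusters = max(labels))
}

# Rotate a map by ZYZ Euler angles (degrees) about the grid center with
# trilinear interpolation (backward sampling).
rotateMapGrid <- function(grid, rot, tilt, psi) {
  d <- dim(grid)
  ctr <- (d - 1) / 2
  r <- eulerZYZ(rot, tilt, psi)
  ix <- rep(seq_len(d[1]) - 1, times = d[2] * d[3])
  iy <- rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3])
  iz <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  pts <- cbind(ix - ctr[1], iy - ctr[2], iz - ctr[3])
  # backward map: sample the source at R^-1 x for destination voxel x;
  # clamp-to-edge sampling keeps constant maps exactly rotation-invariant
  src <- pts %*% r  # (R^T x)^T rows = R^-1 applied to each point
  src <- sweep(src, 2, ctr, "+")
  src <- pmin(pmax(src, 0), matrix(d - 1, nrow(src), 3, byrow = TRUE))
  array(trilinearSample(grid, src), dim = d)
}

#' Best-view heatmap between two conformations
#'
#' For every (rot, tilt) on the grid, both maps are rotated by ZYZ Euler
#' angles (rot, tilt, 0), projected by summing along z, and the Pearson
#' correlation between the two projections is recorded. Views with low
#' correlation discriminate the two conformations best. Cells whose
#' projections have zero variance are set to NA (undefined marker).
#'
#' @param mapA,mapB [VoxelMap-class] objects with identical geometry.
#' @param rotGrid rotation angles in degrees (default 0 to 355 step 5).
#' @param tiltGrid tilt angles in degrees (default 0 to 180 step 5).
#' @return length(rotGrid) x length(tiltGrid) matrix of Pearson r values
#'   (dimnames carry the angles).
#' @export
bestViewHeatmap <- function(mapA, mapB,
                            rotGrid = seq(0, 355, by = 5),
                            tiltGrid = seq(0, 180, by = 5)) {
  if (!sameMapGeometry(mapA, mapB))
    stop("maps must share grid dimensions, voxel size and origin")
  h <- matrix(NA_real_, length(rotGrid), length(tiltGrid),
              dimnames = list(rot = rotGrid, tilt = tiltGrid))
  d <- dim(mapA@grid)
  ctr <- (d - 1) / 2
  pts <- cbind(
    rep(seq_len(d[1]) - 1, times = d[2] * d[3]) - ctr[1],
    rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]) - ctr[2],
    rep(seq_len(d[3]) - 1, each = d[1] * d[2]) - ctr[3]
  )
  sameMap <- identical(mapA@grid, mapB@grid)
  for (i in seq_along(rotGrid)) {
    for (j in seq_along(tiltGrid)) {
      # backward sampling positions are shared by both maps; clamp-to-edge
      # keeps the projection correlation exactly affine-invariant
      src <- sweep(pts %*% eulerZYZ(rotGrid[i], tiltGrid[j], 0), 2, ctr, "+")
      src <- pmin(pmax(src, 0), matrix(d - 1, nrow(src), 3, byrow = TRUE))
      va <- trilinearSample(mapA@grid, src)
      vb <- if (sameMap) va else trilinearSample(mapB@grid, src)
      pa <- rowSums(matrix(va, d[1] * d[2], d[3]))  # project along z
      pb <- rowSums(matrix(vb, d[1] * d[2], d[3]))
      if (stats::sd(pa) == 0 || stats::sd(pb) == 0) next  # stays NA
      h[i, j] <- stats::cor(pa, pb)
    }
  }
  h
}

#' Filter particles by discriminative views
#'
#' Keeps table rows whose (rot, tilt) angles fall in heatmap cells with
#' Pearson correlation at or below the threshold — the views that best
#' distinguish the conformations. Rotations wrap modulo 360 and tilts are
#' clamped to \[0, 180\]; rows landing in undefined (NA) cells are dropped.
#'
#' @param table a [CoefficientTable-class] with per-particle Euler angles.
#' @param heatmap matrix from [bestViewHeatmap()] with angle dimnames.
#' @param threshold correlation threshold; `threshold = 1` keeps every row
#'   in a defined cell.
#' @return the filtered [CoefficientTable-class].
#' @export
selectParticlesByView <- function(table, heatmap, threshold) {
  rots <- as.numeric(rownames(heatmap))
  tilts <- as.numeric(colnames(heatmap))
  ang <- particleInfo(table)
  rot <- ang$rot %% 360
  tilt <- pmin(pmax(ang$tilt, 0), 180)
  nearestCell <- function(x, grid) {
    vapply(x, function(v) which.min(abs(grid - v)), integer(1))
  }
  # rotation distance respects the wrap-around
  ri <- vapply(rot, function(v) {
    dd <- pmin(abs(rots - v), 360 - abs(rots - v))
    which.min(dd)
  }, integer(1))
  ti <- nearestCell(tilt, tilts)
  vals <- heatmap[cbind(ri, ti)]
  keep <- !is.na(vals) & vals <= threshold
  new("CoefficientTable", particles = table@particles[keep, , drop = FALSE],
      coeffs = table@coeffs[keep, , drop = FALSE], lMax = table@lMax,
      nMax = table@nMax, radius = table@radius, center = table@center,
      referenceId = table@referenceId)
}

#' PCA reduction of a coefficient landscape
#'
#' Principal component embedding of the (centered) coefficient rows into
#' `nDims` dimensions — the standard low-dimensional conformational
#' landscape. Deterministic up to component sign.
#'
#' @param table a [CoefficientTable-class].
#' @param nDims target dimension (2 or 3 typically).
#' @return list with `embedding` (M x nDims), `components` (3B x nDims) and
#'   `fractionalVariances`.
#' @export
reduceLandscape <- function(table, nDims = 2) {
  X <- coefRows(table)
  Xc <- sweep(X, 2, colMeans(X))
  maxRank <- min(nrow(X) - 1L, ncol(X))
  if (nDims > maxRank)
    stop(sprintf("requested %d dimensions but at most %d are available (rank bound)",
                 nDims, maxRank))
  sv <- svd(Xc)
  emb <- sv$u[, seq_len(nDims), drop = FALSE] %*% diag(sv$d[seq_len(nDims)], nDims)
  vars <- sv$d^2
  list(embedding = emb,
       components = sv$v[, seq_len(nDims), drop = FALSE],
       fractionalVariances = (vars / sum(vars))[seq_len(nDims)])
}

#' k-means representatives of a coefficient landscape
#'
#' Lloyd k-means (stats::kmeans, several restarts under a fixed seed) on
#' the coefficient rows; the centers are returned as synthetic coefficient
#' rows bundled into a [CoefficientTable-class].
#'
#' @param table a [CoefficientTable-class].
#' @param k number of clusters, <= number of rows.
#' @param seed RNG seed for the restarts.
#' @param nstart random restarts (default 10).
#' @return list with `centers` (a k-row [CoefficientTable-class]), `labels`
#'   and `inertia` (total within-cluster sum of squares).
#' @export
kmeansRepresentatives <- function(table, k, seed = 1, nstart = 10) {
  X <- coefRows(table)
  if (k > nrow(X)) stop("k must not exceed the number of rows")
  if (k == nrow(X)) {
    # every row is its own center
    km <- list(centers = X, cluster = seq_len(k), tot.withinss = 0)
  } else {
    set.seed(seed)
    km <- stats::kmeans(X, centers = k, nstart = nstart, iter.max = 100)
  }
  centers <- CoefficientTable(
    km$centers,
    particles = data.frame(
      particle_id = paste0("center_", seq_len(k)),
      rot = numeric(k), tilt = numeric(k), psi = numeric(k),
      shift_x = numeric(k), shift_y = numeric(k), stringsAsFactors = FALSE),
    lMax = table@lMax, nMax = table@nMax, radius = table@radius,
    center = table@center, referenceId = table@referenceId)
  list(centers = centers, labels = km$cluster, inertia = km$tot.withinss)
}
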