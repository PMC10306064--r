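# Shared fixtures and small independent oracles used across the suite.

# best label agreement of a 2-cluster assignment against ground truth,
# invariant to label swapping
labelAgreement2 <- function(labels, truth) {
  max(mean(labels == truth), mean((3 - labels) == truth))
}

# a small blob structure with a connected ANM/GNM contact graph
connectedBlob <- function(n = 20, seed = 3) {
  makeToyStructure(n, "blob", seed = seed, sigma = 6)
}

# independent Gaussian-splat of point masses onto an explicit grid; used
# both as the makeMapFromAtoms oracle and to build paired maps that share
# geometry exactly
splatOracle <- function(xyz, voxelSize, sigma, box, origin) {
  grid <- array(0, dim = c(box, box, box))
  for (i in seq_len(box)) for (j in seq_len(box)) for (k in seq_len(box)) {
    pos <- (c(i, j, k) - 1) * voxelSize + origin
    for (a in seq_len(nrow(xyz))) {
      grid[i, j, k] <- grid[i, j, k] +
        exp(-sum((pos - xyz[a, ])^2) / (2 * sigma^2))
    }
  }
  grid
}

# dense normal-equations least-squares oracle: (X^T X)^-1 X^T y
normalEquationsSolve <- function(X, y) {
  solve(crossprod(X), crossprod(X, as.matrix(y)))
}

# two-cluster conformer fixture: tight blobs (intra-RMSD ~ intraRmsd)
# separated by a non-rigid deformation of aligned RMSD ~ interRmsd
twoBlobStructures <- function(nPer = 5, p = 50, intraRmsd = 0.2,
                              interRmsd = 5, seed = 9) {
  set.seed(seed)
  base <- atomCoords(makeToyStructure(p, "blob", seed = seed, sigma = 8))
  shift <- matrix(stats::rnorm(3 * p, sd = interRmsd / sqrt(3)), p, 3)
  jitter <- function() matrix(stats::rnorm(3 * p, sd = intraRmsd / sqrt(3)), p, 3)
  c(lapply(seq_len(nPer), function(i) base + jitter()),
    lapply(seq_len(nPer), function(i) base + shift + jitter()))
}

# coefficient landscape whose two clusters differ only inside a region:
# per-row fields are a cluster-specific bump inside the region plus large
# random per-row motion outside it, fitted to a full-support basis
focusedLandscapeFixture <- function(nRows = 60, seed = 13) {
  atoms <- makeToyStructure(200, "two_domain", seed = 11, sigma = 9,
                            separation = 30)
  pts <- atomCoords(atoms)
  mask <- pts[, 1] > 0
  ctr <- colMeans(pts)
  rad <- max(sqrt(rowSums(sweep(pts, 2, ctr)^2))) * 1.1
  basis <- buildBasis(pts, ctr, rad, 3, 3)
  b <- basisSize(basis)
  wIn <- exp(-rowSums(sweep(pts, 2, c(15, 0, 0))^2) / (2 * 5^2))
  wOut <- exp(-rowSums(sweep(pts, 2, c(-15, 0, 0))^2) / (2 * 6^2))
  set.seed(seed)
  truth <- rep(1:2, length.out = nRows)
  dirs <- list(c(2, 0, 0), c(-2, 0, 0))
  rows <- matrix(0, nRows, 3 * b)
  for (i in seq_len(nRows)) {
    dirOut <- stats::rnorm(3)
    dirOut <- dirOut / sqrt(sum(dirOut^2)) * 6
    u <- outer(wIn, dirs[[truth[i]]]) + outer(wOut, dirOut)
    fit <- fitCoefficients(DeformationField(u, pts), basis)
    rows[i, ] <- as.vector(t(coefArray(fit)))
  }
  list(table = CoefficientTable(rows, lMax = 3, nMax = 3, radius = rad,
                                center = ctr),
       basis = basis, mask = mask, truth = truth)
}
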