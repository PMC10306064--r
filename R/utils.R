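# Internal numerical helpers shared across modules.

# Rank-revealing least squares via SVD. Returns the minimum-norm solution of
# min ||X b - y||^2 (+ lambda ||b||^2 when lambda > 0); y may be a matrix
# (one solve per column). Warns when X is rank deficient and lambda == 0.
lsSolve <- function(X, y, lambda = 0, warnRankDeficient = TRUE) {
  y <- as.matrix(y)
  sv <- svd(X)
  d <- sv$d
  tol <- max(dim(X)) * .Machine$double.eps * max(d, 0)
  if (lambda > 0) {
    # Tikhonov: filter factors d / (d^2 + lambda)
    f <- ifelse(d > tol, d / (d^2 + lambda), 0)
  } else {
    rank <- sum(d > tol)
    if (rank < ncol(X) && warnRankDeficient)
      warning(sprintf("design matrix rank deficient (rank %d < %d); returning minimum-norm solution",
                      rank, ncol(X)))
    f <- ifelse(d > tol, 1 / d, 0)
  }
  sv$v %*% (f * (t(sv$u) %*% y))
}

# Optimal rigid superposition (Kabsch): rotation R and translation t such
# that mobile %*% R + t best fits target in least squares. Proper rotation
# enforced (det = +1).
kabsch <- function(mobile, target) {
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  a <- sweep(mobile, 2, cm)
  b <- sweep(target, 2, ct)
  h <- crossprod(a, b)
  sv <- svd(h)
  s <- diag(c(1, 1, sign(det(sv$u %*% t(sv$v)))))
  r <- sv$u %*% s %*% t(sv$v)
  list(rotation = r, translation = as.numeric(ct - cm %*% r))
}

applyRigid <- function(coords, transform) {
  sweep(coords %*% transform$rotation, 2, transform$translation, "+")
}

# RMSD between corresponding coordinate sets, optionally after optimal
# rigid superposition of `a` onto `b`.
coordRmsd <- function(a, b, fit = TRUE) {
  if (fit) a <- applyRigid(a, kabsch(a, b))
  sqrt(mean(rowSums((a - b)^2)))
}

# Accumulate values at (possibly repeated) integer indices into a vector of
# length n: out[idx] gets the sum of the values mapping there.
accumulateAt <- function(values, idx, n) {
  out <- numeric(n)
  s <- rowsum(values, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# Trilinear interpolation of a 3D grid at fractional 0-based voxel
# coordinates (rows of `pts`); points outside the grid contribute 0.
trilinearSample <- function(grid, pts) {
  d <- dim(grid)
  i0 <- floor(pts)
  f <- pts - i0
  out <- numeric(nrow(pts))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- i0[, 1] + cx
    iy <- i0[, 2] + cy
    iz <- i0[, 3] + cz
    w <- (if (cx == 1) f[, 1] else 1 - f[, 1]) *
         (if (cy == 1) f[, 2] else 1 - f[, 2]) *
         (if (cz == 1) f[, 3] else 1 - f[, 3])
    ok <- ix >= 0 & ix < d[1] & iy >= 0 & iy < d[2] & iz >= 0 & iz < d[3] & w > 0
    if (any(ok)) {
      lin <- ix[ok] + d[1] * (iy[ok] + d[2] * iz[ok]) + 1
      out[ok] <- out[ok] + w[ok] * grid[lin]
    }
  }
  out
}

# ZYZ intrinsic rotation matrix from Euler angles in degrees (cryo-EM
# convention: rot about z, tilt about the new y, psi about the new z).
eulerZYZ <- function(rot, tilt, psi) {
  a <- rot * pi / 180
  b <- tilt * pi / 180
  g <- psi * pi / 180
  rz1 <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  rz2 <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3, 3)
  rz1 %*% ry %*% rz2
}

# Real-space coordinates (Angstrom) of every voxel center, P x 3 in grid
# (x fastest) order.
voxelCoordinates <- function(map) {
  d <- dim(map@grid)
  ix <- seq_len(d[1]) - 1
  iy <- seq_len(d[2]) - 1
  iz <- seq_len(d[3]) - 1
  cbind(
    rep(ix, times = d[2] * d[3]) * map@voxelSize + map@origin[1],
    rep(rep(iy, each = d[1]), times = d[3]) * map@voxelSize + map@origin[2],
    rep(iz, each = d[1] * d[2]) * map@voxelSize + map@origin[3]
  )
}

sameMapGeometry <- function(a, b) {
  identical(dim(a@grid), dim(b@grid)) &&
    isTRUE(all.equal(a@voxelSize, b@voxelSize)) &&
    isTRUE(all.equal(a@origin, b@origin))
}
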