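#' Number of Zernike basis functions for given degree bounds
#'
#' Counts the (l, n, m) triples with 0 <= l <= lMax, l <= n <= nMax,
#' n - l even, -l <= m <= l.
#'
#' @param lMax maximum angular degree l.
#' @param nMax maximum radial order n (must be >= lMax).
#' @return integer B.
#' @examples
#' zernikeBasisSize(2, 2)  # 10
#' @export
zernikeBasisSize <- function(lMax, nMax) {
  nrow(zernikeIndexSet(lMax, nMax))
}

#' Ordered (l, n, m) index set of the Zernike basis
#'
#' Column order of every basis matrix built by [buildBasis()]: triples are
#' sorted by l, then n, then m from -l to l.
#'
#' @inheritParams zernikeBasisSize
#' @return data.frame with integer columns `l`, `n`, `m`.
#' @export
zernikeIndexSet <- function(lMax, nMax) {
  lMax <- as.integer(lMax)
  nMax <- as.integer(nMax)
  if (lMax < 0L || nMax < 0L) stop("degree bounds must be non-negative")
  if (lMax > nMax) stop("lMax must not exceed nMax")
  rows <- list()
  for (l in 0:lMax) {
    ns <- seq(l, nMax, by = 2)
    for (n in ns) {
      rows[[length(rows) + 1L]] <-
        data.frame(l = l, n = n, m = seq(-l, l))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Jacobi polynomial P_k^(alpha, beta)(x) by the standard three-term
# recurrence; vectorized over x.
jacobiPoly <- function(k, alpha, beta, x) {
  if (k == 0L) return(rep(1, length(x)))
  pm1 <- rep(1, length(x))
  p <- (alpha - beta) / 2 + (alpha + beta + 2) / 2 * x
  if (k == 1L) return(p)
  for (j in 2:k) {
    c0 <- 2 * j * (j + alpha + beta) * (2 * j + alpha + beta - 2)
    c1 <- (2 * j + alpha + beta - 1) * (alpha^2 - beta^2)
    c2 <- (2 * j + alpha + beta - 1) * (2 * j + alpha + beta) *
          (2 * j + alpha + beta - 2)
    c3 <- 2 * (j + alpha - 1) * (j + beta - 1) * (2 * j + alpha + beta)
    pnew <- ((c1 + c2 * x) * p - c3 * pm1) / c0
    pm1 <- p
    p <- pnew
  }
  p
}

# Max |R_{n,l}| on [0,1] for the unnormalized radial polynomial, evaluated
# on a fixed dense grid: the deterministic normalization constant.
radialNormConstant <- function(n, l) {
  rho <- seq(0, 1, length.out = 4097)
  vals <- rho^l * jacobiPoly((n - l) %/% 2L, 0, l + 0.5, 2 * rho^2 - 1)
  max(abs(vals))
}

#' Canterakis 3D Zernike radial polynomial
#'
#' R_(n,l)(rho) proportional to rho^l * P^(0, l+1/2)_((n-l)/2)(2 rho^2 - 1),
#' scaled so that max over [0, 1] of |R_(n,l)| equals 1. Defined for
#' n >= l with n - l even.
#'
#' @param n radial order.
#' @param l angular degree.
#' @param rho radial coordinate(s) in [0, 1].
#' @return numeric vector of radial values.
#' @export
zernikeRadial <- function(n, l, rho) {
  if (n < l || (n - l) %% 2L != 0L)
    stop("radial polynomial requires n >= l with n - l even")
  raw <- rho^l * jacobiPoly((n - l) %/% 2L, 0, l + 0.5, 2 * rho^2 - 1)
  raw / radialNormConstant(n, l)
}

#' Real spherical harmonics at given directions
#'
#' Orthonormal real spherical harmonics y_(l,m)(theta, phi) without the
#' Condon-Shortley phase, ordered m = -l..l: negative m carry sin(|m| phi),
#' positive m carry cos(m phi).
#'
#' @param l angular degree.
#' @param theta polar angle(s), radians.
#' @param phi azimuthal angle(s), radians.
#' @return length(theta) x (2l + 1) matrix, one column per m.
#' @export
realSphericalHarmonics <- function(l, theta, phi) {
  np <- length(theta)
  if (l == 0L) return(matrix(1 / sqrt(4 * pi), np, 1))
  # pracma::legendre uses the MATLAB convention (Condon-Shortley included);
  # strip the (-1)^m phase.
  plm <- pracma::legendre(l, cos(theta))
  if (np == 1L) plm <- matrix(plm, ncol = 1)
  out <- matrix(0, np, 2L * l + 1L)
  for (m in 0:l) {
    norm <- sqrt((2 * l + 1) / (4 * pi) *
                 exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
    p <- (-1)^m * plm[m + 1L, ]
    if (m == 0L) {
      out[, l + 1L] <- norm * p
    } else {
      out[, l + 1L + m] <- sqrt(2) * norm * p * cos(m * phi)
      out[, l + 1L - m] <- sqrt(2) * norm * p * sin(m * phi)
    }
  }
  out
}

#' Build the Zernike basis at a point set
#'
#' Evaluates every basis function Z_(l,n,m)(r) = R_(n,l)(|r - center|/R) *
#' y_(l,m)(theta, phi) at the given points. Points outside the support ball
#' (|r - center| > radius) get all-zero rows, matching masked-map usage
#' where the mask defines the valid positions.
#'
#' @param points P x 3 matrix (Angstrom) or an [AtomSet-class].
#' @param center 3-vector, center of the support ball (Angstrom).
#' @param radius support-ball radius R (Angstrom), > 0.
#' @param lMax,nMax degree bounds, lMax <= nMax.
#' @return a [ZernikeBasis-class].
#' @examples
#' pts <- matrix(rnorm(60), 20, 3)
#' b <- buildBasis(pts, center = c(0, 0, 0), radius = 5, lMax = 2, nMax = 2)
#' basisSize(b)  # 10
#' @export
buildBasis <- function(points, center, radius, lMax, nMax) {
  if (is(points, "AtomSet")) points <- atomCoords(points)
  points <- as.matrix(points)
  if (radius <= 0) stop("radius must be positive")
  lMax <- as.integer(lMax)
  nMax <- as.integer(nMax)
  if (lMax > nMax) stop("lMax must not exceed nMax")
  center <- as.numeric(center)

  idx <- zernikeIndexSet(lMax, nMax)
  p <- nrow(points)
  rel <- sweep(points, 2, center)
  r <- sqrt(rowSums(rel^2))
  rho <- r / radius
  inside <- rho <= 1
  # angles; degenerate r = 0 mapped to the pole (harmonics there are exact:
  # only m = 0 survives and P_l^0(1) handles it)
  theta <- ifelse(r > 0, acos(pmin(1, pmax(-1, rel[, 3] / pmax(r, .Machine$double.eps)))), 0)
  phi <- atan2(rel[, 2], rel[, 1])

  Z <- matrix(0, p, nrow(idx))
  if (any(inside)) {
    th <- theta[inside]
    ph <- phi[inside]
    rh <- rho[inside]
    for (l in unique(idx$l)) {
      y <- realSphericalHarmonics(l, th, ph)
      for (n in unique(idx$n[idx$l == l])) {
        rad <- zernikeRadial(n, l, rh)
        cols <- which(idx$l == l & idx$n == n)
        Z[inside, cols] <- rad * y
      }
    }
  }
  new("ZernikeBasis", points = points, center = center,
      radius = as.numeric(radius), lMax = lMax, nMax = nMax,
      indexSet = idx, Z = Z)
}
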