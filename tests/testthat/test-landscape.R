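# Landscape toolbox: motion statistics, RMSD clustering, view selection,
# reduction and k-means representatives.

test_that("motion statistics match the brute-force per-point oracle", {
  fx <- reassignmentBasis <- local({
    atoms <- makeToyStructure(40, "blob", seed = 101, sigma = 6)
    pts <- atomCoords(atoms)
    ctr <- colMeans(pts)
    rad <- max(sqrt(rowSums(sweep(pts, 2, ctr)^2))) * 1.2
    list(basis = buildBasis(pts, ctr, rad, 2, 2), ctr = ctr, rad = rad)
  })
  centers <- list(makeRandomCoeffs(2, 2, fx$rad, center = fx$ctr, seed = 102),
                  makeRandomCoeffs(2, 2, fx$rad, center = fx$ctr, seed = 103))
  tab <- makeLandscapeTable(100, centers, noiseSigma = 0.3, seed = 104)$table
  st <- motionStatistics(tab, fx$basis)
  # brute-force loop over rows and points
  z <- basisMatrix(fx$basis)
  p <- nrow(z)
  fields <- lapply(seq_len(100), function(i)
    z %*% t(coefArray(tableRowCoefficients(tab, i))))
  for (pt in c(1, 7, p)) {
    us <- t(vapply(fields, function(f) f[pt, ], numeric(3)))
    expect_equal(st$mean[pt, ], colMeans(us), tolerance = 1e-10)
    expect_equal(st$std[pt],
                 sqrt(mean(rowSums(sweep(us, 2, colMeans(us))^2))),
                 tolerance = 1e-10)
  }
  expect_true(all(st$std >= 0))
})

test_that("motion statistics degenerate cases: identical and mirrored rows", {
  atoms <- makeToyStructure(30, "blob", seed = 105, sigma = 6)
  pts <- atomCoords(atoms)
  ctr <- colMeans(pts)
  rad <- max(sqrt(rowSums(sweep(pts, 2, ctr)^2))) * 1.2
  basis <- buildBasis(pts, ctr, rad, 2, 2)
  a <- makeRandomCoeffs(2, 2, rad, center = ctr, seed = 106)
  row <- as.vector(t(coefArray(a)))
  same <- CoefficientTable(rbind(row, row, row), lMax = 2, nMax = 2,
                           radius = rad, center = ctr)
  st <- motionStatistics(same, basis)
  expect_equal(max(st$std), 0, tolerance = 1e-12)
  expect_equal(st$mean, basisMatrix(basis) %*% t(coefArray(a)),
               tolerance = 1e-12, ignore_attr = TRUE)
  pm <- CoefficientTable(rbind(row, -row), lMax = 2, nMax = 2,
                         radius = rad, center = ctr)
  st2 <- motionStatistics(pm, basis)
  expect_equal(max(abs(st2$mean)), 0, tolerance = 1e-12)
  uA <- basisMatrix(basis) %*% t(coefArray(a))
  expect_equal(st2$std, sqrt(rowSums(uA^2)), tolerance = 1e-10)
  expect_error(motionStatistics(
    CoefficientTable(matrix(0, 0, 30), lMax = 2, nMax = 2, radius = rad),
    basis), "empty")
})

test_that("RMSD clustering separates two blobs and respects the cutoff", {
  s <- twoBlobStructures()
  res <- rmsdCluster(s, cutoff = 1)
  expect_equal(res$nClusters, 2L)
  expect_equal(res$labels, rep(1:2, each = 5))
  for (i in seq_along(s)) {
    expect_lte(coordRmsd <- sqrt(mean(rowSums((
      FlexField:::applyRigid(as.matrix(s[[i]]),
        FlexField:::kabsch(as.matrix(s[[i]]),
                           res$representatives[[res$labels[i]]])) -
        res$representatives[[res$labels[i]]])^2))), 1)
  }
  # degenerate cutoffs
  expect_equal(rmsdCluster(s, cutoff = 1e6)$nClusters, 1L)
  expect_equal(rmsdCluster(s, cutoff = 1e-9)$nClusters, length(s))
  # partition property: every structure in exactly one cluster
  expect_setequal(unique(res$labels), 1:2)
  expect_equal(length(res$labels), length(s))
})

test_that("identical maps and affine rescalings give unit view correlation", {
  atoms <- connectedBlob(15, seed = 107)
  map <- makeMapFromAtoms(atoms, voxelSize = 1.5, sigma = 2, box = 24)
  grid <- list(rot = seq(0, 315, by = 45), tilt = seq(0, 180, by = 30))
  h <- bestViewHeatmap(map, map, grid$rot, grid$tilt)
  expect_true(all(abs(h - 1) < 1e-6))
  aff <- VoxelMap(2 * mapGrid(map) + 3, voxelSize(map), mapOrigin(map))
  h2 <- bestViewHeatmap(map, aff, grid$rot, grid$tilt)
  expect_true(all(abs(h2 - 1) < 1e-6))
})

test_that("view heatmaps are symmetric and spot lobe motion along z", {
  # shared-geometry pair: common blob at the center, lobe at z = 8 vs 13
  box <- 24
  origin <- -(box - 1) / 2 * rep(1, 3)
  ga <- splatGrid <- function(xyz) {
    ax <- (seq_len(box) - 1) + origin[1]
    g <- array(0, dim = rep(box, 3))
    for (i in seq_len(nrow(xyz))) {
      gx <- exp(-(ax - xyz[i, 1])^2 / 8)
      gy <- exp(-(ax - xyz[i, 2])^2 / 8)
      gz <- exp(-(ax - xyz[i, 3])^2 / 8)
      g <- g + outer(outer(gx, gy), gz)
    }
    g
  }
  mapA <- VoxelMap(splatGrid(rbind(c(0, 0, 0), c(0, 0, 8))), 1, origin)
  mapB <- VoxelMap(splatGrid(rbind(c(0, 0, 0), c(0, 0, 13))), 1, origin)
  hab <- bestViewHeatmap(mapA, mapB, c(0, 90, 180), c(0, 45, 90))
  hba <- bestViewHeatmap(mapB, mapA, c(0, 90, 180), c(0, 45, 90))
  expect_equal(hab, hba, tolerance = 1e-10)
  # axial views hide motion along z; equatorial views expose it
  expect_true(all(hab[, "0"] > hab[, "90"]))
  # 90-degree in-plane rotation equals an exact index-permutation oracle
  # (voxel centers map onto voxel centers for quarter turns about z)
  src <- mapGrid(mapA)
  rot90 <- FlexField:::rotateMapGrid(src, 90, 0, 0)
  cw <- array(0, dim = dim(src))
  ccw <- array(0, dim = dim(src))
  for (i in seq_len(box)) for (j in seq_len(box)) {
    cw[i, j, ] <- src[j, box + 1 - i, ]
    ccw[i, j, ] <- src[box + 1 - j, i, ]
  }
  expect_lt(min(max(abs(rot90 - cw)), max(abs(rot90 - ccw))), 1e-12)
})

test_that("view-based particle selection keeps exactly the requested cells", {
  atoms <- makeToyStructure(20, "blob", seed = 108, sigma = 5)
  ctr <- colMeans(atomCoords(atoms))
  rad <- 20
  centers <- list(makeRandomCoeffs(2, 2, rad, center = ctr, seed = 109))
  tab <- makeLandscapeTable(40, centers, noiseSigma = 0.1, seed = 110)$table
  # synthetic heatmap over a coarse grid: two known-good (low r) cells
  h <- matrix(0.9, 4, 3, dimnames = list(rot = c(0, 90, 180, 270),
                                         tilt = c(0, 90, 180)))
  h["90", "90"] <- 0.1
  h["270", "90"] <- 0.2
  expect_equal(particleCount(selectParticlesByView(tab, h, 1)), 40L)
  expect_equal(particleCount(selectParticlesByView(tab, h, 0.05)), 0L)
  # place specific particles into the two good cells
  info <- particleInfo(tab)
  info$rot <- rep(0, 40); info$tilt <- rep(0, 40)
  info$rot[c(3, 9)] <- c(91, 268)   # wrap/nearest-cell resolution
  info$tilt[c(3, 9)] <- c(88, 95)
  tab2 <- new("CoefficientTable", particles = info, coeffs = coefRows(tab),
              lMax = tab@lMax, nMax = tab@nMax, radius = tab@radius,
              center = tab@center, referenceId = tab@referenceId)
  kept <- selectParticlesByView(tab2, h, 0.5)
  expect_identical(particleInfo(kept)$particle_id,
                   particleInfo(tab)$particle_id[c(3, 9)])
})

test_that("PCA landscape reduction is rank-aware and contractive", {
  atoms <- makeToyStructure(20, "blob", seed = 111, sigma = 5)
  ctr <- colMeans(atomCoords(atoms))
  a <- makeRandomCoeffs(2, 2, 20, center = ctr, seed = 112)
  row <- as.vector(t(coefArray(a)))
  # rows on a line in coefficient space: second embedding axis collapses
  lineRows <- outer(seq(-2, 2, length.out = 9), row)
  lineTab <- CoefficientTable(lineRows, lMax = 2, nMax = 2, radius = 20,
                              center = ctr)
  emb <- reduceLandscape(lineTab, 2)$embedding
  expect_lt(max(abs(emb[, 2])), 1e-8)
  expect_gt(stats::sd(emb[, 1]), 0)
  # more dimensions than members can support
  tiny <- CoefficientTable(lineRows[1:3, ], lMax = 2, nMax = 2, radius = 20,
                           center = ctr)
  expect_error(reduceLandscape(tiny, 3), "rank")
})

test_that("landscape embeddings preserve cluster structure and distances", {
  atoms <- makeToyStructure(20, "blob", seed = 113, sigma = 5)
  ctr <- colMeans(atomCoords(atoms))
  centers <- list(makeRandomCoeffs(2, 2, 20, center = ctr, magnitude = 2,
                                   seed = 114),
                  makeRandomCoeffs(2, 2, 20, center = ctr, magnitude = 2,
                                   seed = 115))
  fx <- makeLandscapeTable(80, centers, noiseSigma = 0.1, seed = 116)
  red <- reduceLandscape(fx$table, 2)
  # contraction: embedded distances never exceed coefficient-space ones
  X <- coefRows(fx$table)
  idx <- cbind(c(1, 5, 20), c(50, 60, 79))
  for (r in seq_len(nrow(idx))) {
    dEmb <- sqrt(sum((red$embedding[idx[r, 1], ] - red$embedding[idx[r, 2], ])^2))
    dFull <- sqrt(sum((X[idx[r, 1], ] - X[idx[r, 2], ])^2))
    expect_lte(dEmb, dFull + 1e-10)
  }
  set.seed(1)
  km <- stats::kmeans(red$embedding, 2, nstart = 10)
  expect_gte(labelAgreement2(km$cluster, fx$labels), 0.98)
})

test_that("k-means representatives match degenerate and oracle cases", {
  atoms <- makeToyStructure(20, "blob", seed = 117, sigma = 5)
  ctr <- colMeans(atomCoords(atoms))
  centers <- list(makeRandomCoeffs(2, 2, 20, center = ctr, magnitude = 2, seed = 118),
                  makeRandomCoeffs(2, 2, 20, center = ctr, magnitude = 2, seed = 119),
                  makeRandomCoeffs(2, 2, 20, center = ctr, magnitude = 2, seed = 120))
  fx <- makeLandscapeTable(30, centers, noiseSigma = 0.05, seed = 121)
  # k = 1: center is the mean row
  one <- kmeansRepresentatives(fx$table, 1, seed = 1)
  expect_equal(as.numeric(coefRows(one$centers)),
               colMeans(coefRows(fx$table)), tolerance = 1e-10)
  # k = M: every row its own center
  allk <- kmeansRepresentatives(fx$table, 30, seed = 1)
  expect_equal(sort(allk$labels), 1:30)
  expect_equal(allk$inertia, 0, tolerance = 1e-10)
  # well-separated clusters: inertia matches a best-of-20 restart oracle
  res <- kmeansRepresentatives(fx$table, 3, seed = 2)
  set.seed(99)
  oracle <- stats::kmeans(coefRows(fx$table), 3, nstart = 20, iter.max = 100)
  expect_lte(abs(res$inertia - oracle$tot.withinss),
             0.01 * oracle$tot.withinss)
  expect_error(kmeansRepresentatives(fx$table, 31), "exceed")
})
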