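# IDSS and baseline descriptors: PDF invariants, deformation behavior,
# rotation invariance, convergence.

makeDescribed <- function() {
  rod <- makeSyntheticShape("rod", length = 40, radius = 3, sourceId = "rod")
  bent <- makeSyntheticShape("bent_rod", length = 40, radius = 3,
                             angle = 60, sourceId = "bent")
  sph <- makeSyntheticShape("sphere", radius = 7, sourceId = "sph")
  list(rod = rod, bent = bent, sph = sph,
       d = lapply(list(rod = rod, bent = bent, sph = sph), function(g)
         describeGrid(g, methods = c("IDSS", "D2"), seed = 21)))
}
fixtures <- makeDescribed()

test_that("histogram descriptors are probability densities", {
  g <- fixtures$rod
  descs <- describeGrid(g, methods = c("IDSS", "D2", "GD", "SD", "SAH"),
                        seed = 4)
  for (m in names(descs)) {
    expect_true(all(descriptorBins(descs[[m]]) >= 0))
    expect_lt(abs(sum(descriptorBins(descs[[m]])) - 1), 1e-9)
  }
})

test_that("identical distances put all mass in the top bin", {
  ds <- new("InnerDistanceSet", values = rep(7.5, 6), n = 4L,
            sourceId = "const")
  d <- idssDescriptor(ds, B = 32L)
  expect_equal(descriptorBins(d)[32], 1)
  expect_equal(sum(descriptorBins(d)), 1)
})

test_that("fixed_range rejects a range smaller than the data", {
  ds <- new("InnerDistanceSet", values = c(1, 2, 10), n = 3L, sourceId = "x")
  expect_error(idssDescriptor(ds, mode = "fixed_range", dMax = 5), "smaller")
  d <- idssDescriptor(ds, mode = "fixed_range", dMax = 10)
  expect_equal(sum(descriptorBins(d)), 1)
})

test_that("IDSS keeps conformers together better than it keeps shapes apart", {
  d <- fixtures$d
  l1 <- function(a, b, m) similarity(d[[a]][[m]], d[[b]][[m]])$l1
  expect_lt(l1("rod", "bent", "IDSS"), l1("rod", "sph", "IDSS"))
  # the chord-based D2 moves more under articulation than the IDSS does
  expect_gt(l1("rod", "bent", "D2"), l1("rod", "bent", "IDSS"))
})

test_that("on a convex body D2 and IDSS nearly coincide", {
  d <- describeGrid(fixtures$sph, methods = c("IDSS", "D2"), seed = 8)
  # voxel-path lengths carry direction-dependent metrication error (up to
  # ~13% over the chord), which smears the fine 128-bin histogram; the two
  # distributions still sit far closer to each other than to a different
  # shape's signature
  gap <- sum(abs(descriptorBins(d$IDSS) - descriptorBins(d$D2)))
  expect_lt(gap, 0.6)
  contrast <- similarity(fixtures$d$rod$IDSS, fixtures$d$sph$IDSS)$l1
  expect_lt(gap, contrast)
})

test_that("SD is seeded and converges to dense D2 on a sphere", {
  g <- makeSyntheticShape("sphere", radius = 8, sourceId = "sph8")
  surf <- extractSurface(g)
  s1 <- sdDescriptor(surf, nPairs = 1000, seed = 5)
  s2 <- sdDescriptor(surf, nPairs = 1000, seed = 5)
  expect_identical(descriptorBins(s1), descriptorBins(s2))
  dense <- d2Descriptor(lloydSample(surf, nrow(surfaceIndices(surf))))
  sd50k <- sdDescriptor(surf, nPairs = 50000, seed = 6)
  expect_lt(sum(abs(descriptorBins(sd50k) - descriptorBins(dense))), 0.05)
})

test_that("GD hugs the IDSS on a thin rod and fails on split surfaces", {
  g <- makeSyntheticShape("rod", length = 40, radius = 3, sourceId = "thin")
  surf <- extractSurface(g)
  s <- lloydSample(surf, 64, seed = 2)
  gd <- gdDescriptor(surf, s)
  vg <- buildVoxelGraph(g)
  idss <- idssDescriptor(allPairsInnerDistances(vg, s))
  expect_lt(sum(abs(descriptorBins(gd) - descriptorBins(idss))), 0.35)
  # internal cavity: its wall is surface but unreachable along the surface
  occ <- array(TRUE, c(7, 7, 7)); occ[4, 4, 4] <- FALSE
  cav <- gridFromArray(occ, "cavity")
  surfC <- extractSurface(cav)
  idx <- surfaceIndices(surfC)
  inner <- which(rowSums(abs(sweep(idx, 2, c(4, 4, 4)))) == 1)[1]
  outer_ <- which(idx[, 1] == 1)[1]
  sp <- new("SamplePoints", indices = idx[c(inner, outer_), ], grid = cav,
            seed = 1L)
  expect_error(gdDescriptor(surfC, sp), "disconnect")
})

test_that("SHD concentrates energy at l = 0 for a centered ball", {
  g <- makeSyntheticShape("sphere", radius = 8)
  d <- shdDescriptor(g)
  e <- matrix(descriptorBins(d), ncol = 17, byrow = TRUE)  # shells x l
  # shells strictly inside the ball sample a constant function: their
  # l >= 1 coefficients vanish to machine precision (exact quadrature)
  inner <- e[1:24, , drop = FALSE]
  expect_lt(sum(inner[, -1]^2) / sum(inner^2), 1e-12)
  # the jagged voxel boundary contributes a little anisotropy on the
  # outermost shells; overall it stays below 1% of the energy
  expect_lt(sum(e[, -1]^2) / sum(e^2), 0.01)
})

test_that("descriptors are exactly invariant under 90-degree rotation", {
  g <- makeSyntheticShape("bent_rod", length = 30, radius = 4, angle = 50,
                          sourceId = "b")
  occ <- occupancy(g)
  d <- dim(occ)
  rot <- array(FALSE, c(d[2], d[1], d[3]))  # (i, j) -> (j, d1 + 1 - i)
  for (k in seq_len(d[3])) rot[, , k] <- t(occ[rev(seq_len(d[1])), , k])
  g2 <- gridFromArray(rot, "b")
  # landmark-free descriptors must match to machine precision
  expect_equal(descriptorBins(sahDescriptor(g2)),
               descriptorBins(sahDescriptor(g)), tolerance = 1e-12)
  expect_equal(descriptorBins(shdDescriptor(g2)),
               descriptorBins(shdDescriptor(g)), tolerance = 1e-9)
  # landmark descriptors match when the landmarks rotate with the shape
  s <- lloydSample(extractSurface(g), 48, seed = 13)
  idx <- samplePoints(s)
  idxRot <- cbind(idx[, 2], d[1] + 1L - idx[, 1], idx[, 3])
  sRot <- new("SamplePoints", indices = idxRot, grid = g2, seed = 13L)
  expect_equal(
    descriptorBins(d2Descriptor(sRot)),
    descriptorBins(d2Descriptor(s)), tolerance = 1e-12)
  expect_equal(
    descriptorBins(idssDescriptor(
      allPairsInnerDistances(buildVoxelGraph(g2), sRot))),
    descriptorBins(idssDescriptor(
      allPairsInnerDistances(buildVoxelGraph(g), s))), tolerance = 1e-12)
})

test_that("descriptors are stable under arbitrary rotation + revoxelization", {
  g1 <- makeSyntheticShape("bent_rod", length = 30, radius = 4, angle = 50)
  g2 <- makeSyntheticShape("bent_rod", length = 30, radius = 4, angle = 50,
                           rotate = c(33, 61, 17))
  d1 <- describeGrid(g1, methods = c("IDSS", "SHD"), seed = 31)
  d2 <- describeGrid(g2, methods = c("IDSS", "SHD"), seed = 31)
  expect_lt(similarity(d1$IDSS, d2$IDSS)$l1, 0.2)
  expect_lt(sqrt(sum((descriptorBins(d1$SHD) -
                        descriptorBins(d2$SHD))^2)), 0.1)
})

test_that("IDSS in per-shape-max mode is scale invariant", {
  g1 <- makeSyntheticShape("bent_rod", length = 24, radius = 3, angle = 40)
  g2 <- makeSyntheticShape("bent_rod", length = 48, radius = 6, angle = 40)
  d1 <- describeGrid(g1, methods = "IDSS", seed = 17)$IDSS
  d2 <- describeGrid(g2, methods = "IDSS", seed = 17)$IDSS
  expect_lt(similarity(d1, d2)$l1, 0.25)  # discretization tolerance
})

test_that("SAH separates flat, convex and concave neighborhoods", {
  # large slab: surface voxels away from the rim see a discrete half-space
  # whose ball-occupancy fraction is (N + A) / (2N): exactly half the ball
  # plus the voxel's own lattice plane (A plane voxels of N in the ball)
  off <- as.matrix(expand.grid(-4:4, -4:4, -4:4))
  off <- off[rowSums(off^2) <= 16 + 1e-9, ]
  hs <- (sum(off[, 3] < 0) + sum(off[, 3] == 0)) / nrow(off)
  slab <- blockGrid(30, 30, 12, margin = 5, id = "slab")
  d <- sahDescriptor(slab, ballRadius = 4L, B = 64L)
  bins <- descriptorBins(d)
  win <- which(abs((seq_len(64) - 0.5) / 64 - hs) <= 0.06)
  expect_gte(sum(bins[win]), 0.6)  # fractions cluster at the flat value
  expect_equal(which.max(bins), floor(hs * 64) + 1)
  # dumbbell: ball ends are convex (< 0.5), the neck junction is concave
  db <- makeSyntheticShape("dumbbell", radius = 7, radius2 = 7,
                           neckRadius = 2.5, sep = 22, sourceId = "db")
  f <- sahDescriptor(db, ballRadius = 4L, B = 64L)
  bins <- descriptorBins(f)
  expect_gt(sum(bins[1:32]), 0)    # fractions below 0.5
  expect_gt(sum(bins[34:64]), 0)   # fractions above 0.5
})

test_that("descriptor JSON round-trips bit-exactly", {
  d <- fixtures$d$rod$IDSS
  f <- tempfile(fileext = ".json")
  writeDescriptor(d, f)
  d2 <- readDescriptor(f)
  expect_identical(descriptorBins(d2), descriptorBins(d))
  expect_identical(d2@dMax, d@dMax)
  expect_identical(d2@method, "IDSS")
})
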