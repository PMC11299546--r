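test_that("gyrification recovers analytic curvature and its scaling law", {
  ## interior of a flat patch is (near) zero
  pm <- planeMesh(25, 1)
  g <- scalarValues(gyrification(pm, average_fwhm_mm = 0))
  inner <- abs(meshVertices(pm)[, 1]) < 6 & abs(meshVertices(pm)[, 2]) < 6
  expect_lt(max(g[inner]), 1e-3)
  ## sphere of radius 12: |H| = 1/12 within 2%
  sph <- icosphere(4, 12)
  gs <- scalarValues(gyrification(sph))
  expect_lt(abs(mean(gs) - 1 / 12) * 12, 0.02)
  ## |H| scales as 1/s under uniform scaling
  sph2 <- icosphere(4, 24)
  expect_lt(abs(mean(scalarValues(gyrification(sph2))) * 24 - 1), 0.02)
})

test_that("sulcal depth vanishes on convex meshes and measures dents", {
  sph <- icosphere(3, 12)
  d0 <- scalarValues(sulcalDepth(sph))
  expect_lt(max(d0), 1e-3)
  expect_true(all(d0 >= 0))
  ## inward dent: depth to the hull cap is D - R(1 - cos(alpha))
  v <- meshVertices(sph)
  ang <- acos(pmin(1, v %*% c(0, 0, 1) / 12))
  alpha <- 0.32; D <- 5
  dent <- ifelse(ang < alpha, D * cos(pi * ang / (2 * alpha))^2, 0)
  vd <- v * as.vector(1 - dent / 12)
  dm <- brainmorph:::surfaceMesh(vd, meshFaces(sph))
  dd <- scalarValues(sulcalDepth(dm))
  expected <- D - 12 * (1 - cos(alpha))
  expect_lt(abs(max(dd) - expected) / expected, 0.05)
  ## sqrt transform flag
  ds <- scalarValues(sulcalDepth(dm, sqrt_transform = TRUE))
  expect_equal(ds, sqrt(dd), tolerance = 1e-9)
})

test_that("spherical parameterization is faithful and fold-robust", {
  ## an already-spherical mesh maps to itself (up to radial projection)
  sph <- icosphere(3, 7)
  mp <- sphericalParameterize(sph)
  expect_lt(max(abs(mp@areaDistortion - 1)), 0.01)
  expect_true(all(abs(sqrt(rowSums(mp@coords^2)) - 1) < 1e-8))
  ## folded phantom: bijective (no flipped spherical triangles), bounded
  ## distortion for moderate folds
  m2 <- foldedMesh(2)
  mp2 <- sphericalParameterize(m2)
  expect_identical(brainmorph:::sphereFlippedFaces(mp2, meshFaces(m2)), 0L)
  expect_lt(median(mp2@areaDistortion), 2)
  expect_gt(median(mp2@areaDistortion), 0.5)
  ## genus > 0 is rejected
  bad <- new("SurfaceMesh", vertices = meshVertices(sph),
             faces = meshFaces(sph), eulerCharacteristic = 0L, genus = 1L)
  expect_error(sphericalParameterize(bad), "genus")
})

test_that("fractal dimension is 2 for spheres and grows with folding", {
  sph <- icosphere(4, 12)
  mp <- sphericalParameterize(sph)
  fd <- fractalDimension(sph, mp)
  expect_lt(abs(as.numeric(fd) - 2), 0.05)
  ## scale invariance
  sph2 <- icosphere(4, 24)
  fd2 <- fractalDimension(sph2, sphericalParameterize(sph2))
  expect_lt(abs(as.numeric(fd) - as.numeric(fd2)), 0.01)
  ## monotone in fold amplitude at fixed frequency
  m2 <- foldedMesh(2); m4 <- foldedMesh(4)
  f2 <- fractalDimension(m2, sphericalParameterize(m2))
  f4 <- fractalDimension(m4, sphericalParameterize(m4))
  expect_gt(as.numeric(f4), as.numeric(f2))
  expect_gt(as.numeric(f2), 2)
  expect_error(fractalDimension(sph, mp, l_max = 6), "l_max")
})

test_that("surface ratio is 1 on planes, > 1 in folds, and matches MC", {
  pm <- planeMesh(41, 1)
  ctr_idx <- which(meshVertices(pm)[, 1] == 0 & meshVertices(pm)[, 2] == 0)
  sr <- scalarValues(surfaceRatio(pm, radius_mm = 10, vertices = ctr_idx))
  expect_lt(abs(sr - 1), 0.01)
  ## folded phantom: sulcal vertices exceed 1
  m4 <- foldedMesh(4)
  set.seed(31)
  vs <- sample(nrow(meshVertices(m4)), 20)
  r4 <- scalarValues(surfaceRatio(m4, radius_mm = 8, vertices = vs))
  expect_gt(mean(r4), 1)
  ## Monte-Carlo oracle: sample points uniformly on faces, count in-ball
  mcRatio <- function(mesh, vidx, r, n = 200000) {
    v <- meshVertices(mesh); f <- meshFaces(mesh)
    fa <- brainmorph:::meshFaceAreas(v, f)
    pick <- sample(nrow(f), n, TRUE, prob = fa)
    u1 <- runif(n); u2 <- runif(n)
    s <- sqrt(u1)
    p <- (1 - s) * v[f[pick, 1], ] + s * (1 - u2) * v[f[pick, 2], ] +
      s * u2 * v[f[pick, 3], ]
    ctr <- v[vidx, ]
    inb <- rowSums(sweep(p, 2, ctr)^2) <= r^2
    sum(fa) * mean(inb) / (pi * r^2)
  }
  set.seed(17)
  for (vi in vs[1:5]) {
    mc <- mcRatio(m4, vi, 8)
    mine <- scalarValues(surfaceRatio(m4, 8, vi))
    expect_lt(abs(mine - mc) / mc, 0.02)
  }
})

test_that("folding metrics are invariant to rigid motion and reindexing", {
  m2 <- foldedMesh(2)
  v <- meshVertices(m2); f <- meshFaces(m2)
  ## random rotation + translation
  set.seed(3)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_); if (det(R) < 0) R[, 1] <- -R[, 1]
  vr <- v %*% R + matrix(c(5, -3, 2), nrow(v), 3, byrow = TRUE)
  mr <- brainmorph:::surfaceMesh(vr, f)
  expect_equal(mean(scalarValues(gyrification(mr))),
               mean(scalarValues(gyrification(m2))), tolerance = 1e-6)
  expect_equal(mean(scalarValues(sulcalDepth(mr))),
               mean(scalarValues(sulcalDepth(m2))), tolerance = 1e-3)
  ## vertex reindexing permutation
  perm <- sample(nrow(v))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  mp_ <- brainmorph:::surfaceMesh(v[perm, ], matrix(inv[f], ncol = 3))
  expect_equal(sort(scalarValues(gyrification(mp_))),
               sort(scalarValues(gyrification(m2))), tolerance = 1e-9)
})

test_that("all four metrics detect a planted folding increase", {
  m2 <- foldedMesh(2); m4 <- foldedMesh(4)
  expect_gt(mean(scalarValues(gyrification(m4))),
            mean(scalarValues(gyrification(m2))))
  expect_gt(mean(scalarValues(sulcalDepth(m4))),
            mean(scalarValues(sulcalDepth(m2))))
  set.seed(5)
  v2 <- sample(nrow(meshVertices(m2)), 25)
  v4 <- sample(nrow(meshVertices(m4)), 25)
  expect_gt(mean(scalarValues(surfaceRatio(m4, 8, v4))),
            mean(scalarValues(surfaceRatio(m2, 8, v2))))
  ## FD covered in the fractal-dimension block above
})
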