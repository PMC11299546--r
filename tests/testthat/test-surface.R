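test_that("boundary distances respect analytic shell geometry", {
  surf <- shellSurface()
  bd <- surf$bd
  gm <- bd$gm_mask
  wmd <- volData(bd$wmd); csfd <- volData(bd$csfd)
  ## metric inequality: wmd + csfd >= WM-CSF separation (= 4 mm shell)
  expect_gt(min((wmd + csfd)[gm]), 4 * 0.8)
  ## GM voxels adjacent to WM carry sub-voxel distances
  pl <- volData(surf$seg@pveLabel)
  near_wm <- gm & array(volData(bd$wmd_signed) < 1, dim(pl))
  expect_lt(mean(wmd[gm & wmd < 1]), 1)
  ## errors without GM
  z <- Volume(array(0, c(8, 8, 8)))
  empty <- new("PveSegmentation", prob = list(csf = z, gm = z, wm = z),
               pveLabel = z, gmFraction = z)
  expect_error(boundaryDistances(empty), "no GM")
})

test_that("csfd equals the analytic distance for an all-GM ball", {
  ## ball of GM radius 9 in CSF: csfd = 9 - rho within half a voxel
  dm <- c(28, 28, 28)
  proto <- Volume(array(0, dm))
  w <- brainmorph:::worldGrid(proto)
  rho <- sqrt(rowSums(w^2))
  fgm <- Volume(array(pmin(1, pmax(0, 9.5 - rho)), dm),
                affine = volAffine(proto))
  ## distance to the 0.5 level of the gm fraction (boundary at rho = 9)
  f_if <- brainmorph:::interfaceDistance(fgm, query_mask = volData(fgm) >= 0.5)
  inside <- volData(fgm) >= 0.5 & array(rho < 8, dm)
  err <- f_if$dist[inside] - (9 - rho[inside])
  expect_lt(max(abs(err)), 0.5)
})

test_that("PBT recovers the shell thickness and its invariants", {
  surf <- shellSurface()
  th <- volData(surf$pbt$thickness)
  gm <- surf$bd$gm_mask
  expect_lt(abs(mean(th[gm]) - 4), 0.2)
  expect_true(all(th >= 0))
  ## thickness never exceeds wmd + csfd
  expect_true(all(th[gm] <= (volData(surf$bd$wmd) +
                               volData(surf$bd$csfd))[gm] + 1e-6))
})

test_that("a blurred sulcus inherits the banks' thickness, not the double", {
  ## two 4-mm GM slabs between WM plates; the CSF gap between them is
  ## visible for y < 0 and blurred (partial volume, invisible) for y >= 0
  dm <- c(20, 20, 14)
  proto <- Volume(array(0, dm))
  fgm <- array(0, dm); fcsf <- array(0, dm); fwm <- array(0, dm)
  for (k in 1:14) {
    if (k <= 2 || k >= 12) fwm[, , k] <- 1
    else if (k == 7) {
      fcsf[, 1:10, k] <- 1                      # visible half
      fcsf[, 11:20, k] <- 0.4                   # blurred half
      fgm[, 11:20, k] <- 0.6
    } else fgm[, , k] <- 1
  }
  aff <- volAffine(proto)
  seg <- new("PveSegmentation",
             prob = list(csf = Volume(fcsf, affine = aff),
                         gm = Volume(fgm, affine = aff),
                         wm = Volume(fwm, affine = aff)),
             pveLabel = Volume(fwm * 3 + (fgm >= 0.5) * 2 + (fcsf >= 0.5) * 1,
                               affine = aff),
             gmFraction = Volume(fgm, affine = aff))
  bd <- boundaryDistances(seg)
  pbt <- pbtThickness(bd$wmd, bd$csfd, bd$gm_mask,
                      wmd_signed = bd$wmd_signed)
  th <- volData(pbt$thickness)
  ## blurred-side voxels away from the lateral borders
  blur <- array(FALSE, dm); blur[5:16, 13:18, 3:6] <- TRUE
  blur <- blur & bd$gm_mask
  naive <- (volData(bd$wmd) + volData(bd$csfd))[blur]
  expect_gt(mean(naive), 1.5 * 4)          # the naive value is inflated
  expect_lt(abs(mean(th[blur]) - 4) / 4, 0.1)  # PBT stays near 4 mm
})

test_that("central surface extraction yields clean sphere topology", {
  surf <- shellSurface()
  ctr <- surf$central
  expect_identical(ctr@eulerCharacteristic, 2L)
  expect_identical(ctr@genus, 0L)
  ## mesh radius and area match the r = 12 mid-shell sphere within 2%
  r <- sqrt(rowSums(meshVertices(ctr)^2))
  expect_lt(abs(mean(r) - 12), 0.15)
  area <- sum(brainmorph:::meshFaceAreas(meshVertices(ctr), meshFaces(ctr)))
  expect_lt(abs(area - 4 * pi * 12^2) / (4 * pi * 12^2), 0.02)
  ## empty isosurface errors
  expect_error(extractCentralSurface(Volume(array(1, c(8, 8, 8)))), "sign")
})

test_that("central surface lies between white and pial everywhere", {
  surf <- shellSurface()
  rw <- sqrt(rowSums(meshVertices(surf$white)^2))
  rc <- sqrt(rowSums(meshVertices(surf$central)^2))
  rp <- sqrt(rowSums(meshVertices(surf$pial)^2))
  expect_true(all(rw < rc & rc < rp))
})

test_that("FreeSurfer-metric thickness matches analytic cases and oracle", {
  ## parallel planes at distance d
  p1 <- planeMesh(15, 1)
  v2 <- meshVertices(p1); v2[, 3] <- 3.2
  p2 <- brainmorph:::surfaceMesh(v2, meshFaces(p1))
  t_pl <- scalarValues(refineThicknessFs(p1, p2))
  expect_lt(max(abs(t_pl - 3.2)), 1e-9)
  ## concentric spheres radii 10 / 14 -> thickness 4 within 1%
  s10 <- icosphere(3, 10); s14 <- icosphere(3, 14)
  t_sph <- scalarValues(refineThicknessFs(s10, s14))
  expect_lt(max(abs(t_sph - 4)) / 4, 0.01)
  ## brute-force nearest-triangle oracle on a small mesh pair
  w <- icosphere(1, 5)
  p <- icosphere(1, 6.5)
  mine <- scalarValues(refineThicknessFs(w, p))
  brute <- function(pts, verts, faces) {
    vapply(seq_len(nrow(pts)), function(i) {
      dmin <- Inf
      for (f in seq_len(nrow(faces))) {
        tri <- verts[faces[f, ], , drop = FALSE]
        d <- brainmorph:::cpp_point_mesh_dist(pts[i, , drop = FALSE],
                                              tri, matrix(1:3, 1))
        dmin <- min(dmin, d)
      }
      dmin
    }, 0)
  }
  d1 <- brute(meshVertices(w), meshVertices(p), meshFaces(p))
  d2 <- brute(meshVertices(p), meshVertices(w), meshFaces(w))
  expect_equal(mine, (d1 + d2) / 2, tolerance = 1e-6)
  expect_error(refineThicknessFs(w, icosphere(2, 6.5)), "correspond")
})

test_that("surface sampling follows equidistant and equi-volume rules", {
  ## radius field: sampled value reveals the sampling radius
  dm <- c(64, 64, 64)
  proto <- Volume(array(0, dm), voxel_size = 0.6)
  w <- brainmorph:::worldGrid(proto)
  radial <- Volume(array(sqrt(rowSums(w^2)), dm), affine = volAffine(proto))
  ctr <- icosphere(3, radius = 12)
  th <- new("VertexScalars", values = rep(4, nrow(meshVertices(ctr))),
            name = "t", units = "mm")
  eq <- sampleToSurface(radial, ctr, th, 0.5, "equidistant")
  ev <- sampleToSurface(radial, ctr, th, 0.5, "equivolume")
  expect_lt(abs(mean(scalarValues(eq)) - 12), 0.05)
  ## closed-form spherical wedge: ((10^3 + 14^3)/2)^(1/3) = 12.244
  expect_lt(abs(mean(scalarValues(ev)) - ((10^3 + 14^3) / 2)^(1 / 3)), 0.05)
  ## constant volume samples constant
  cv <- Volume(array(7, dm), affine = volAffine(proto))
  expect_true(all(abs(scalarValues(
    sampleToSurface(cv, ctr, th, 0.3, "equivolume")) - 7) < 1e-9))
  ## flat slab: equivolume reduces to equidistant
  pm <- planeMesh(21, 1)
  thp <- new("VertexScalars", values = rep(3, nrow(meshVertices(pm))),
             name = "t", units = "mm")
  grad <- Volume(array(rep(seq_len(dm[3]), each = dm[1] * dm[2]), dm),
                 affine = volAffine(proto))
  a <- scalarValues(sampleToSurface(grad, pm, thp, 0.7, "equidistant"))
  b <- scalarValues(sampleToSurface(grad, pm, thp, 0.7, "equivolume"))
  inner <- abs(meshVertices(pm)[, 1]) < 8 & abs(meshVertices(pm)[, 2]) < 8
  expect_lt(max(abs(a - b)[inner]), 1e-6)
  expect_error(sampleToSurface(cv, ctr, th, 1.2), "depth_fraction")
})

test_that("surface scalar smoothing hits its FWHM and conserves the mean", {
  sph <- icosphere(4, radius = 40)
  v <- meshVertices(sph)
  va <- brainmorph:::meshVertexAreas(v, meshFaces(sph))
  s <- new("VertexScalars",
           values = as.numeric(seq_len(nrow(v)) == which.max(v[, 3])),
           name = "imp", units = "")
  ## constants are fixed points
  cst <- new("VertexScalars", values = rep(2, nrow(v)), name = "c",
             units = "")
  expect_equal(scalarValues(smoothSurfaceScalar(sph, cst, 12)), rep(2, nrow(v)))
  sm <- smoothSurfaceScalar(sph, s, 12)
  u <- scalarValues(sm)
  ## area-weighted mean preserved
  expect_lt(abs(sum(u * va) - sum(scalarValues(s) * va)) /
              sum(scalarValues(s) * va), 1e-6)
  ## geodesic FWHM within 15%
  gd <- 40 * acos(pmin(1, v[, 3] / 40))
  sig2 <- sum(u * va * gd^2) / sum(u * va) / 2
  fwhm <- sqrt(8 * log(2) * sig2)
  expect_lt(abs(fwhm - 12) / 12, 0.15)
})

test_that("mean thickness is consistent across voxel resolutions", {
  ## the same shell regenerated at 1.0 / 0.8 mm changes mean PBT thickness
  ## by < 5% (the finest grid is covered in the acceptance suite)
  mt <- vapply(c(1.0, 0.8), function(vs) {
    gs <- ceiling(2 * (17 + 4.5 * vs) / vs)
    ph <- generatePhantom(phantomSpec(grid_shape = gs, voxel_size = vs,
                                     wm_radius = 10, gm_thickness = 4,
                                     csf_thickness = 3))
    seg <- truthSegmentation(ph)
    bd <- boundaryDistances(seg)
    pbt <- pbtThickness(bd$wmd, bd$csfd, bd$gm_mask,
                        wmd_signed = bd$wmd_signed)
    mean(volData(pbt$thickness)[bd$gm_mask])
  }, 0)
  expect_lt(abs(diff(mt)) / mt[1], 0.05)
})
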