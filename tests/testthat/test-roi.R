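twoHemiAtlas <- function(proto) {
  w <- brainmorph:::worldGrid(proto)
  lab <- ifelse(sqrt(rowSums(w^2)) < 18, ifelse(w[, 1] < 0, 1, 2), 0)
  makeAtlas(Volume(array(lab, dim(volData(proto))),
                   affine = volAffine(proto)),
            lut = data.frame(code = 1:2, name = c("left", "right")))
}

test_that("atlas warping is a nearest-neighbour pull-back", {
  seg <- shellSegmentation()
  atl <- twoHemiAtlas(seg@pveLabel)
  dm <- dim(volData(seg@pveLabel))
  id <- new("DeformationField", displacement = array(0, c(dm, 3L)),
            grid = seg@pveLabel,
            jacobian = Volume(array(1, dm), affine = volAffine(seg@pveLabel)))
  same <- warpAtlas(atl, id)
  expect_identical(volData(same@labels), volData(atl@labels))
  ## labels cannot be invented
  g <- generateDeformation(dm[1], amplitude_mm = 2, smoothness_mm = 10,
                           seed = 4)
  wa <- warpAtlas(atl, g)
  expect_true(all(unique(as.vector(volData(wa@labels))) %in%
                    c(0, atl@lut$code)))
  ## round trip overlap > 95% on labelled voxels
  dback <- new("DeformationField", displacement = -g@displacement,
               grid = g@grid, jacobian = g@jacobian)
  back <- warpAtlas(wa, dback)
  lab0 <- volData(atl@labels)
  labb <- volData(back@labels)
  sel <- lab0 > 0
  expect_gt(mean(labb[sel] == lab0[sel]), 0.95)
  ## non-integer labels rejected
  bad <- atl
  bad@labels <- Volume(volData(atl@labels) + 0.5,
                       affine = volAffine(atl@labels))
  expect_error(warpAtlas(bad, id), "integer")
})

test_that("regional volumes are exact sums and additive over regions", {
  seg <- shellSegmentation()
  atl <- twoHemiAtlas(seg@pveLabel)
  tab <- regionalVolumes(seg, atl)
  ## left + right equals the whole-brain GM inside the labelled region
  lab <- as.vector(volData(atl@labels))
  gmf <- as.vector(volData(seg@gmFraction))
  whole <- sum(gmf[lab > 0]) * prod(voxelSize(seg@pveLabel)) / 1000
  expect_equal(sum(tab$gm_ml), whole, tolerance = 1e-9)
  ## hand-built 4-voxel region with gm fractions (1, .5, .25, 0) at 2 ml
  ## voxels gives 3.5 ml
  z <- array(0, c(4, 1, 1))
  gm4 <- Volume(array(c(1, 0.5, 0.25, 0), c(4, 1, 1)),
                voxel_size = c(2000)^(1 / 3))
  seg4 <- new("PveSegmentation",
              prob = list(csf = Volume(array(0, c(4, 1, 1)),
                                       affine = volAffine(gm4)),
                          gm = gm4,
                          wm = Volume(array(0, c(4, 1, 1)),
                                      affine = volAffine(gm4))),
              pveLabel = gm4, gmFraction = gm4)
  atl4 <- makeAtlas(Volume(array(1, c(4, 1, 1)), affine = volAffine(gm4)),
                    lut = data.frame(code = 1, name = "all"))
  t4 <- regionalVolumes(seg4, atl4, voxel_volume = 2000)
  expect_equal(t4$gm_ml, 3.5)
  ## absent region: zero row with a warning
  atl5 <- makeAtlas(Volume(array(1, c(4, 1, 1)), affine = volAffine(gm4)),
                    lut = data.frame(code = c(1, 7),
                                     name = c("all", "ghost")))
  expect_warning(t5 <- regionalVolumes(seg4, atl5, voxel_volume = 2000),
                 "ghost")
  expect_equal(t5$gm_ml[t5$code == 7], 0)
})

test_that("regional thickness is the area-weighted mean per region", {
  sph <- icosphere(3, 12)
  v <- meshVertices(sph)
  lab <- ifelse(v[, 3] >= 0, 1L, 2L)
  atl <- makeAtlas(lab, lut = data.frame(code = 1:2,
                                         name = c("north", "south")))
  ## constant thickness: every region reports the constant
  cst <- new("VertexScalars", values = rep(4, nrow(v)), name = "th",
             units = "mm")
  tab <- regionalThickness(cst, atl, sph)
  expect_true(all(abs(tab$mean_mm - 4) < 1e-12))
  ## hemispheres with distinct thickness recover 3 and 5 within 2%
  th <- new("VertexScalars", values = ifelse(lab == 1L, 5, 3), name = "th",
            units = "mm")
  tab2 <- regionalThickness(th, atl, sph)
  expect_lt(abs(tab2$mean_mm[tab2$code == 1] - 5) / 5, 0.02)
  expect_lt(abs(tab2$mean_mm[tab2$code == 2] - 3) / 3, 0.02)
  ## partition identity: area-weighted mean over regions = global mean
  va <- brainmorph:::meshVertexAreas(v, meshFaces(sph))
  glob <- sum(scalarValues(th) * va) / sum(va)
  expect_equal(sum(tab2$mean_mm * tab2$area_mm2) / sum(tab2$area_mm2),
               glob, tolerance = 1e-12)
  expect_error(regionalThickness(th, makeAtlas(rep(0L, nrow(v))), sph),
               "unlabeled")
})
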