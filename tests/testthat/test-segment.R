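test_that("k-means initialization recovers the tissue means, sorted", {
  ph <- shellPhantom()
  mask <- volData(ph$truth@hardLabels) > 0
  init <- initClasses(ph$image, mask)
  mu <- vapply(init@classMeans, function(m) volData(m)[1], 0)
  expect_true(all(diff(mu) > 0))
  expect_lt(max(abs(mu - c(40, 80, 120)) / c(40, 80, 120)), 0.01)
  ## degenerate input
  bin <- Volume(array(rep(c(0, 1), 2048), c(16, 16, 16)))
  expect_error(initClasses(bin, array(TRUE, c(16, 16, 16))), "degenerate")
  expect_error(initClasses(ph$image, mask & FALSE), "1000")
})

test_that("AMAP with beta = 0 and constant means equals per-voxel ML", {
  sp <- phantomSpec(grid_shape = 36, wm_radius = 7, csf_thickness = 2,
                    noise_percent = 5, seed = 4)
  ph <- generatePhantom(sp)
  mask <- volData(smoothFwhm(ph$image, 2)) > 20
  init <- initClasses(ph$image, mask)
  seg <- amapSegment(ph$image, init, mrf_beta = 0, adaptive = FALSE)
  model <- brainmorph:::segModel(seg)
  mu <- vapply(model@classMeans, function(m) volData(m)[1], 0)
  va <- model@classVars
  a <- volData(ph$image)
  ll <- vapply(1:3, function(c) as.vector(-(a - mu[c])^2 / (2 * va[c]) -
                                            0.5 * log(va[c])),
               numeric(length(a)))
  ml <- max.col(ll, ties.method = "first")
  got <- round(volData(seg@pveLabel))[mask]
  expect_true(all(got == ml[as.vector(mask)]))
})

test_that("adaptive local means beat constant means under bias", {
  ## pure-bias condition: the PVE boundary placed with bias-adapted local
  ## means stays on the true tissue interface; constant means misplace it
  sp <- phantomSpec(grid_shape = 48, wm_radius = 10, gm_thickness = 4,
                    csf_thickness = 3, bias_percent = 10, seed = 6)
  ph <- generatePhantom(sp)
  truth <- volData(ph$truth@hardLabels)
  mask <- volData(smoothFwhm(ph$image, 2)) > 0.2 * max(volData(ph$image))
  init <- initClasses(ph$image, mask)
  kap <- function(adaptive) {
    seg <- pveRefine(ph$image,
                     amapSegment(ph$image, init, adaptive = adaptive))
    kappaCoefficient(round(volData(seg@pveLabel)), truth, 2)
  }
  expect_gt(kap(TRUE), kap(FALSE))
})

test_that("local intensity transform anchors the tissue plateaus", {
  ph <- shellPhantom()
  seg <- shellSegmentation()
  lit <- localIntensityTransform(ph$image, seg)
  model <- brainmorph:::segModel(seg)
  mw <- volData(model@classMeans[[3]])
  mg <- volData(model@classMeans[[2]])
  ## voxels exactly at the local WM mean map to 1
  a <- volData(ph$image)
  at_wm <- abs(a - mw) < 0.5
  expect_lt(max(abs(volData(lit)[at_wm] - 1)), 0.01)
  ## midway between GM and WM local means maps to 5/6
  mid <- abs(a - (mg + mw) / 2) < 0.8
  expect_gt(sum(mid), 20)
  expect_lt(max(abs(volData(lit)[mid] - 5 / 6)), 0.01)
  ## histogram modes at 1/3, 2/3, 1 for the noiseless phantom
  vals <- volData(lit)[volData(ph$truth@hardLabels) > 0]
  for (anchor in c(1 / 3, 2 / 3, 1))
    expect_gt(mean(abs(vals - anchor) < 0.01), 0.05)
})

test_that("PVE assigns the mixed-class label scale correctly", {
  ph <- shellPhantom()
  seg <- shellSegmentation()
  model <- brainmorph:::segModel(seg)
  a <- volData(ph$image)
  mw <- volData(model@classMeans[[3]])
  mg <- volData(model@classMeans[[2]])
  pl <- volData(seg@pveLabel)
  ## voxels at the local WM mean get label 3
  at_wm <- abs(a - mw) < 0.25 & pl > 0
  expect_lt(max(abs(pl[at_wm] - 3)), 0.02)
  ## midway GM/WM voxels get label 2.5 (when truly mixed)
  mid <- abs(a - (mg + mw) / 2) < 0.8 & pl > 2 & pl < 3
  expect_gt(sum(mid), 10)
  expect_lt(max(abs(pl[mid] - 2.5)), 0.025)
  ## gm fraction identity
  gmf <- volData(seg@gmFraction)
  lab <- pl[pl > 0]
  expect_equal(gmf[pl > 0], pmax(0, 1 - abs(lab - 2)), tolerance = 1e-12)
  ## total GM volume matches the generator's ground truth within 2%
  gt <- sum(volData(ph$truth@fractions$gm))
  expect_lt(abs(sum(gmf) - gt) / gt, 0.02)
})

test_that("probabilities sum to one inside the mask after each stage", {
  seg <- shellSegmentation()
  mask <- attr(seg, "mask")
  s <- volData(seg@prob$csf) + volData(seg@prob$gm) + volData(seg@prob$wm)
  expect_true(all(abs(s[mask] - 1) < 1e-4))
})

test_that("Cohen's kappa follows its definition and error contract", {
  ph <- shellPhantom()
  lab <- ph$truth@hardLabels
  expect_identical(kappaCoefficient(lab, lab, 2), 1)
  ## complementary maps on a 50/50 grid
  a <- array(rep(c(1, 0), 500), c(10, 10, 10))
  expect_identical(kappaCoefficient(a, 1 - a, 1), -1)
  ## hand-computed 2x2 example: confusion (4,1,1,4) -> kappa 0.6
  x <- array(c(rep(1, 5), rep(0, 5)), c(10, 1, 1))
  y <- array(c(rep(1, 4), 0, 1, rep(0, 4)), c(10, 1, 1))
  expect_equal(kappaCoefficient(x, y, 1), 0.6)
  ## degenerate maps
  z <- array(1, c(4, 4, 4))
  expect_error(kappaCoefficient(z, z, 1), "undefined")
})

test_that("TIV and compartments are additive and close to truth", {
  ph <- shellPhantom()
  seg <- shellSegmentation()
  tv <- tivMl(seg)
  expect_equal(tv$tiv_ml, tv$csf_ml + tv$gm_ml + tv$wm_ml)
  expect_lt(abs(tv$tiv_ml - ph$truth@tivMl) / ph$truth@tivMl, 0.03)
  ## empty segmentation gives zero
  z <- Volume(array(0, c(8, 8, 8)))
  empty <- new("PveSegmentation",
               prob = list(csf = z, gm = z, wm = z), pveLabel = z,
               gmFraction = z)
  expect_identical(tivMl(empty)$tiv_ml, 0)
})

test_that("AMAP is equivariant under axis flips (no spatial priors)", {
  sp <- phantomSpec(grid_shape = 40, wm_radius = 7, csf_thickness = 2,
                    fold_amplitude = 1.5, fold_frequency = 3L,
                    noise_percent = 3, seed = 8)
  ph <- generatePhantom(sp)
  flip <- function(a) a[dim(a)[1]:1, , ]
  mask <- volData(smoothFwhm(ph$image, 2)) > 20
  seg1 <- amapSegment(ph$image, initClasses(ph$image, mask))
  img2 <- Volume(flip(volData(ph$image)), affine = volAffine(ph$image))
  seg2 <- amapSegment(img2, initClasses(img2, flip(mask)))
  expect_equal(flip(volData(seg1@pveLabel)), volData(seg2@pveLabel),
               tolerance = 1e-10)
})
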