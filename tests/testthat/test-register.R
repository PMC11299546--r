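test_that("Jacobian determinant matches analytic and oracle values", {
  ## identity
  f0 <- generateDeformation(16, 0)
  expect_true(all(volData(f0@jacobian) == 1))
  ## global scaling by s per axis -> s^3 in the interior
  proto <- Volume(array(0, c(20, 20, 20)))
  w <- brainmorph:::worldGrid(proto)
  s <- 1.07
  fldS <- new("DeformationField",
              displacement = array((s - 1) * w, c(20, 20, 20, 3)),
              grid = proto, jacobian = Volume(array(1, c(20, 20, 20))))
  j <- volData(jacobianDet(fldS))
  expect_lt(max(abs(j[3:18, 3:18, 3:18] - s^3)), 1e-9)
  ## random smooth field vs an independent finite-difference oracle
  f <- generateDeformation(20, amplitude_mm = 1.5, smoothness_mm = 6, seed = 2)
  d <- f@displacement
  jac <- volData(f@jacobian)
  idx <- cbind(sample(3:18, 40, TRUE), sample(3:18, 40, TRUE),
               sample(3:18, 40, TRUE))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; jj <- idx[r, 2]; k <- idx[r, 3]
    J <- diag(3)
    for (ci in 1:3) {
      J[ci, 1] <- J[ci, 1] + (d[i + 1, jj, k, ci] - d[i - 1, jj, k, ci]) / 2
      J[ci, 2] <- J[ci, 2] + (d[i, jj + 1, k, ci] - d[i, jj - 1, k, ci]) / 2
      J[ci, 3] <- J[ci, 3] + (d[i, jj, k + 1, ci] - d[i, jj, k - 1, ci]) / 2
    }
    expect_lt(abs(det(J) - jac[i, jj, k]), 1e-3)
  }
})

test_that("warping respects identity, conservation and label contracts", {
  ph <- shellPhantom()
  f0 <- new("DeformationField",
            displacement = array(0, c(48, 48, 48, 3)), grid = ph$image,
            jacobian = Volume(array(1, c(48, 48, 48)),
                              affine = volAffine(ph$image)))
  expect_equal(volData(warpVolume(ph$image, f0)), volData(ph$image),
               tolerance = 1e-9)
  ## modulated warp conserves tissue volume within 1%
  g <- generateDeformation(48, amplitude_mm = 2, smoothness_mm = 10, seed = 5)
  gm <- ph$truth@fractions$gm
  mod <- modulateVolume(warpVolume(gm, g), g@jacobian)
  expect_lt(abs(sum(volData(mod)) - sum(volData(gm))) / sum(volData(gm)),
            0.01)
  ## label volumes must use nearest-neighbour interpolation
  expect_error(warpVolume(ph$truth@hardLabels, g), "nearest")
  lab <- warpVolume(ph$truth@hardLabels, g, interp = "nearest")
  expect_true(all(volData(lab) %in% 0:3))
})

test_that("registration recovers a known warp and improves overlap", {
  sp <- phantomSpec(grid_shape = 48, wm_radius = 10, gm_thickness = 4,
                    fold_amplitude = 2, fold_frequency = 4L)
  ph <- generatePhantom(sp)
  ## self-registration is the identity
  fs <- registerDiffeo(ph$image, ph$image)
  expect_lt(mean(sqrt(apply(fs@displacement^2, c(1, 2, 3), sum))), 0.05)
  ## known-warp recovery under 1 voxel mean endpoint error (head region)
  g <- generateDeformation(48, amplitude_mm = 2.5, smoothness_mm = 10,
                           seed = 5)
  warped <- warpVolume(ph$image, g)
  f <- registerDiffeo(warped, ph$image)
  expect_gt(min(volData(f@jacobian)), 0)
  head <- volData(ph$truth@hardLabels) > 0
  epe <- sqrt(apply((f@displacement - g@displacement)^2, c(1, 2, 3), sum))
  expect_lt(mean(epe[head]), 1)
  ## Dice improves for a distinct phantom pair
  sp2 <- phantomSpec(grid_shape = 48, wm_radius = 11, gm_thickness = 3.6,
                     fold_amplitude = 1.5, fold_frequency = 4L, seed = 9)
  ph2 <- generatePhantom(sp2)
  f2 <- registerDiffeo(ph$image, ph2$image)
  dice <- function(a, b) {
    aa <- volData(a) > 0.5; bb <- volData(b) > 0.5
    2 * sum(aa & bb) / (sum(aa) + sum(bb))
  }
  gm1 <- ph$truth@fractions$gm
  gm2 <- ph2$truth@fractions$gm
  expect_gt(dice(gm1, warpVolume(gm2, f2)), dice(gm1, gm2))
})

test_that("template building converges to its fixed point and sharpens", {
  ph <- shellPhantom()
  ## identical inputs: template equals the input after registration
  tmpl <- buildTemplate(list(ph$image, ph$image), n_iter = 1,
                        iters_per_level = c(10L, 5L, 5L))
  expect_lt(mean(abs(volData(tmpl) - volData(ph$image))), 0.5)
  ## two shifted blobs: template blob centred between them within 1 voxel
  blob <- function(cx) {
    v <- Volume(array(0, c(32, 32, 32)))
    w <- brainmorph:::worldGrid(v)
    Volume(array(100 * exp(-rowSums(sweep(w, 2, c(cx, 0, 0))^2) / 18),
                 c(32, 32, 32)), affine = volAffine(v))
  }
  tm <- buildTemplate(list(blob(-2), blob(2)), n_iter = 2,
                      iters_per_level = c(15L, 10L, 5L))
  w <- brainmorph:::worldGrid(tm)
  ctr <- colSums(w * as.vector(volData(tm))) / sum(volData(tm))
  expect_lt(abs(ctr[1]), 1)
})
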