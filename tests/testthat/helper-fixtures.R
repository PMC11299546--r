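## Shared fixtures, computed once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

## noiseless concentric-shell phantom (WM 10 mm, GM 4 mm) at 1 mm
shellPhantom <- function() memo("shell", {
  generatePhantom(phantomSpec(grid_shape = 48, wm_radius = 10,
                              gm_thickness = 4, csf_thickness = 3))
})

## segmentation of the shell phantom through the full AMAP + PVE route
shellSegmentation <- function() memo("shell_seg", {
  ph <- shellPhantom()
  mask <- volData(smoothFwhm(ph$image, 2)) > 0.2 * max(volData(ph$image))
  pveRefine(ph$image, amapSegment(ph$image, initClasses(ph$image, mask)))
})

## a PveSegmentation assembled directly from phantom ground truth
truthSegmentation <- function(ph) {
  tr <- ph$truth
  seg <- new("PveSegmentation",
             prob = list(csf = tr@fractions$csf, gm = tr@fractions$gm,
                         wm = tr@fractions$wm),
             pveLabel = Volume(volData(tr@hardLabels),
                               affine = volAffine(tr@hardLabels)),
             gmFraction = tr@fractions$gm)
  seg
}

## surface stream of the shell phantom (distances, PBT, meshes)
shellSurface <- function() memo("shell_surf", {
  seg <- shellSegmentation()
  bd <- boundaryDistances(seg)
  pbt <- pbtThickness(bd$wmd, bd$csfd, bd$gm_mask,
                      wmd_signed = bd$wmd_signed)
  surf <- extractCorticalSurfaces(pbt$central_level, pbt$thickness)
  c(list(bd = bd, pbt = pbt, seg = seg), surf)
})

## folded phantom central mesh from ground-truth fractions
foldedMesh <- function(amplitude = 2, seed = 21) {
  key <- sprintf("folded_%g_%d", amplitude, seed)
  memo(key, {
    ph <- generatePhantom(phantomSpec(grid_shape = 56, wm_radius = 10,
                                      gm_thickness = 4, csf_thickness = 3,
                                      fold_amplitude = amplitude,
                                      fold_frequency = 4L, seed = seed))
    seg <- truthSegmentation(ph)
    bd <- boundaryDistances(seg)
    pbt <- pbtThickness(bd$wmd, bd$csfd, bd$gm_mask,
                        wmd_signed = bd$wmd_signed)
    extractCentralSurface(pbt$central_level)
  })
}

## regular plane patch mesh (n x n vertices, spacing h, z = 0)
planeMesh <- function(n = 41, h = 1) {
  xy <- expand.grid(x = seq_len(n) - (n + 1) / 2, y = seq_len(n) - (n + 1) / 2)
  v <- cbind(xy$x * h, xy$y * h, 0)
  idx <- function(i, j) (j - 1L) * n + i
  f <- matrix(0L, 0, 3)
  for (j in 1:(n - 1)) for (i in 1:(n - 1))
    f <- rbind(f,
               c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
               c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  brainmorph:::surfaceMesh(v, f)
}
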