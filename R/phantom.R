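#' Create a phantom specification
#'
#' The phantom is a star-shaped "cortex": a white-matter core whose radius is
#' perturbed by a smooth angular folding term
#' `foldAmplitude * sin(f * theta) * sin(f * phi)`, wrapped in a grey-matter
#' shell of constant normal thickness and a CSF shell. Noise follows the
#' BrainWeb convention (sigma as a percentage of the WM mean, Gaussian).
#'
#' @param grid_shape voxels per axis (scalar or length 3).
#' @param voxel_size isotropic voxel size, mm.
#' @param wm_radius white-matter core radius, mm.
#' @param gm_thickness grey-matter thickness, mm.
#' @param csf_thickness CSF shell thickness, mm.
#' @param fold_amplitude folding amplitude, mm.
#' @param fold_frequency integer cycles per revolution.
#' @param intensity_means (CSF, GM, WM) means, strictly increasing.
#' @param noise_percent Gaussian sigma as % of WM mean.
#' @param bias_percent peak-to-peak % of the multiplicative bias field.
#' @param seed RNG seed.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(grid_shape = 48L, voxel_size = 1, wm_radius = 10,
                        gm_thickness = 4, csf_thickness = 3,
                        fold_amplitude = 0, fold_frequency = 4L,
                        intensity_means = c(40, 80, 120),
                        noise_percent = 0, bias_percent = 0, seed = 1L) {
  new("PhantomSpec",
      gridShape = rep_len(as.integer(grid_shape), 3L),
      voxelSize = as.double(voxel_size), wmRadius = as.double(wm_radius),
      gmThickness = as.double(gm_thickness),
      csfThickness = as.double(csf_thickness),
      foldAmplitude = as.double(fold_amplitude),
      foldFrequency = as.integer(fold_frequency),
      intensityMeans = as.double(intensity_means),
      noisePercent = as.double(noise_percent),
      biasPercent = as.double(bias_percent), seed = as.integer(seed))
}

## Approximate signed normal distance from the folded WM surface at world
## points (N x 3): (rho - r(theta, phi)) divided by the surface slant factor
## sqrt(1 + |grad_s r|^2 / rho^2). Exact for fold_amplitude = 0.
phantomSignedDistance <- function(pts, spec) {
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  rho <- sqrt(x^2 + y^2 + z^2)
  rho <- pmax(rho, 1e-9)
  theta <- acos(pmin(1, pmax(-1, z / rho)))
  phi <- atan2(y, x)
  A <- spec@foldAmplitude; f <- spec@foldFrequency
  r <- spec@wmRadius + A * sin(f * theta) * sin(f * phi)
  if (A > 0) {
    drdt <- A * f * cos(f * theta) * sin(f * phi)
    st <- pmax(sin(theta), 1e-6)
    drdp <- A * f * sin(f * theta) * cos(f * phi) / st
    slant <- sqrt(1 + (drdt^2 + drdp^2) / rho^2)
  } else slant <- 1
  (rho - r) / slant
}

#' Generate a synthetic brain phantom with exact ground truth
#'
#' Tissue fractions are computed by 3x3x3 supersampling of each voxel against
#' the analytic geometry; the image is the fraction-weighted mixture of the
#' tissue means, multiplied by a smooth separable polynomial bias field
#' scaled to `bias_percent` peak-to-peak, plus Gaussian noise with
#' `sigma = noise_percent / 100 * WM mean`. The output is a pure function of
#' the spec (bit-identical reruns).
#'
#' @param spec a [PhantomSpec-class].
#' @return `list(image = Volume, truth = PhantomTruth)`.
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  dm <- spec@gridShape
  vs <- spec@voxelSize
  reach <- spec@wmRadius + spec@gmThickness + spec@csfThickness +
    spec@foldAmplitude
  if (reach + 4 * vs > min(dm) / 2 * vs)
    stop("phantom geometry exceeds the grid: needs radius ", reach,
         " mm + 4 voxel margin, grid half-extent is ", min(dm) / 2 * vs,
         " mm", call. = FALSE)
  proto <- Volume(array(0, dm), voxel_size = vs)
  ctr <- worldGrid(proto)
  n <- nrow(ctr)
  t_gm <- spec@gmThickness; t_csf <- spec@csfThickness
  fr <- matrix(0, n, 4) # BG, CSF, GM, WM counts
  offs <- (c(0, 1, 2) - 1) / 3 * vs
  for (ox in offs) for (oy in offs) for (oz in offs) {
    sd <- phantomSignedDistance(sweep(ctr, 2, c(ox, oy, oz), "+"), spec)
    lab <- ifelse(sd < 0, 4L, ifelse(sd < t_gm, 3L,
             ifelse(sd < t_gm + t_csf, 2L, 1L)))
    fr[cbind(seq_len(n), lab)] <- fr[cbind(seq_len(n), lab)] + 1
  }
  fr <- fr / 27
  fcsf <- newData(proto, fr[, 2]); fgm <- newData(proto, fr[, 3])
  fwm <- newData(proto, fr[, 4])
  hard <- max.col(fr, ties.method = "last") - 1L # 0 BG, 1 CSF, 2 GM, 3 WM
  head_frac <- fr[, 2] + fr[, 3] + fr[, 4]
  voxvol <- vs^3
  tiv_ml <- voxvol * sum(head_frac > 0.5) / 1000
  m <- spec@intensityMeans
  img <- fr[, 2] * m[1] + fr[, 3] * m[2] + fr[, 4] * m[3]
  if (spec@biasPercent > 0) {
    nx <- (ctr[, 1] - min(ctr[, 1])) / (max(ctr[, 1]) - min(ctr[, 1])) * 2 - 1
    ny <- (ctr[, 2] - min(ctr[, 2])) / (max(ctr[, 2]) - min(ctr[, 2])) * 2 - 1
    nz <- (ctr[, 3] - min(ctr[, 3])) / (max(ctr[, 3]) - min(ctr[, 3])) * 2 - 1
    raw <- (1 + 0.5 * nx) * (1 + 0.5 * ny) * (1 + 0.5 * nz)
    bias <- 1 + (raw - mean(range(raw))) / diff(range(raw)) *
      (spec@biasPercent / 100)
    img <- img * bias
  }
  if (spec@noisePercent > 0) {
    sigma <- spec@noisePercent / 100 * m[3]
    img <- img + withSeed(spec@seed, rnorm(n, 0, sigma))
  }
  thick <- ifelse(hard == 2L, t_gm, 0)
  truth <- new("PhantomTruth",
               hardLabels = newData(proto, hard),
               fractions = list(csf = fcsf, gm = fgm, wm = fwm),
               trueThicknessMm = t_gm,
               thicknessMap = newData(proto, thick),
               tivMl = tiv_ml, spec = spec)
  list(image = newData(proto, img), truth = truth)
}

#' Generate a two-group phantom cohort with planted atrophy
#'
#' Group B phantoms have their grey-matter thickness reduced by
#' `atrophy_percent`; each subject gets seeded jitter on the WM radius
#' (sd 0.3 mm) and on the tissue intensity means (sd 2% multiplicative).
#'
#' @param n_per_group subjects per group (>= 2).
#' @param atrophy_percent planted GM thickness reduction in group B, percent
#'   (0 <= x < 100).
#' @param base_spec a [PhantomSpec-class] template.
#' @param seed cohort seed.
#' @param jitter_radius_mm sd of the WM-radius jitter.
#' @param jitter_intensity_frac sd of the multiplicative intensity jitter.
#' @return A list of subjects, each
#'   `list(image, truth, group, tiv_ml, subject_id)`.
#' @export
generateCohort <- function(n_per_group, atrophy_percent, base_spec,
                           seed = 1L, jitter_radius_mm = 0.3,
                           jitter_intensity_frac = 0.02) {
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  if (atrophy_percent < 0 || atrophy_percent >= 100)
    stop("atrophy_percent must be in [0, 100)", call. = FALSE)
  pars <- withSeed(seed, {
    ns <- 2L * n_per_group
    list(dr = rnorm(ns, 0, jitter_radius_mm),
         di = matrix(1 + rnorm(ns * 3, 0, jitter_intensity_frac), ns, 3),
         seeds = sample.int(.Machine$integer.max, ns))
  })
  out <- vector("list", 2L * n_per_group)
  for (s in seq_len(2L * n_per_group)) {
    grp <- if (s <= n_per_group) "A" else "B"
    th <- base_spec@gmThickness *
      (if (grp == "B") 1 - atrophy_percent / 100 else 1)
    means <- sort(base_spec@intensityMeans * pars$di[s, ])
    sp <- phantomSpec(grid_shape = base_spec@gridShape,
                      voxel_size = base_spec@voxelSize,
                      wm_radius = base_spec@wmRadius + pars$dr[s],
                      gm_thickness = th,
                      csf_thickness = base_spec@csfThickness,
                      fold_amplitude = base_spec@foldAmplitude,
                      fold_frequency = base_spec@foldFrequency,
                      intensity_means = means,
                      noise_percent = base_spec@noisePercent,
                      bias_percent = base_spec@biasPercent,
                      seed = pars$seeds[s])
    ph <- generatePhantom(sp)
    out[[s]] <- list(image = ph$image, truth = ph$truth, group = grp,
                     tiv_ml = ph$truth@tivMl,
                     subject_id = sprintf("sub-%02d", s))
  }
  out
}

#' Generate a smooth invertible ground-truth deformation
#'
#' A Gaussian-filtered random stationary velocity field, exponentiated by
#' scaling and squaring. The amplitude is clipped (with a message) whenever
#' needed to keep the Jacobian determinant positive everywhere.
#'
#' @param grid_shape voxels per axis (scalar or length 3).
#' @param amplitude_mm approximate maximum displacement, mm.
#' @param smoothness_mm Gaussian smoothing FWHM of the velocity field, mm.
#' @param seed RNG seed.
#' @param voxel_size isotropic voxel size, mm.
#' @return A [DeformationField-class] with positive Jacobian everywhere.
#' @export
generateDeformation <- function(grid_shape, amplitude_mm, smoothness_mm = 8,
                                seed = 1L, voxel_size = 1) {
  stopifnot(amplitude_mm >= 0)
  dm <- rep_len(as.integer(grid_shape), 3L)
  proto <- Volume(array(0, dm), voxel_size = voxel_size)
  if (amplitude_mm == 0) {
    disp <- array(0, c(dm, 3L))
    return(new("DeformationField", displacement = disp, grid = proto,
               jacobian = newData(proto, 1)))
  }
  vel <- withSeed(seed, array(rnorm(prod(dm) * 3), c(dm, 3L)))
  sig <- smoothness_mm / sqrt(8 * log(2)) / voxel_size
  for (c in 1:3)
    vel[, , , c] <- array(cpp_gaussian_smooth(as.double(vel[, , , c]), dm,
                                              rep(sig, 3)), dm)
  vmax <- max(sqrt(apply(vel^2, c(1, 2, 3), sum)))
  vel <- vel * (amplitude_mm / vmax)
  repeat {
    field <- exponentiateVelocity(vel, proto)
    if (min(volData(field@jacobian)) > 0) break
    vel <- vel * 0.9
    message("generateDeformation: amplitude clipped by 10% to keep the ",
            "Jacobian positive")
  }
  field
}
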