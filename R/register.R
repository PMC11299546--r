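## Diffeomorphic registration via a stationary velocity field (SVF) with
## demons forces, Gaussian regularization and scaling-and-squaring
## exponentiation. The DeformationField convention throughout:
## T(x) = x + d(x) in world mm on the reference grid, and
## warpVolume(moving, field) samples moving at T(x) (pull-back), so
## warp(moving, field) ~ fixed after registration.

## central-difference gradient of a 3-D array along voxel axes, then mapped
## to world derivatives via the inverse affine direction block
worldGradient <- function(arr, affine) {
  dm <- dim(arr)
  g <- array(0, c(dm, 3L))
  idx <- function(n) list(lo = c(1L, seq_len(n - 1L)), hi = c(seq_len(n - 1L) + 1L, n),
                          den = c(1, rep(2, n - 2L), 1))
  ix <- idx(dm[1]); iy <- idx(dm[2]); iz <- idx(dm[3])
  g[, , , 1] <- (arr[ix$hi, , ] - arr[ix$lo, , ]) / ix$den
  g[, , , 2] <- (arr[, iy$hi, ] - arr[, iy$lo, ]) / rep(iy$den, each = dm[1])
  g[, , , 3] <- sweep(arr[, , iz$hi] - arr[, , iz$lo], 3, iz$den, "/")
  Ainv <- solve(affine[1:3, 1:3])
  out <- array(0, c(dm, 3L))
  for (j in 1:3)
    out[, , , j] <- g[, , , 1] * Ainv[1, j] + g[, , , 2] * Ainv[2, j] +
      g[, , , 3] * Ainv[3, j]
  out
}

## sample a displacement field (mm, on `grid`) at world points (N x 3)
sampleDisplacement <- function(disp, grid, pts_world, fill = 0) {
  vx <- worldToVoxel(grid, pts_world)
  dm <- dim(disp)[1:3]
  out <- matrix(0, nrow(pts_world), 3)
  for (c in 1:3)
    out[, c] <- cpp_trilinear(as.double(disp[, , , c]), dm, vx, fill)
  out
}

## exponentiate a stationary velocity field (mm) by scaling and squaring
exponentiateVelocity <- function(vel, grid) {
  dm <- dim(vel)[1:3]
  vmax <- max(sqrt(apply(vel^2, c(1, 2, 3), sum)))
  minvs <- min(voxelSize(grid))
  nsq <- max(0L, ceiling(log2(max(1e-12, vmax) / (0.4 * minvs))))
  d <- vel / 2^nsq
  w <- worldGrid(grid)
  if (nsq > 0) for (s in seq_len(nsq)) {
    dmat <- matrix(d, ncol = 3)
    d2 <- sampleDisplacement(d, grid, w + dmat, fill = 0)
    d <- array(dmat + d2, c(dm, 3L))
  }
  field <- new("DeformationField", displacement = d, grid = grid,
               jacobian = newData(grid, 1))
  field@jacobian <- jacobianDet(field)
  field
}

#' Jacobian determinant of a deformation field
#'
#' Determinant of the spatial gradient of the mapping `x + d(x)`, by central
#' finite differences in world mm.
#'
#' @param field a [DeformationField-class].
#' @return A [Volume-class] of local volume change (1 = volume preserved).
#' @export
jacobianDet <- function(field) {
  d <- field@displacement
  aff <- volAffine(field@grid)
  J <- array(0, c(dim(d)[1:3], 3L, 3L))
  for (i in 1:3) {
    J[, , , i, ] <- worldGradient(d[, , , i], aff)
    J[, , , i, i] <- J[, , , i, i] + 1
  }
  det3 <- J[, , , 1, 1] * (J[, , , 2, 2] * J[, , , 3, 3] - J[, , , 2, 3] * J[, , , 3, 2]) -
          J[, , , 1, 2] * (J[, , , 2, 1] * J[, , , 3, 3] - J[, , , 2, 3] * J[, , , 3, 1]) +
          J[, , , 1, 3] * (J[, , , 2, 1] * J[, , , 3, 2] - J[, , , 2, 2] * J[, , , 3, 1])
  newData(field@grid, det3)
}

#' Warp a volume through a deformation field
#'
#' Pull-back interpolation: the output at reference-grid position x samples
#' the input at `x + d(x)`. Label volumes (integer-valued with few distinct
#' values) must be warped with nearest-neighbour interpolation.
#'
#' @param vol input [Volume-class].
#' @param field a [DeformationField-class].
#' @param interp "trilinear" or "nearest".
#' @return Warped [Volume-class] on the field's reference grid.
#' @export
warpVolume <- function(vol, field, interp = c("trilinear", "nearest")) {
  interp <- match.arg(interp)
  v <- as.vector(volData(vol))
  if (interp == "trilinear") {
    u <- unique(v)
    if (length(u) <= 100 && all(abs(u - round(u)) < 1e-9) && length(u) > 1)
      stop("label volume detected: warp with interp = 'nearest'", call. = FALSE)
  }
  w <- worldGrid(field@grid)
  tgt <- w + matrix(field@displacement, ncol = 3)
  vx <- worldToVoxel(vol, tgt)
  f <- if (interp == "trilinear") cpp_trilinear else cpp_nearest
  out <- f(as.double(volData(vol)), dim(volData(vol)), vx, 0)
  newData(field@grid, out)
}

#' Modulate a warped tissue map by the Jacobian determinant
#'
#' Multiplying the warped map by the deformation's Jacobian makes voxel-wise
#' tissue volumes match native space (the VBM modulation step).
#'
#' @param warped warped tissue [Volume-class].
#' @param jacobian Jacobian determinant [Volume-class] of the same field.
#' @return Modulated [Volume-class].
#' @export
modulateVolume <- function(warped, jacobian) {
  stopifnot(all(dim(volData(warped)) == dim(volData(jacobian))))
  newData(warped, volData(warped) * volData(jacobian))
}

## moment-based pre-alignment: translation + isotropic scale mapping the
## fixed frame onto the moving frame, A(x) = cm + s * (x - cf)
momentAlign <- function(fixed, moving) {
  mom <- function(vol) {
    a <- pmax(volData(vol), 0)
    w <- worldGrid(vol)
    s <- sum(a)
    ctr <- colSums(w * as.vector(a)) / s
    rms <- sqrt(sum(as.vector(a) * rowSums(sweep(w, 2, ctr)^2)) / s)
    list(ctr = ctr, rms = rms)
  }
  mf <- mom(fixed); mm <- mom(moving)
  list(cf = mf$ctr, cm = mm$ctr, s = mm$rms / mf$rms)
}

#' Diffeomorphic registration of two volumes
#'
#' Moment-based affine pre-alignment (translation + isotropic scale) followed
#' by multi-resolution stationary-velocity demons: at each level the demons
#' force updates a velocity field that is Gaussian-regularized and
#' exponentiated by scaling and squaring, guaranteeing a positive Jacobian.
#' Deterministic given its inputs.
#'
#' @param fixed reference [Volume-class].
#' @param moving [Volume-class] to be aligned to `fixed`.
#' @param levels number of resolution levels (coarsest = factor 2^(levels-1)).
#' @param iters_per_level iterations per level, coarse to fine (recycled).
#' @param smooth_mm Gaussian FWHM regularizing the velocity field, mm.
#' @param seed unused (the optimizer is deterministic); kept for interface
#'   stability.
#' @return A [DeformationField-class] on the fixed grid such that
#'   `warpVolume(moving, field)` approximates `fixed`.
#' @export
registerDiffeo <- function(fixed, moving, levels = 3L,
                           iters_per_level = c(30L, 20L, 10L),
                           smooth_mm = 6, seed = 1L) {
  al <- momentAlign(fixed, moving)
  if (!is.finite(al$s) || al$s <= 0)
    stop("registration failure: images do not overlap after pre-alignment",
         call. = FALSE)
  iters <- rep_len(iters_per_level, levels)
  ## aligned moving sampled on the fixed grid through the affine
  alignedOn <- function(grid) {
    w <- worldGrid(grid)
    tgt <- sweep(sweep(w, 2, al$cf) * al$s, 2, al$cm, "+")
    vx <- worldToVoxel(moving, tgt)
    newData(grid, cpp_trilinear(as.double(volData(moving)), dim(volData(moving)),
                                vx, 0))
  }
  vel <- NULL
  for (l in seq_len(levels)) {
    fac <- 2^(levels - l)
    target <- min(voxelSize(fixed)) * fac
    Fl <- if (fac > 1) resampleIsotropic(fixed, target) else fixed
    Ml <- alignedOn(Fl)
    dm <- dim(volData(Fl))
    if (is.null(vel)) {
      vel <- array(0, c(dm, 3L))
    } else {
      old <- vel
      oldgrid <- prevgrid
      vel <- array(0, c(dm, 3L))
      vx <- worldToVoxel(oldgrid, worldGrid(Fl))
      for (c in 1:3)
        vel[, , , c] <- array(cpp_trilinear(as.double(old[, , , c]),
                                            dim(old)[1:3], vx, 0), dm)
    }
    sig <- smooth_mm / sqrt(8 * log(2)) / voxelSize(Fl)
    step <- min(voxelSize(Fl))
    for (it in seq_len(iters[l])) {
      phi <- exponentiateVelocity(vel, Fl)
      Mw <- warpVolume(Ml, phi)
      diffim <- volData(Fl) - volData(Mw)
      g <- worldGradient(volData(Mw), volAffine(Fl))
      g2 <- g[, , , 1]^2 + g[, , , 2]^2 + g[, , , 3]^2
      denom <- g2 + diffim^2 / step^2
      denom[denom < 1e-12] <- Inf
      u <- array(0, c(dm, 3L))
      for (c in 1:3) u[, , , c] <- diffim * g[, , , c] / denom
      ## cap the update at half a voxel for stability
      umag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
      cap <- pmin(1, (0.5 * step) / pmax(umag, 1e-12))
      for (c in 1:3) u[, , , c] <- u[, , , c] * cap
      vel <- vel + u
      for (c in 1:3)
        vel[, , , c] <- array(cpp_gaussian_smooth(as.double(vel[, , , c]),
                                                  dm, sig), dm)
    }
    prevgrid <- Fl
  }
  phi <- exponentiateVelocity(vel, fixed)
  ## compose with the affine: T(x) = A(x + d_nl(x))
  w <- worldGrid(fixed)
  xn <- w + matrix(phi@displacement, ncol = 3)
  tot <- sweep(sweep(xn, 2, al$cf) * al$s, 2, al$cm, "+") - w
  field <- new("DeformationField",
               displacement = array(tot, c(dim(volData(fixed)), 3L)),
               grid = fixed, jacobian = newData(fixed, 1))
  field@jacobian <- jacobianDet(field)
  if (min(volData(field@jacobian)) <= 0)
    stop("registration produced a non-positive Jacobian", call. = FALSE)
  field
}

#' Iterative template construction
#'
#' Registers all volumes to the current mean, averages the warped images and
#' repeats. The template sharpens over iterations relative to naive
#' averaging.
#'
#' @param volumes list of [Volume-class] objects (>= 2), same grid.
#' @param n_iter template refinement iterations.
#' @param ... passed to [registerDiffeo()].
#' @return The template [Volume-class].
#' @export
buildTemplate <- function(volumes, n_iter = 3L, ...) {
  stopifnot(length(volumes) >= 2)
  grid <- volumes[[1]]
  stack <- vapply(volumes, function(v) as.vector(volData(v)),
                  numeric(length(volData(grid))))
  tmpl <- newData(grid, rowMeans(stack))
  for (it in seq_len(n_iter)) {
    warped <- vapply(volumes, function(v) {
      f <- registerDiffeo(tmpl, v, ...)
      as.vector(volData(warpVolume(v, f)))
    }, numeric(length(volData(grid))))
    tmpl <- newData(grid, rowMeans(warped))
  }
  tmpl
}

## mean gradient magnitude; the sharpness measure used for template checks
meanGradientMagnitude <- function(vol) {
  g <- worldGradient(volData(vol), volAffine(vol))
  mean(sqrt(g[, , , 1]^2 + g[, , , 2]^2 + g[, , , 3]^2))
}
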