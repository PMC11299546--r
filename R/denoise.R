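#' Estimate local image noise from Laplacian pseudo-residuals
#'
#' The residual at each voxel is the difference between the intensity and
#' the mean of its 6 neighbours, normalised by `sqrt(1 + 1/6)` so that its
#' standard deviation equals the noise sigma for white Gaussian noise.
#' Local sigma aggregates squared residuals over a sliding window; the
#' global sigma is the median of the local map over the mask.
#'
#' @param vol a [Volume-class].
#' @param mask logical array of head voxels (non-empty).
#' @param window_radius half-width of the aggregation window, voxels.
#' @return A [NoiseMap-class].
#' @export
estimateNoise <- function(vol, mask, window_radius = 2L) {
  a <- volData(vol)
  dm <- dim(a)
  mask <- array(as.logical(mask), dm)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  ## 6-neighbour mean by clamped shifts
  shift <- function(x, d, ax) {
    idx <- rep(list(quote(expr = )), 3)
    n <- dim(x)[ax]
    src <- pmin(pmax(seq_len(n) + d, 1L), n)
    idx[[ax]] <- src
    do.call(`[`, c(list(x), idx))
  }
  s6 <- shift(a, 1L, 1) + shift(a, -1L, 1) + shift(a, 1L, 2) +
    shift(a, -1L, 2) + shift(a, 1L, 3) + shift(a, -1L, 3)
  r <- (a - s6 / 6) / sqrt(1 + 1 / 6)
  ## first pass: plain aggregation, to scale the structure threshold
  s2 <- array(cpp_box_mean(as.double(r^2), dm, as.integer(window_radius)), dm)
  sig0 <- median(sqrt(pmax(s2[mask], 0)))
  ## iterated exclusion of voxels whose gradient exceeds what noise alone
  ## produces (tissue edges would otherwise inflate the local sigma); the
  ## threshold shrinks to a fixed point as structure is removed
  g <- worldGradient(a, volAffine(vol))
  gmag <- sqrt(g[, , , 1]^2 + g[, , , 2]^2 + g[, , , 3]^2) * min(voxelSize(vol))
  sig <- array(sig0, dm)
  for (pass in 1:4) {
    valid <- (gmag <= 2.5 * max(sig0, 1e-12)) * 1.0
    num <- array(cpp_box_mean(as.double(r^2 * valid), dm,
                              as.integer(window_radius)), dm)
    den <- array(cpp_box_mean(as.double(valid), dm,
                              as.integer(window_radius)), dm)
    s2 <- ifelse(den > 0.05, num / pmax(den, 0.05), sig0^2)
    sig <- sqrt(pmax(s2, 0))
    new0 <- median(sig[mask])
    if (new0 >= sig0 * 0.95) break
    sig0 <- new0
  }
  new("NoiseMap", sigmaLocal = newData(vol, sig),
      sigmaGlobal = median(sig[mask]))
}

#' Spatially adaptive non-local means (SANLM) denoising
#'
#' Blockwise non-local means with 3^3 patches and a 7^3 search window;
#' patch weights are `exp(-||dP||^2 / (2 beta sigma_local^2 |P|))`, so the
#' filtering strength adapts voxel-wise to the local noise level. The output
#' is a convex combination of input values and therefore stays inside the
#' input range.
#'
#' @param vol a [Volume-class].
#' @param noise a [NoiseMap-class] on the same grid, or `NULL` to estimate
#'   one from `mask`.
#' @param beta filtering strength multiplier (default 1).
#' @param mask head mask used when `noise` is `NULL` (default: positive voxels).
#' @param patch_radius patch half-width (default 1).
#' @param search_radius search half-width (default 3).
#' @return Denoised [Volume-class].
#' @export
sanlmDenoise <- function(vol, noise = NULL, beta = 1, mask = NULL,
                         patch_radius = 1L, search_radius = 3L) {
  if (is.null(noise)) {
    if (is.null(mask)) mask <- volData(vol) > 0
    noise <- estimateNoise(vol, mask)
  }
  if (!all(dim(volData(noise@sigmaLocal)) == dim(volData(vol))))
    stop("noise map grid does not match the volume", call. = FALSE)
  out <- cpp_sanlm(as.double(volData(vol)), dim(volData(vol)),
                   as.double(volData(noise@sigmaLocal)), beta,
                   as.integer(patch_radius), as.integer(search_radius))
  newData(vol, out)
}
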