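## AMAP tissue segmentation: Gaussian class likelihoods with locally varying
## class means (bias adaptivity), a Potts MRF prior over hard labels, and a
## partial-volume reassignment into the 5-class {CSF, CSF/GM, GM, GM/WM, WM}
## model on the continuous 1-3 PVE label scale. No atlas priors anywhere.

#' Initialize the tissue model by 3-class k-means
#'
#' Deterministic quantile seeding: cluster centres start at the 1/6, 3/6 and
#' 5/6 intensity quantiles within the mask. The three class means are
#' returned sorted ascending (CSF < GM < WM, T1-like ordering) and broadcast
#' as spatially constant mean fields.
#'
#' @param vol a [Volume-class].
#' @param mask logical array of head voxels (>= 1000 voxels).
#' @param mrf_beta initial Potts smoothness weight stored in the model.
#' @return A [TissueModel-class].
#' @export
initClasses <- function(vol, mask, mrf_beta = 0.1) {
  a <- volData(vol)
  mask <- array(as.logical(mask), dim(a))
  x <- a[mask]
  if (length(x) < 1000)
    stop("mask must cover at least 1000 voxels", call. = FALSE)
  if (length(unique(x)) < 3)
    stop("degenerate input: fewer than 3 distinct intensities", call. = FALSE)
  ctr <- quantile(x, c(1, 3, 5) / 6, names = FALSE)
  if (length(unique(ctr)) < 3)
    ctr <- quantile(unique(x), c(1, 3, 5) / 6, names = FALSE)
  km <- kmeans(x, centers = matrix(ctr, ncol = 1), iter.max = 50)
  ord <- order(km$centers)
  ## cluster medians resist the partial-volume tails better than the means
  mu <- vapply(ord, function(k) median(x[km$cluster == k]), 0)
  va <- vapply(ord, function(k) {
    v <- var(x[km$cluster == k])
    if (!is.finite(v) || v <= 0) (diff(range(x)) / 100)^2 else v
  }, 0)
  new("TissueModel",
      classMeans = lapply(mu, function(m) newData(vol, m)),
      classVars = va, mrfBeta = mrf_beta)
}

## default head mask: smoothed image above half the CSF mean estimate
defaultHeadMask <- function(vol, csf_mean) {
  volData(smoothFwhm(vol, 2)) > 0.5 * csf_mean
}

#' Adaptive MAP segmentation with MRF regularization
#'
#' Iterated conditional modes / EM hybrid. The E-step assigns labels by the
#' Gaussian likelihood under locally varying class means times a Potts prior
#' `exp(beta * #same-label 6-neighbours)`. The M-step re-estimates the class
#' means locally by Gaussian-smoothing posterior-weighted intensities
#' (default kernel 24 mm FWHM), which makes the model adapt to smooth
#' intensity inhomogeneities without consuming any spatial tissue priors.
#' Stops after `iters` iterations or when fewer than 0.1% of labels change.
#'
#' @param vol a [Volume-class].
#' @param init a [TissueModel-class] from [initClasses()].
#' @param iters maximum iterations.
#' @param mrf_beta Potts weight (overrides the model's value).
#' @param adaptive use locally varying means (`FALSE` = spatially constant).
#' @param adapt_fwhm_mm smoothing kernel of the local mean fields, mm.
#' @param mask head mask; default thresholds the smoothed image at half the
#'   initial CSF mean.
#' @return A [PveSegmentation-class] (pure 3-class probabilities; run
#'   [pveRefine()] for the mixed-class PVE label).
#' @export
amapSegment <- function(vol, init, iters = 16L, mrf_beta = init@mrfBeta,
                        adaptive = TRUE, adapt_fwhm_mm = 24,
                        mask = NULL) {
  a <- volData(vol)
  dm <- dim(a)
  mu0 <- vapply(init@classMeans, function(m) volData(m)[1], 0)
  if (is.null(mask)) mask <- defaultHeadMask(vol, mu0[1])
  mask <- array(as.logical(mask), dm)
  nmask <- sum(mask)
  mu <- lapply(mu0, function(m) array(m, dm))
  va <- init@classVars
  sig_vox <- adapt_fwhm_mm / sqrt(8 * log(2)) / voxelSize(vol)
  labels <- array(0L, dm)
  ## initial per-voxel ML assignment
  score0 <- vapply(1:3, function(c) -(a - mu[[c]])^2 / (2 * va[c]) -
                     0.5 * log(va[c]), array(0, dm))
  labels[mask] <- max.col(matrix(score0, ncol = 3)[as.vector(mask), ,
                                                   drop = FALSE])
  post <- NULL
  gain <- array(1, dm)
  for (it in seq_len(iters)) {
    counts <- cpp_potts_counts(as.integer(labels), dm, 3L)
    sc <- matrix(0, prod(dm), 3)
    for (c in 1:3)
      sc[, c] <- as.vector(-(a - mu[[c]])^2 / (2 * va[c]) -
                             0.5 * log(va[c])) + mrf_beta * counts[, c]
    scm <- sc - apply(sc, 1, max)
    post <- exp(scm)
    post <- post / rowSums(post)
    newlab <- array(0L, dm)
    newlab[mask] <- max.col(sc[as.vector(mask), , drop = FALSE],
                            ties.method = "first")
    changed <- sum(newlab != labels & mask)
    labels <- newlab
    ## M-step. Class weights keep only high-confidence voxels, so partial-
    ## volume mixtures at tissue boundaries cannot drag the means. In the
    ## adaptive mode the classes share one smooth multiplicative gain field
    ## (the intensity-inhomogeneity estimate), built by Gaussian-smoothing
    ## each class's intensity ratio to its global mean and pooling the
    ## classes by their local support; all three local mean fields then
    ## move coherently with the bias.
    gnum <- array(0, dm); gden <- array(0, dm)
    acorr <- a / gain # bias-corrected image under the current gain estimate
    gmeans <- numeric(3)
    for (c in 1:3) {
      w <- array(post[, c] * (post[, c] >= 0.9), dm)
      w[!mask] <- 0
      d <- a[mask] - as.vector(mu[[c]])[as.vector(mask)]
      va[c] <- max(sum(post[as.vector(mask), c] * d^2) /
                     max(sum(post[as.vector(mask), c]), 1e-9), 1e-12)
      gmeans[c] <- sum(w * acorr) / max(sum(w), 1e-9)
      if (adaptive && gmeans[c] > 0) {
        gnum <- gnum + array(cpp_gaussian_smooth(
          as.double(w * acorr / gmeans[c]), dm, sig_vox), dm)
        gden <- gden + array(cpp_gaussian_smooth(as.double(w), dm, sig_vox),
                             dm)
      }
    }
    if (adaptive) {
      ## multiplicative update: the smoothed residual ratio converges to 1,
      ## so the accumulated gain reaches the full inhomogeneity amplitude
      ## even though one smoothing pass underestimates it
      resid <- ifelse(gden > 1e-4, gnum / pmax(gden, 1e-4), 1)
      gain <- pmin(pmax(gain * resid, 0.5), 2)
    }
    for (c in 1:3) mu[[c]] <- array(gmeans[c], dm) * gain
    ## enforce CSF < GM < WM ordering of the local means voxel-wise
    mm <- cbind(as.vector(mu[[1]]), as.vector(mu[[2]]), as.vector(mu[[3]]))
    if (any(mm[, 1] > mm[, 2] | mm[, 2] > mm[, 3])) {
      warning("local class means crossed; re-sorted", call. = FALSE)
      mm <- t(apply(mm, 1, sort))
      for (c in 1:3) mu[[c]] <- array(mm[, c], dm)
    }
    if (changed / max(nmask, 1) < 0.001 && it > 1) break
  }
  ## final E-step so labels and posteriors agree with the final model
  counts <- cpp_potts_counts(as.integer(labels), dm, 3L)
  sc <- matrix(0, prod(dm), 3)
  for (c in 1:3)
    sc[, c] <- as.vector(-(a - mu[[c]])^2 / (2 * va[c]) -
                           0.5 * log(va[c])) + mrf_beta * counts[, c]
  scm <- sc - apply(sc, 1, max)
  post <- exp(scm)
  post <- post / rowSums(post)
  labels <- array(0L, dm)
  labels[mask] <- max.col(sc[as.vector(mask), , drop = FALSE],
                          ties.method = "first")
  prob <- lapply(1:3, function(c) {
    p <- array(post[, c], dm)
    p[!mask] <- 0
    newData(vol, p)
  })
  names(prob) <- c("csf", "gm", "wm")
  pve <- array(0, dm)
  pve[mask] <- labels[mask]
  gmfrac <- pmax(0, 1 - abs(pve - 2))
  gmfrac[pve == 0] <- 0
  model <- new("TissueModel",
               classMeans = lapply(mu, function(m) newData(vol, m)),
               classVars = va, mrfBeta = mrf_beta)
  seg <- new("PveSegmentation", prob = prob, pveLabel = newData(vol, pve),
             gmFraction = newData(vol, gmfrac))
  attr(seg, "model") <- model
  attr(seg, "mask") <- mask
  attr(seg, "iterations") <- it
  seg
}

## local mean fields of a segmentation (set by amapSegment)
segModel <- function(seg) {
  m <- attr(seg, "model")
  if (is.null(m)) stop("segmentation carries no tissue model", call. = FALSE)
  m
}

#' Local intensity transformation
#'
#' Voxel-wise piecewise-linear map sending the local CSF/GM/WM mean estimates
#' to the canonical values 1/3, 2/3 and 1 (monotone per voxel), reducing the
#' effect of locally elevated grey-matter intensities before surface
#' processing.
#'
#' @param vol a [Volume-class].
#' @param seg a [PveSegmentation-class] from [amapSegment()].
#' @return Transformed [Volume-class] with tissue plateaus at 1/3, 2/3, 1.
#' @export
localIntensityTransform <- function(vol, seg) {
  stopifnot(all(dim(volData(vol)) == dim(volData(seg@pveLabel))))
  model <- segModel(seg)
  a <- volData(vol)
  mc <- volData(model@classMeans[[1]])
  mg <- volData(model@classMeans[[2]])
  mw <- volData(model@classMeans[[3]])
  out <- array(0, dim(a))
  lo <- a <= mc
  mid1 <- a > mc & a <= mg
  mid2 <- a > mg & a <= mw
  hi <- a > mw
  out[lo] <- pmax(0, (a / pmax(mc, 1e-9) / 3)[lo])
  out[mid1] <- (1 / 3 + (a - mc) / pmax(mg - mc, 1e-9) / 3)[mid1]
  out[mid2] <- (2 / 3 + (a - mg) / pmax(mw - mg, 1e-9) / 3)[mid2]
  out[hi] <- (1 + (a - mw) / pmax(mw - mg, 1e-9) / 3)[hi]
  newData(vol, out)
}

#' Partial-volume estimation (5-class refinement)
#'
#' Reassigns voxels among {CSF, CSF/GM, GM, GM/WM, WM}: the mixed fraction of
#' the brighter tissue is `f = (I - m_low) / (m_high - m_low)` clipped to
#' [0,1] using the local mean fields; the PVE label is `code_low + f` on the
#' 1-3 scale. Mixed classes are only allowed next to both parent tissues;
#' elsewhere the voxel is rounded to the nearest pure class.
#'
#' @param vol the intensity [Volume-class].
#' @param seg a [PveSegmentation-class] from [amapSegment()].
#' @return A refined [PveSegmentation-class] with continuous `pveLabel` and
#'   consistent fractional probabilities.
#' @export
pveRefine <- function(vol, seg) {
  model <- segModel(seg)
  mask <- attr(seg, "mask")
  a <- volData(vol)
  dm <- dim(a)
  if (is.null(mask)) mask <- volData(seg@pveLabel) > 0
  mc <- volData(model@classMeans[[1]])
  mg <- volData(model@classMeans[[2]])
  mw <- volData(model@classMeans[[3]])
  hard <- round(volData(seg@pveLabel))
  upper <- a > mg
  f_hi <- pmin(1, pmax(0, (a - mg) / pmax(mw - mg, 1e-9)))
  f_lo <- pmin(1, pmax(0, (a - mc) / pmax(mg - mc, 1e-9)))
  pve <- ifelse(upper, 2 + f_hi, 1 + f_lo)
  ## mixed voxels must touch both parent tissues (6-neighbourhood)
  counts <- cpp_potts_counts(as.integer(array(hard, dm)), dm, 3L)
  n_csf <- array(counts[, 1], dm); n_gm <- array(counts[, 2], dm)
  n_wm <- array(counts[, 3], dm)
  mixed_hi <- upper & pve > 2 & pve < 3
  ok_hi <- (n_gm > 0 | hard == 2) & (n_wm > 0 | hard == 3)
  pve[mixed_hi & !ok_hi] <- 2 + round(f_hi[mixed_hi & !ok_hi])
  mixed_lo <- !upper & pve > 1 & pve < 2
  ok_lo <- (n_csf > 0 | hard == 1) & (n_gm > 0 | hard == 2)
  pve[mixed_lo & !ok_lo] <- 1 + round(f_lo[mixed_lo & !ok_lo])
  pve[!mask] <- 0
  gmfrac <- pmax(0, 1 - abs(pve - 2))
  gmfrac[pve == 0] <- 0
  p_wm <- pmax(0, pmin(1, pve - 2))
  p_csf <- pmax(0, pmin(1, 2 - pve))
  p_csf[pve == 0] <- 0
  p_gm <- gmfrac
  prob <- list(csf = newData(vol, p_csf), gm = newData(vol, p_gm),
               wm = newData(vol, p_wm))
  out <- new("PveSegmentation", prob = prob, pveLabel = newData(vol, pve),
             gmFraction = newData(vol, gmfrac))
  attr(out, "model") <- model
  attr(out, "mask") <- mask
  out
}

#' Cohen's kappa between two label maps for one tissue
#'
#' Chance-corrected agreement of the binary tissue-vs-rest maps:
#' `kappa = (p_o - p_e) / (1 - p_e)`. A value of 1 means perfect
#' correspondence between the two segmentations.
#'
#' @param a,b hard label volumes/arrays on the same grid (fuzzy inputs are
#'   argmax-hardened by the caller).
#' @param tissue label code to compare (e.g. 2 for GM on the 0-3 scale).
#' @return kappa, a scalar in [-1, 1].
#' @export
kappaCoefficient <- function(a, b, tissue) {
  av <- if (is(a, "Volume")) volData(a) else a
  bv <- if (is(b, "Volume")) volData(b) else b
  stopifnot(all(dim(av) == dim(bv)))
  x <- as.vector(av) == tissue
  y <- as.vector(bv) == tissue
  n <- length(x)
  p_o <- mean(x == y)
  px <- mean(x); py <- mean(y)
  p_e <- px * py + (1 - px) * (1 - py)
  if (abs(1 - p_e) < 1e-12)
    stop("kappa undefined: both maps are constant (p_e = 1)", call. = FALSE)
  (p_o - p_e) / (1 - p_e)
}

#' Tissue compartment volumes and total intracranial volume
#'
#' TIV is the voxel volume times the summed CSF + GM + WM probabilities;
#' compartment volumes sum to the TIV exactly.
#'
#' @param seg a [PveSegmentation-class].
#' @param voxel_volume voxel volume in mm^3 (default from the segmentation grid).
#' @return list with `tiv_ml`, `csf_ml`, `gm_ml`, `wm_ml`.
#' @export
tivMl <- function(seg, voxel_volume = NULL) {
  if (is.null(voxel_volume)) voxel_volume <- prod(voxelSize(seg@pveLabel))
  s <- vapply(seg@prob, function(p) sum(volData(p)), 0)
  vols <- voxel_volume * s / 1000
  list(tiv_ml = sum(vols), csf_ml = unname(vols["csf"]),
       gm_ml = unname(vols["gm"]), wm_ml = unname(vols["wm"]))
}
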