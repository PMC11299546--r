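## Retrospective quality ratings: noise-to-contrast, inhomogeneity-to-
## contrast and resolution, each mapped linearly onto a 0.5-10.5 rating
## scale between configurable anchors, combined by a weighted mean, plus a
## cohort homogeneity z-score.

## letter grade from a rating: A <= 1.5, B <= 2.5, C <= 3.5, D <= 4.5,
## E <= 5.5, F above; +/- modifiers from the within-band position
gradeFromRating <- function(rating) {
  letters6 <- c("A", "B", "C", "D", "E", "F")
  idx <- pmin(6L, pmax(1L, ceiling(rating - 0.5)))
  frac <- rating - (idx - 0.5)
  mod <- ifelse(idx == 6L, "",
                ifelse(frac < 1 / 3, "+", ifelse(frac > 2 / 3, "-", "")))
  paste0(letters6[idx], mod)
}

## linear rating between anchors, clipped to [0.5, 10.5]
rateLinear <- function(x, x_best, x_worst) {
  r <- 0.5 + (x - x_best) / (x_worst - x_best) * 10
  pmin(10.5, pmax(0.5, r))
}

#' Rate image quality from an image and its segmentation
#'
#' Measures: `ncr` = sd of WM residuals (after removing the smooth local WM
#' mean) divided by the GM-WM contrast; `icr` = sd of the smooth WM mean
#' field divided by the contrast; `res` = RMS voxel size. Each is mapped
#' linearly onto the 0.5-10.5 rating scale between its anchors, graded
#' A+..F, and combined with weights (2,1,1) favouring noise.
#'
#' @param vol the intensity [Volume-class].
#' @param seg its [PveSegmentation-class].
#' @param anchors list of c(best, worst) anchors per measure.
#' @param weights weights of (ncr, icr, res) in the overall rating.
#' @return A [QcReport-class].
#' @export
qcRate <- function(vol, seg,
                   anchors = list(ncr = c(0, 0.5), icr = c(0, 0.5),
                                  res = c(0.5, 3)),
                   weights = c(2, 1, 1)) {
  a <- volData(vol)
  dm <- dim(a)
  ## pure-tissue masks: high-probability voxels eroded by one voxel
  erode1 <- function(m) {
    array(cpp_box_mean(as.double(m), dm, 1L), dm) > 1 - 1e-9
  }
  wm <- erode1(volData(seg@prob$wm) > 0.9)
  gm <- volData(seg@prob$gm) > 0.9
  if (!any(wm) || !any(gm))
    stop("qc unavailable: empty pure-tissue mask", call. = FALSE)
  ## smooth WM mean field (masked normalized convolution)
  sig <- 12
  num <- volData(smoothFwhm(newData(vol, a * wm), sig))
  den <- volData(smoothFwhm(newData(vol, wm * 1.0), sig))
  mfield <- num / pmax(den, 1e-6)
  contrast <- abs(mean(a[wm]) - mean(a[gm]))
  ncr <- sd(a[wm] - mfield[wm]) / contrast
  icr <- sd(mfield[wm]) / contrast
  res <- sqrt(mean(voxelSize(vol)^2))
  measures <- c(ncr = ncr, icr = icr, res = res)
  ratings <- c(ncr = rateLinear(ncr, anchors$ncr[1], anchors$ncr[2]),
               icr = rateLinear(icr, anchors$icr[1], anchors$icr[2]),
               res = rateLinear(res, anchors$res[1], anchors$res[2]))
  overall <- sum(ratings * weights) / sum(weights)
  new("QcReport", measures = measures, ratings = ratings,
      grades = setNames(gradeFromRating(ratings), names(ratings)),
      overallRating = overall, overallGrade = gradeFromRating(overall),
      zScore = NA_real_)
}

#' Cohort homogeneity z-scores
#'
#' Each subject's (registered, smoothed) grey-matter map is correlated with
#' the leave-one-out mean of the rest; `z = standardized(1 - r)`, so large z
#' marks outliers. Subjects with |z| > 2 are flagged.
#'
#' @param gm_maps list of [Volume-class] maps on a common grid, or a
#'   subjects x voxels matrix.
#' @param flag_z flag threshold (default 2).
#' @return data.frame with `subject`, `r`, `z`, `flagged`.
#' @export
sampleHomogeneity <- function(gm_maps, flag_z = 2) {
  X <- if (is.list(gm_maps))
    do.call(rbind, lapply(gm_maps, function(v) as.vector(volData(v))))
  else as.matrix(gm_maps)
  n <- nrow(X)
  if (n < 3) stop("sample homogeneity requires >= 3 subjects", call. = FALSE)
  tot <- colSums(X)
  r <- vapply(seq_len(n), function(i) {
    loo <- (tot - X[i, ]) / (n - 1)
    cor(X[i, ], loo)
  }, 0)
  z <- as.vector(scale(1 - r))
  if (all(!is.finite(z))) z <- rep(0, n)  # identical maps: sd = 0
  data.frame(subject = seq_len(n), r = r, z = z, flagged = abs(z) > flag_z)
}
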