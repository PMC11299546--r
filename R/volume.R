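#' Construct a Volume
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-to-world matrix (RAS mm, 0-based voxel indices).
#'   If `NULL`, a centred axis-aligned affine is built from `voxel_size`.
#' @param voxel_size voxel size in mm (scalar or length 3); ignored when
#'   `affine` is given.
#' @return A [Volume-class] object.
#' @export
Volume <- function(data, affine = NULL, voxel_size = 1) {
  data <- array(as.double(data), dim = dim(data))
  if (is.null(affine)) {
    vs <- rep_len(voxel_size, 3L)
    affine <- diag(c(vs, 1))
    affine[1:3, 4] <- -(dim(data) - 1) / 2 * vs
  }
  vs <- sqrt(colSums(affine[1:3, 1:3, drop = FALSE]^2))
  new("Volume", data = data, affine = affine, voxelSize = vs)
}

## replace the data of a volume, keeping geometry
newData <- function(vol, data) {
  data <- array(as.double(data), dim = dim(vol@data))
  new("Volume", data = data, affine = vol@affine, voxelSize = vol@voxelSize)
}

## world <-> continuous 0-based voxel coordinates (points as N x 3 matrices)
voxelToWorld <- function(vol, ijk) {
  ijk <- rbind(t(ijk), 1)
  t(vol@affine %*% ijk)[, 1:3, drop = FALSE]
}
worldToVoxel <- function(vol, xyz) {
  xyz <- rbind(t(xyz), 1)
  t(solve(vol@affine) %*% xyz)[, 1:3, drop = FALSE]
}

## N x 3 matrix of all 0-based voxel index triples (i fastest), and the
## matching world coordinates
voxelGrid <- function(dm) {
  cbind(rep.int(seq_len(dm[1]) - 1L, dm[2] * dm[3]),
        rep.int(rep(seq_len(dm[2]) - 1L, each = dm[1]), dm[3]),
        rep(seq_len(dm[3]) - 1L, each = dm[1] * dm[2]))
}
worldGrid <- function(vol) voxelToWorld(vol, voxelGrid(dim(vol@data)))

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return A [Volume-class]; data promoted to double.
#' @export
readVolume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("not a readable NIfTI-1 file: ", path, " (",
                         conditionMessage(e), ")", call. = FALSE))
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1]
  if (length(dim(a)) != 3L)
    stop("expected a 3-D volume, got dimensions ",
         paste(dim(a), collapse = "x"), call. = FALSE)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  Volume(a, affine = aff)
}

#' Write a Volume as NIfTI-1
#'
#' Data are written as 32-bit float; world coordinates (sform and qform) are
#' preserved.
#'
#' @param vol a [Volume-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@data)
  RNifti::pixdim(img) <- vol@voxelSize
  RNifti::sform(img) <- structure(vol@affine, code = 2L)
  RNifti::qform(img) <- structure(vol@affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Resample a volume to an isotropic grid
#'
#' Trilinear interpolation onto a grid of `target_mm` isotropic voxels
#' covering the same world extent (nearest-neighbour for label volumes).
#'
#' @param vol a [Volume-class].
#' @param target_mm target isotropic voxel size, mm (default 1).
#' @param interp "trilinear" or "nearest".
#' @return Resampled [Volume-class].
#' @export
resampleIsotropic <- function(vol, target_mm = 1, interp = c("trilinear", "nearest")) {
  stopifnot(target_mm > 0)
  interp <- match.arg(interp)
  dm <- dim(vol@data)
  if (all(abs(vol@voxelSize - target_mm) < 1e-9)) return(vol)
  ## world extent spanned by voxel centres, per axis direction of the affine
  newdim <- pmax(2L, as.integer(round((dm - 1) * vol@voxelSize / target_mm)) + 1L)
  ## new affine: same direction cosines scaled to target_mm, same first-voxel corner
  dirs <- sweep(vol@affine[1:3, 1:3, drop = FALSE], 2, vol@voxelSize, "/")
  naff <- diag(4)
  naff[1:3, 1:3] <- dirs * target_mm
  naff[1:3, 4] <- vol@affine[1:3, 4]
  out <- Volume(array(0, newdim), affine = naff)
  vx <- worldToVoxel(vol, worldGrid(out))
  ## clamp to the source grid so border voxels extend the edge values
  ## (keeps constants constant instead of bleeding in zeros)
  for (c in 1:3) vx[, c] <- pmin(pmax(vx[, c], 0), dm[c] - 1)
  f <- if (interp == "trilinear") cpp_trilinear else cpp_nearest
  newData(out, f(as.double(vol@data), dim(vol@data), vx, 0))
}

#' Gaussian smoothing with FWHM given in mm
#'
#' Separable Gaussian filtering with per-axis sigma = fwhm / sqrt(8 ln 2)
#' converted to voxels; borders are zero-padded (plain convolution).
#' `fwhm_mm = 0` is the identity.
#'
#' @param vol a [Volume-class].
#' @param fwhm_mm full width at half maximum, mm.
#' @return Smoothed [Volume-class].
#' @export
smoothFwhm <- function(vol, fwhm_mm) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(vol)
  sigma_vox <- fwhm_mm / sqrt(8 * log(2)) / vol@voxelSize
  newData(vol, cpp_gaussian_smooth(as.double(vol@data), dim(vol@data), sigma_vox))
}

## seeded evaluation that restores the caller's RNG state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
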