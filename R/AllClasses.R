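## Central S4 containers. Conventions used throughout the package:
##  - voxel indices are 0-based in all voxel<->world arithmetic,
##  - the affine maps homogeneous 0-based voxel indices to RAS world mm,
##  - arrays are stored column-major [i, j, k] exactly as R arrays.

#' Volume: a 3-D scalar grid with voxel-to-world geometry
#'
#' The universal carrier for images, probability maps, distance maps and
#' statistic maps. `affine` maps 0-based voxel indices (homogeneous) to RAS
#' world coordinates in mm; `voxelSize` must equal the column norms of the
#' affine's 3x3 block.
#'
#' @slot data 3-D numeric array.
#' @slot affine 4x4 voxel-to-world matrix (RAS mm).
#' @slot voxelSize numeric(3), mm per axis.
#' @export
setClass("Volume",
  representation(data = "array", affine = "matrix", voxelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3-D array")
    if (!all(dim(object@affine) == c(4L, 4L)))
      msg <- c(msg, "affine must be 4x4")
    d <- try(det(object@affine), silent = TRUE)
    if (inherits(d, "try-error") || !is.finite(d) || abs(d) < 1e-12)
      msg <- c(msg, "affine must be invertible")
    cn <- sqrt(colSums(object@affine[1:3, 1:3, drop = FALSE]^2))
    if (any(abs(cn - object@voxelSize) > 1e-6))
      msg <- c(msg, "voxelSize must equal the affine column norms")
    if (length(msg)) msg else TRUE
  })

#' PhantomSpec: parameters of a synthetic brain phantom
#'
#' Defines the star-shaped cortical phantom: a folded white-matter core, a
#' grey-matter shell of constant normal thickness, and a surrounding CSF
#' shell, imaged with T1-like tissue intensities, a smooth multiplicative
#' bias field and Gaussian noise expressed as a percentage of the WM mean
#' (BrainWeb convention).
#'
#' @slot gridShape integer(3) voxels per axis.
#' @slot voxelSize isotropic voxel size, mm.
#' @slot wmRadius white-matter core radius, mm.
#' @slot gmThickness grey-matter shell thickness (normal direction), mm.
#' @slot csfThickness CSF shell thickness, mm.
#' @slot foldAmplitude amplitude of the angular folding term, mm.
#' @slot foldFrequency integer folding frequency, cycles per revolution.
#' @slot intensityMeans numeric(3), (CSF, GM, WM) image means, strictly increasing.
#' @slot noisePercent Gaussian noise sigma as % of the WM mean.
#' @slot biasPercent peak-to-peak % amplitude of the multiplicative bias field.
#' @slot seed integer RNG seed; the phantom is a pure function of its spec.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSize = "numeric",
                 wmRadius = "numeric", gmThickness = "numeric",
                 csfThickness = "numeric", foldAmplitude = "numeric",
                 foldFrequency = "integer", intensityMeans = "numeric",
                 noisePercent = "numeric", biasPercent = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(diff(object@intensityMeans) <= 0))
      msg <- c(msg, "intensityMeans must be strictly increasing (T1-like ordering)")
    if (object@noisePercent < 0) msg <- c(msg, "noisePercent must be >= 0")
    if (object@gmThickness <= 0) msg <- c(msg, "gmThickness must be > 0")
    if (object@foldAmplitude < 0) msg <- c(msg, "foldAmplitude must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' PhantomTruth: exact ground truth of a generated phantom
#'
#' @slot hardLabels Volume with codes 0 = background, 1 = CSF, 2 = GM, 3 = WM.
#' @slot fractions list of three Volumes (csf, gm, wm) summing to 1 in the head.
#' @slot trueThicknessMm scalar true cortical thickness (constant by construction).
#' @slot thicknessMap Volume, per-voxel true thickness over GM (0 elsewhere).
#' @slot tivMl total intracranial volume, ml.
#' @slot spec the generating PhantomSpec.
#' @export
setClass("PhantomTruth",
  representation(hardLabels = "Volume", fractions = "list",
                 trueThicknessMm = "numeric", thicknessMap = "Volume",
                 tivMl = "numeric", spec = "PhantomSpec"))

#' NoiseMap: local and global noise estimates
#'
#' @slot sigmaLocal Volume of local noise sigma (image units).
#' @slot sigmaGlobal scalar, median of sigmaLocal over the head mask.
#' @export
setClass("NoiseMap",
  representation(sigmaLocal = "Volume", sigmaGlobal = "numeric"))

#' TissueModel: locally varying Gaussian class model for AMAP
#'
#' @slot classMeans list of three Volumes (csf, gm, wm local mean fields).
#' @slot classVars numeric(3) per-class variances.
#' @slot mrfBeta Potts smoothness weight.
#' @export
setClass("TissueModel",
  representation(classMeans = "list", classVars = "numeric",
                 mrfBeta = "numeric"),
  validity = function(object) {
    if (length(object@classMeans) != 3L) return("classMeans must have 3 entries")
    if (any(object@classVars <= 0)) return("classVars must be positive")
    TRUE
  })

#' PveSegmentation: tissue probabilities plus a continuous PVE label map
#'
#' The PVE label is on the 1-3 scale (1 = CSF, 2 = GM, 3 = WM) with mixed
#' voxels in (1,2) and (2,3); 0 marks background. `gmFraction` equals
#' 1 - |pveLabel - 2| clipped to [0,1] over labelled voxels.
#'
#' @slot prob list of three Volumes (csf, gm, wm) in [0,1].
#' @slot pveLabel Volume on the continuous 1-3 scale, 0 = background.
#' @slot gmFraction Volume of grey-matter fractional content.
#' @export
setClass("PveSegmentation",
  representation(prob = "list", pveLabel = "Volume", gmFraction = "Volume"))

#' DeformationField: dense displacement with Jacobian determinant
#'
#' @slot displacement 4-D array [nx, ny, nz, 3], mm displacement in world frame.
#' @slot grid Volume carrying the reference geometry (data may be empty).
#' @slot jacobian Volume of local volume-change determinant.
#' @export
setClass("DeformationField",
  representation(displacement = "array", grid = "Volume",
                 jacobian = "Volume"),
  validity = function(object) {
    d <- dim(object@displacement)
    if (length(d) != 4L || d[4] != 3L)
      return("displacement must be [nx, ny, nz, 3]")
    TRUE
  })

#' SurfaceMesh: closed oriented triangle mesh in world mm
#'
#' @slot vertices V x 3 matrix, mm.
#' @slot faces F x 3 integer matrix, 1-based vertex indices, outward orientation.
#' @slot eulerCharacteristic integer V - E + F.
#' @slot genus integer (2 - chi) / 2.
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix",
                 eulerCharacteristic = "integer", genus = "integer"),
  validity = function(object) {
    if (ncol(object@vertices) != 3L) return("vertices must be V x 3")
    if (ncol(object@faces) != 3L) return("faces must be F x 3")
    f <- as.integer(object@faces)
    if (any(f < 1L) || any(f > nrow(object@vertices)))
      return("face indices out of range")
    TRUE
  })

#' VertexScalars: one scalar measure per mesh vertex
#'
#' @slot values numeric, one per vertex.
#' @slot name measure identifier.
#' @slot units "mm", "1/mm" or "" (dimensionless).
#' @export
setClass("VertexScalars",
  representation(values = "numeric", name = "character", units = "character"),
  validity = function(object) {
    if (any(!is.finite(object@values))) return("values must be finite")
    TRUE
  })

#' SphereMap: spherical parameterization of a genus-0 mesh
#'
#' @slot coords V x 3 unit-sphere coordinates.
#' @slot areaDistortion per-vertex area-distortion ratio.
#' @export
setClass("SphereMap",
  representation(coords = "matrix", areaDistortion = "numeric"),
  validity = function(object) {
    n <- sqrt(rowSums(object@coords^2))
    if (any(abs(n - 1) > 1e-8)) return("all mapped points must have unit norm")
    TRUE
  })

#' Design: second-level GLM design with exchangeability structure
#'
#' @slot matrix observations x regressors design matrix.
#' @slot names regressor names.
#' @slot contrast numeric contrast weights (length = regressor count).
#' @slot blocks exchangeability-block id per observation.
#' @slot tail "one" or "two" sided.
#' @export
setClass("Design",
  representation(matrix = "matrix", names = "character",
                 contrast = "numeric", blocks = "integer", tail = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@contrast) != ncol(object@matrix))
      msg <- c(msg, "contrast length must equal regressor count")
    if (qr(object@matrix)$rank < ncol(object@matrix))
      msg <- c(msg, "design matrix must have full column rank")
    if (length(object@blocks) != nrow(object@matrix))
      msg <- c(msg, "blocks must partition the observations")
    if (!object@tail %in% c("one", "two"))
      msg <- c(msg, "tail must be 'one' or 'two'")
    if (length(msg)) msg else TRUE
  })

#' TfceParams: threshold-free cluster enhancement parameters
#'
#' @slot E extent exponent.
#' @slot H height exponent.
#' @slot nSteps threshold discretization steps.
#' @slot connectivity 6, 18 or 26 for grids; meshes use edge adjacency.
#' @export
setClass("TfceParams",
  representation(E = "numeric", H = "numeric", nSteps = "integer",
                 connectivity = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@E <= 0 || object@H <= 0) msg <- c(msg, "E and H must be > 0")
    if (object@nSteps < 10L) msg <- c(msg, "nSteps must be >= 10")
    if (!object@connectivity %in% c(6L, 18L, 26L))
      msg <- c(msg, "connectivity must be 6, 18 or 26")
    if (length(msg)) msg else TRUE
  })

#' Atlas: integer region labels with a lookup table
#'
#' Volumetric atlases carry a label Volume; surface atlases carry one integer
#' code per vertex. Code 0 means unlabeled.
#'
#' @slot labels a Volume of integer codes or an integer vector (surface atlas).
#' @slot lut data.frame with columns `code` and `name`.
#' @slot space "volume" or "surface".
#' @export
setClass("Atlas",
  representation(labels = "ANY", lut = "data.frame", space = "character"),
  validity = function(object) {
    if (!object@space %in% c("volume", "surface"))
      return("space must be 'volume' or 'surface'")
    codes <- if (object@space == "volume") unique(as.vector(volData(object@labels)))
             else unique(object@labels)
    codes <- setdiff(as.integer(round(codes)), 0L)
    if (!all(codes %in% object@lut$code))
      return("every nonzero label code must be present in the lut")
    TRUE
  })

#' QcReport: retrospective image quality ratings
#'
#' Sub-measures (noise-to-contrast, inhomogeneity-to-contrast, resolution)
#' are each mapped onto a 0.5-10.5 rating scale and letter grades A+..F;
#' the overall rating is a weighted mean of the sub-ratings.
#'
#' @slot measures named numeric: ncr, icr, res.
#' @slot ratings named numeric ratings in [0.5, 10.5].
#' @slot grades named character grades.
#' @slot overallRating numeric.
#' @slot overallGrade character.
#' @slot zScore numeric or NA (cohort homogeneity score, absent for one image).
#' @export
setClass("QcReport",
  representation(measures = "numeric", ratings = "numeric",
                 grades = "character", overallRating = "numeric",
                 overallGrade = "character", zScore = "numeric"),
  validity = function(object) {
    if (any(object@ratings < 0.5 - 1e-9 | object@ratings > 10.5 + 1e-9))
      return("ratings must lie in [0.5, 10.5]")
    TRUE
  })
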