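#' @name accessors
#' @title Accessors for brainmorph S4 containers
#' @description Slot access goes through these accessors throughout the
#'   package and in user code.
#' @param x an object.
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname accessors
#' @export
setGeneric("volAffine", function(x) standardGeneric("volAffine"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))
#' @rdname accessors
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))
#' @rdname accessors
#' @export
setGeneric("scalarValues", function(x) standardGeneric("scalarValues"))

#' @rdname accessors
#' @export
setMethod("volData", "Volume", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("volAffine", "Volume", function(x) x@affine)
#' @rdname accessors
#' @export
setMethod("voxelSize", "Volume", function(x) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("meshVertices", "SurfaceMesh", function(x) x@vertices)
#' @rdname accessors
#' @export
setMethod("meshFaces", "SurfaceMesh", function(x) x@faces)
#' @rdname accessors
#' @export
setMethod("scalarValues", "VertexScalars", function(x) x@values)

setMethod("show", "Volume", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume %d x %d x %d, voxel %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3],
              paste(signif(object@voxelSize, 4), collapse = " x "),
              min(object@data), max(object@data)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0(
    "PhantomSpec: grid %s @ %.3g mm, WM radius %.3g mm, GM %.3g mm,\n",
    "  folds %.3g mm x %d cycles, means (%s), noise %.3g%%, bias %.3g%%, seed %d\n"),
    paste(object@gridShape, collapse = "x"), object@voxelSize,
    object@wmRadius, object@gmThickness, object@foldAmplitude,
    object@foldFrequency, paste(object@intensityMeans, collapse = ", "),
    object@noisePercent, object@biasPercent, object@seed))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: TIV %.2f ml, true thickness %.3g mm\n",
              object@tivMl, object@trueThicknessMm))
})

setMethod("show", "PveSegmentation", function(object) {
  d <- dim(volData(object@pveLabel))
  gm <- sum(volData(object@gmFraction))
  cat(sprintf("PveSegmentation %d x %d x %d, GM fraction sum %.1f voxels\n",
              d[1], d[2], d[3], gm))
})

setMethod("show", "DeformationField", function(object) {
  mx <- max(sqrt(apply(object@displacement^2, c(1, 2, 3), sum)))
  jr <- range(volData(object@jacobian))
  cat(sprintf("DeformationField: max |d| %.3g mm, jacobian in [%.3g, %.3g]\n",
              mx, jr[1], jr[2]))
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces, chi %d, genus %d\n",
              nrow(object@vertices), nrow(object@faces),
              object@eulerCharacteristic, object@genus))
})

setMethod("show", "VertexScalars", function(object) {
  cat(sprintf("VertexScalars '%s' [%s]: n %d, mean %.4g, range [%.4g, %.4g]\n",
              object@name, object@units, length(object@values),
              mean(object@values), min(object@values), max(object@values)))
})

setMethod("show", "QcReport", function(object) {
  cat(sprintf("QcReport: overall %.2f (%s); %s\n",
              object@overallRating, object@overallGrade,
              paste(sprintf("%s %.2f (%s)", names(object@ratings),
                            object@ratings, object@grades), collapse = ", ")))
})
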