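## File interchange: triangle meshes as OFF and GIFTI (ASCII encoding),
## vertex scalars as GIFTI functional files and CSV, deformation fields as
## 4-D NIfTI displacement volumes, phantom specs as JSON, cohorts as a CSV
## manifest.

#' Write / read a triangle mesh as OFF
#'
#' Plain-text Object File Format: header `OFF`, counts, vertex rows, then
#' face rows (0-based indices).
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path output path.
#' @return `path` invisibly; `readMeshOff` returns a [SurfaceMesh-class].
#' @export
writeMeshOff <- function(mesh, path) {
  v <- meshVertices(mesh)
  f <- meshFaces(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(v), nrow(f)), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
             con)
  invisible(path)
}

#' @rdname writeMeshOff
#' @export
readMeshOff <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  if (trimws(ln[1]) != "OFF") stop("not an OFF file: ", path, call. = FALSE)
  cnt <- as.integer(strsplit(trimws(ln[2]), "\\s+")[[1]])
  nv <- cnt[1]; nf <- cnt[2]
  v <- matrix(as.numeric(unlist(strsplit(trimws(ln[3:(2 + nv)]), "\\s+"))),
              ncol = 3, byrow = TRUE)
  fr <- strsplit(trimws(ln[(3 + nv):(2 + nv + nf)]), "\\s+")
  f <- t(vapply(fr, function(x) as.integer(x[2:4]) + 1L, integer(3)))
  surfaceMesh(v, f)
}

## minimal GIFTI (XML, ASCII-encoded data arrays)
giftiDataArray <- function(values, intent, datatype, dims) {
  di <- paste(vapply(seq_along(dims), function(i)
    sprintf('Dim%d="%d"', i - 1L, dims[i]), ""), collapse = " ")
  sprintf(paste0(
    '<DataArray Intent="%s" DataType="%s" ArrayIndexingOrder="RowMajorOrder" ',
    'Dimensionality="%d" %s Encoding="ASCII" Endian="LittleEndian" ',
    'ExternalFileName="" ExternalFileOffset="">\n<Data>%s</Data>\n</DataArray>'),
    intent, datatype, length(dims), di,
    paste(values, collapse = " "))
}

#' Write / read meshes and vertex scalars as GIFTI
#'
#' A minimal GIFTI implementation with ASCII-encoded data arrays: surface
#' files carry a POINTSET and a TRIANGLE array; functional files carry one
#' NIFTI_INTENT_SHAPE array per scalar.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path output path (`.gii` suggested).
#' @return `path` invisibly; the readers return a [SurfaceMesh-class] /
#'   [VertexScalars-class].
#' @export
writeMeshGifti <- function(mesh, path) {
  v <- meshVertices(mesh)
  f <- meshFaces(mesh) - 1L
  xml <- c('<?xml version="1.0" encoding="UTF-8"?>',
           '<GIFTI Version="1.0" NumberOfDataArrays="2">',
           giftiDataArray(sprintf("%.9g", t(v)), "NIFTI_INTENT_POINTSET",
                          "NIFTI_TYPE_FLOAT32", c(nrow(v), 3L)),
           giftiDataArray(sprintf("%d", t(f)), "NIFTI_INTENT_TRIANGLE",
                          "NIFTI_TYPE_INT32", c(nrow(f), 3L)),
           '</GIFTI>')
  writeLines(xml, path)
  invisible(path)
}

#' @rdname writeMeshGifti
#' @export
readMeshGifti <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  intents <- xml2::xml_attr(arrays, "Intent")
  getData <- function(node) {
    as.numeric(strsplit(trimws(xml2::xml_text(
      xml2::xml_find_first(node, ".//Data"))), "\\s+")[[1]])
  }
  vp <- which(intents == "NIFTI_INTENT_POINTSET")
  tp <- which(intents == "NIFTI_INTENT_TRIANGLE")
  if (!length(vp) || !length(tp))
    stop("GIFTI file lacks POINTSET/TRIANGLE arrays", call. = FALSE)
  v <- matrix(getData(arrays[[vp]]), ncol = 3, byrow = TRUE)
  f <- matrix(as.integer(getData(arrays[[tp]])), ncol = 3, byrow = TRUE) + 1L
  surfaceMesh(v, f)
}

#' @rdname writeMeshGifti
#' @param s a [VertexScalars-class].
#' @export
writeScalarsGifti <- function(s, path) {
  xml <- c('<?xml version="1.0" encoding="UTF-8"?>',
           '<GIFTI Version="1.0" NumberOfDataArrays="1">',
           giftiDataArray(sprintf("%.9g", scalarValues(s)),
                          "NIFTI_INTENT_SHAPE", "NIFTI_TYPE_FLOAT32",
                          length(scalarValues(s))),
           '</GIFTI>')
  writeLines(xml, path)
  invisible(path)
}

#' @rdname writeMeshGifti
#' @param name,units metadata for the scalars read back.
#' @export
readScalarsGifti <- function(path, name = "scalars", units = "") {
  doc <- xml2::read_xml(path)
  node <- xml2::xml_find_first(doc, ".//DataArray")
  vals <- as.numeric(strsplit(trimws(xml2::xml_text(
    xml2::xml_find_first(node, ".//Data"))), "\\s+")[[1]])
  new("VertexScalars", values = vals, name = name, units = units)
}

#' Write / read vertex scalars as CSV
#'
#' @param s a [VertexScalars-class].
#' @param path output path.
#' @return `path` invisibly; the reader returns a [VertexScalars-class].
#' @export
writeScalarsCsv <- function(s, path) {
  write.csv(data.frame(vertex = seq_along(scalarValues(s)),
                       value = scalarValues(s)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScalarsCsv
#' @param name,units metadata for the scalars read back.
#' @export
readScalarsCsv <- function(path, name = "scalars", units = "") {
  d <- read.csv(path)
  new("VertexScalars", values = as.numeric(d$value), name = name,
      units = units)
}

#' Write / read a deformation field as 4-D NIfTI
#'
#' Displacements (mm, world frame) are stored as a 4-D volume with the
#' x/y/z components along the fourth dimension; the Jacobian is recomputed
#' on read.
#'
#' @param field a [DeformationField-class].
#' @param path output path.
#' @return `path` invisibly; `readDeformation` returns a
#'   [DeformationField-class].
#' @export
writeDeformation <- function(field, path) {
  img <- RNifti::asNifti(field@displacement)
  RNifti::pixdim(img) <- voxelSize(field@grid)
  RNifti::sform(img) <- structure(volAffine(field@grid), code = 2L)
  RNifti::qform(img) <- structure(volAffine(field@grid), code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname writeDeformation
#' @export
readDeformation <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 4L || dim(a)[4] != 3L)
    stop("expected a 4-D displacement volume with 3 components", call. = FALSE)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  grid <- Volume(array(0, dim(a)[1:3]), affine = aff)
  d <- array(as.double(a), dim(a))
  field <- new("DeformationField", displacement = d, grid = grid,
               jacobian = newData(grid, 1))
  field@jacobian <- jacobianDet(field)
  field
}

#' Serialize a phantom spec to JSON and back
#'
#' @param spec a [PhantomSpec-class].
#' @param path output path.
#' @return `path` invisibly; the reader returns a [PhantomSpec-class].
#' @export
writePhantomSpec <- function(spec, path) {
  jsonlite::write_json(list(
    grid_shape = spec@gridShape, voxel_size = spec@voxelSize,
    wm_radius = spec@wmRadius, gm_thickness = spec@gmThickness,
    csf_thickness = spec@csfThickness, fold_amplitude = spec@foldAmplitude,
    fold_frequency = spec@foldFrequency,
    intensity_means = spec@intensityMeans,
    noise_percent = spec@noisePercent, bias_percent = spec@biasPercent,
    seed = spec@seed), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePhantomSpec
#' @export
readPhantomSpec <- function(path) {
  j <- jsonlite::fromJSON(path)
  phantomSpec(grid_shape = j$grid_shape, voxel_size = j$voxel_size,
              wm_radius = j$wm_radius, gm_thickness = j$gm_thickness,
              csf_thickness = j$csf_thickness,
              fold_amplitude = j$fold_amplitude,
              fold_frequency = j$fold_frequency,
              intensity_means = j$intensity_means,
              noise_percent = j$noise_percent,
              bias_percent = j$bias_percent, seed = j$seed)
}

#' Write a cohort to disk with a CSV manifest
#'
#' Saves each subject's image (and hard truth labels) as NIfTI under `dir`
#' and writes `manifest.csv` with subject id, group, TIV and file paths.
#'
#' @param cohort list from [generateCohort()].
#' @param dir output directory.
#' @return The manifest data.frame, invisibly.
#' @export
writeCohortManifest <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(s) {
    img <- file.path(dir, paste0(s$subject_id, "_T1.nii.gz"))
    lab <- file.path(dir, paste0(s$subject_id, "_labels.nii.gz"))
    writeVolume(s$image, img)
    writeVolume(s$truth@hardLabels, lab)
    data.frame(subject = s$subject_id, group = s$group, tiv_ml = s$tiv_ml,
               image = img, labels = lab)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
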