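## Region-based morphometry: atlas warping, regional tissue volumes in
## native space, regional mean thickness on surfaces.

#' Construct a volumetric or surface atlas
#'
#' @param labels integer label [Volume-class] (volumetric) or an integer
#'   vector of per-vertex codes (surface). Code 0 = unlabeled.
#' @param lut data.frame with columns `code`, `name`; defaults to
#'   auto-generated names for the codes present.
#' @return An [Atlas-class].
#' @export
makeAtlas <- function(labels, lut = NULL) {
  space <- if (is(labels, "Volume")) "volume" else "surface"
  codes <- if (space == "volume") unique(as.vector(volData(labels)))
           else unique(labels <- as.integer(labels))
  codes <- sort(setdiff(as.integer(round(codes)), 0L))
  if (is.null(lut))
    lut <- data.frame(code = codes, name = sprintf("region_%03d", codes))
  new("Atlas", labels = labels, lut = lut, space = space)
}

#' Warp a volumetric atlas through a deformation field
#'
#' Nearest-neighbour label pull-back from template space to native space;
#' the lookup table is preserved, and no new codes can appear.
#'
#' @param atlas a volumetric [Atlas-class] on the field's reference grid
#'   side ("template").
#' @param field a [DeformationField-class] mapping the target grid into the
#'   atlas grid.
#' @return The warped [Atlas-class].
#' @export
warpAtlas <- function(atlas, field) {
  if (atlas@space != "volume")
    stop("warpAtlas requires a volumetric atlas", call. = FALSE)
  lab <- volData(atlas@labels)
  if (any(abs(lab - round(lab)) > 1e-9))
    stop("atlas labels must be integer-valued", call. = FALSE)
  warped <- warpVolume(atlas@labels, field, interp = "nearest")
  makeAtlas(newData(warped, as.integer(round(volData(warped)))),
            lut = atlas@lut)
}

#' Regional tissue volumes in native space
#'
#' `gm_ml(region) = voxel_volume x sum(gm_fraction over the region)` and
#' analogously for WM and CSF; unlabeled voxels are excluded. Regions in the
#' lookup table that are absent from the label volume give a zero row with a
#' warning. Volumes are additive under region merging by construction.
#'
#' @param seg a [PveSegmentation-class].
#' @param atlas a volumetric [Atlas-class] on the same grid.
#' @param voxel_volume voxel volume, mm^3 (default from the grid).
#' @return data.frame: `code`, `region`, `gm_ml`, `wm_ml`, `csf_ml`.
#' @export
regionalVolumes <- function(seg, atlas, voxel_volume = NULL) {
  if (is.null(voxel_volume)) voxel_volume <- prod(voxelSize(seg@pveLabel))
  lab <- as.vector(volData(atlas@labels))
  stopifnot(length(lab) == length(volData(seg@pveLabel)))
  out <- data.frame(code = atlas@lut$code, region = atlas@lut$name,
                    gm_ml = 0, wm_ml = 0, csf_ml = 0)
  frac <- list(gm_ml = as.vector(volData(seg@gmFraction)),
               wm_ml = as.vector(volData(seg@prob$wm)),
               csf_ml = as.vector(volData(seg@prob$csf)))
  for (i in seq_len(nrow(out))) {
    sel <- lab == out$code[i]
    if (!any(sel)) {
      warning("region ", out$region[i], " (code ", out$code[i],
              ") absent from the label volume", call. = FALSE)
      next
    }
    for (f in names(frac))
      out[[f]][i] <- voxel_volume * sum(frac[[f]][sel]) / 1000
  }
  out
}

#' Regional mean cortical thickness
#'
#' Area-weighted mean thickness per surface region (vertex area = one third
#' of incident face areas).
#'
#' @param thickness a [VertexScalars-class] (mm).
#' @param atlas a surface [Atlas-class] with one code per vertex.
#' @param mesh the [SurfaceMesh-class] carrying the vertex areas.
#' @return data.frame: `code`, `region`, `mean_mm`, `area_mm2`.
#' @export
regionalThickness <- function(thickness, atlas, mesh) {
  if (atlas@space != "surface")
    stop("regionalThickness requires a surface atlas", call. = FALSE)
  lab <- as.integer(atlas@labels)
  v <- meshVertices(mesh)
  if (length(lab) != nrow(v))
    stop("label count must equal vertex count", call. = FALSE)
  if (all(lab == 0L)) stop("all vertices unlabeled", call. = FALSE)
  va <- meshVertexAreas(v, meshFaces(mesh))
  th <- scalarValues(thickness)
  out <- data.frame(code = atlas@lut$code, region = atlas@lut$name,
                    mean_mm = NA_real_, area_mm2 = 0)
  for (i in seq_len(nrow(out))) {
    sel <- lab == out$code[i]
    if (!any(sel)) next
    out$mean_mm[i] <- sum(th[sel] * va[sel]) / sum(va[sel])
    out$area_mm2[i] <- sum(va[sel])
  }
  out
}
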