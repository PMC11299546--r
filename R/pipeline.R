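## Cross-sectional pipeline orchestration: the mandatory voxel stream
## (denoise -> segment -> register) and the optional surface stream
## (thickness -> central surface -> folding metrics), plus study-level
## template building, smoothing and statistics.

#' Default pipeline configuration
#'
#' A single JSON-serializable list of stage toggles and parameters. Unknown
#' keys are rejected when merging user overrides.
#'
#' @param ... overrides of the defaults (nested lists merged by name).
#' @return Configuration list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    stages = list(denoise = TRUE, segment = TRUE, register = FALSE,
                  surface = TRUE, metrics = FALSE, qc = TRUE),
    denoise = list(beta = 1.0),
    segment = list(mrf_beta = 0.1, iters = 16, adaptive = TRUE,
                   adapt_fwhm_mm = 24),
    register = list(levels = 3, smooth_mm = 6),
    surface = list(),
    smoothing = list(volume_fwhm_mm = 6, surface_fwhm_mm = 12),
    stats = list(tail = "one", n_perm = 500, alpha = 0.05, fdr_q = 0.05),
    seed = 1L)
  over <- list(...)
  merge <- function(base, over, path = "") {
    for (k in names(over)) {
      if (!k %in% names(base))
        stop("unknown config key: ", path, k, call. = FALSE)
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge(base[[k]], over[[k]], paste0(path, k, ".")) else over[[k]]
    }
    base
  }
  merge(cfg, over)
}

#' Process one subject through the cross-sectional streams
#'
#' Runs denoise -> segment (-> register to a template, if given) and, when
#' the voxel stream succeeded and the surface toggle is on, the surface
#' stream (boundary distances, PBT thickness, central surface, optional
#' folding metrics). Any stage error aborts with the stage name; outputs of
#' completed stages are retained in the partial report.
#'
#' @param img a [Volume-class] or a NIfTI path.
#' @param config a [pipelineConfig()] list.
#' @param template optional template [Volume-class] to register to.
#' @param out_dir optional directory for NIfTI/CSV outputs.
#' @param longitudinal reserved; errors if TRUE (not implemented).
#' @return Subject report list (segmentation, TIV, QC, thickness summary,
#'   meshes, per-stage status).
#' @export
runSubject <- function(img, config = pipelineConfig(), template = NULL,
                       out_dir = NULL, longitudinal = FALSE) {
  if (isTRUE(longitudinal))
    stop("longitudinal stream not implemented", call. = FALSE)
  report <- list(stages_run = character(), outputs = character())
  stage <- function(name, expr) {
    r <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    report$stages_run <<- c(report$stages_run, name)
    r
  }
  vol <- stage("read_volume",
               if (is(img, "Volume")) img else readVolume(img))
  work <- vol
  if (isTRUE(config$stages$denoise))
    work <- stage("denoise", sanlmDenoise(work, beta = config$denoise$beta))
  seg <- NULL
  if (isTRUE(config$stages$segment)) {
    seg <- stage("segment", {
      mask <- volData(work) > 0.2 * max(volData(work))
      init <- initClasses(work, mask, mrf_beta = config$segment$mrf_beta)
      s <- amapSegment(work, init, iters = config$segment$iters,
                       mrf_beta = config$segment$mrf_beta,
                       adaptive = config$segment$adaptive,
                       adapt_fwhm_mm = config$segment$adapt_fwhm_mm)
      pveRefine(work, s)
    })
    report$tiv <- tivMl(seg)
    model <- segModel(seg)
    report$class_means <- vapply(model@classMeans,
                                 function(m) mean(volData(m)), 0)
  }
  if (isTRUE(config$stages$qc) && !is.null(seg))
    report$qc <- stage("qc", qcRate(work, seg))
  if (isTRUE(config$stages$register) && !is.null(template) && !is.null(seg)) {
    report$registration <- stage("register", {
      fld <- registerDiffeo(template, seg@gmFraction,
                            levels = config$register$levels,
                            smooth_mm = config$register$smooth_mm)
      wgm <- modulateVolume(warpVolume(seg@gmFraction, fld), fld@jacobian)
      list(field = fld, gm_modulated = wgm)
    })
  }
  if (isTRUE(config$stages$surface) && !is.null(seg)) {
    report$surface <- stage("surface", {
      bd <- boundaryDistances(seg)
      pbt <- pbtThickness(bd$wmd, bd$csfd, bd$gm_mask,
                          wmd_signed = bd$wmd_signed)
      surf <- extractCorticalSurfaces(pbt$central_level, pbt$thickness)
      th <- volData(pbt$thickness)
      list(thickness = pbt$thickness, central = surf$central,
           white = surf$white, pial = surf$pial,
           vertex_thickness = surf$vertex_thickness,
           mean_thickness_mm = mean(th[th > 0]))
    })
    if (isTRUE(config$stages$metrics)) {
      report$metrics <- stage("metrics", {
        ctr <- report$surface$central
        list(gyrification = gyrification(ctr),
             sulcal_depth = sulcalDepth(ctr))
      })
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(seg)) {
      for (nm in names(seg@prob)) {
        p <- file.path(out_dir, paste0("p_", nm, ".nii.gz"))
        writeVolume(seg@prob[[nm]], p)
        report$outputs <- c(report$outputs, p)
      }
      p <- file.path(out_dir, "pve_label.nii.gz")
      writeVolume(seg@pveLabel, p)
      report$outputs <- c(report$outputs, p)
    }
  }
  report$segmentation <- seg
  report
}

#' Run a two-group study on a phantom cohort
#'
#' Processes all subjects, builds a GM template, warps and modulates each
#' subject's GM map, smooths (6 mm default), and runs the TFCE permutation
#' group comparison plus the regional (FDR-corrected) table when an atlas
#' is supplied.
#'
#' @param cohort list from [generateCohort()] (or an equivalent list with
#'   `image`, `group`, `tiv_ml` entries), or the path to a manifest CSV
#'   with columns `subject`, `group`, `tiv_ml`, `image` (NIfTI paths), as
#'   written by [writeCohortManifest()].
#' @param config a [pipelineConfig()] list.
#' @param atlas optional template-space volumetric [Atlas-class].
#' @param template_iters template refinement iterations.
#' @return Study report list: subject reports, template, VBM stats,
#'   homogeneity table, optional ROI table.
#' @export
runStudy <- function(cohort, config = pipelineConfig(), atlas = NULL,
                     template_iters = 1L) {
  if (is.character(cohort)) {
    man <- read.csv(cohort)
    need <- c("subject", "group", "tiv_ml", "image")
    if (!all(need %in% names(man)))
      stop("manifest must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    cohort <- lapply(seq_len(nrow(man)), function(i)
      list(image = readVolume(man$image[i]), group = man$group[i],
           tiv_ml = man$tiv_ml[i], subject_id = man$subject[i]))
  }
  subjects <- lapply(cohort, function(s)
    runSubject(s$image, config = config))
  gms <- lapply(subjects, function(r) r$segmentation@gmFraction)
  tmpl <- buildTemplate(gms, n_iter = template_iters,
                        levels = config$register$levels,
                        smooth_mm = config$register$smooth_mm)
  warped <- vector("list", length(gms))
  fields <- vector("list", length(gms))
  for (i in seq_along(gms)) {
    fld <- registerDiffeo(tmpl, gms[[i]], levels = config$register$levels,
                          smooth_mm = config$register$smooth_mm)
    fields[[i]] <- fld
    wmod <- modulateVolume(warpVolume(gms[[i]], fld), fld@jacobian)
    warped[[i]] <- smoothFwhm(wmod, config$smoothing$volume_fwhm_mm)
  }
  Y <- do.call(rbind, lapply(warped, function(v) as.vector(volData(v))))
  tiv <- vapply(cohort, function(s) s$tiv_ml, 0)
  Y <- globalScalingTiv(Y, tiv)
  groups <- vapply(cohort, function(s) s$group, "")
  design <- makeDesign(groups, tail = config$stats$tail)
  fwe <- permutationFwe(Y, design, params = tfceParams(),
                        n_perm = config$stats$n_perm, seed = config$seed,
                        dims = dim(volData(tmpl)))
  homog <- sampleHomogeneity(warped)
  report <- list(subjects = subjects, template = tmpl, fields = fields,
                 vbm = fwe, homogeneity = homog, design = design)
  if (!is.null(atlas)) {
    tabs <- lapply(seq_along(cohort), function(i) {
      nat <- warpAtlas(atlas, fields[[i]])
      regionalVolumes(subjects[[i]]$segmentation, nat)
    })
    gm_mat <- do.call(rbind, lapply(tabs, function(t) t$gm_ml))
    pvals <- apply(gm_mat, 2, function(y) {
      if (sd(y) == 0) return(1)
      stats::t.test(y[groups == "A"], y[groups == "B"],
                    alternative = "greater", var.equal = TRUE)$p.value
    })
    report$roi <- data.frame(atlas@lut,
                             mean_A = colMeans(gm_mat[groups == "A", , drop = FALSE]),
                             mean_B = colMeans(gm_mat[groups == "B", , drop = FALSE]),
                             p = pvals,
                             fdr_reject = fdrBh(pvals, config$stats$fdr_q)$reject)
  }
  report
}
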