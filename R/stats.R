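## Second-level GLM, TFCE, permutation FWE with exchangeability blocks and
## Freedman-Lane nuisance handling, global scaling for TIV, and BH-FDR.

#' Build a two-group design with optional covariates
#'
#' @param group factor/character of group membership (two levels).
#' @param covariates optional numeric matrix/data.frame of nuisance
#'   regressors (e.g. age).
#' @param blocks exchangeability-block ids (default: one block).
#' @param tail "one" (default, group A > group B under the contrast) or "two".
#' @return A [Design-class] whose contrast tests the group difference.
#' @export
makeDesign <- function(group, covariates = NULL, blocks = NULL,
                       tail = c("one", "two")) {
  tail <- match.arg(tail)
  g <- factor(group)
  if (nlevels(g) != 2) stop("group must have exactly two levels", call. = FALSE)
  X <- cbind(1, as.numeric(g == levels(g)[1]))
  nm <- c("intercept", paste0("group_", levels(g)[1]))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    cn <- colnames(covariates)
    if (is.null(cn)) cn <- paste0("cov", seq_len(ncol(covariates)))
    ## centre nuisance covariates
    covariates <- sweep(covariates, 2, colMeans(covariates))
    X <- cbind(X, covariates)
    nm <- c(nm, cn)
  }
  ctr <- c(0, 1, rep(0, ncol(X) - 2))
  if (is.null(blocks)) blocks <- rep(1L, nrow(X))
  new("Design", matrix = X, names = nm, contrast = ctr,
      blocks = as.integer(as.factor(blocks)), tail = tail)
}

#' Element-wise GLM t statistics
#'
#' Ordinary least squares per element (voxel or vertex):
#' `t = c'beta / sqrt(sigma^2 c'(X'X)^-1 c)`.
#'
#' @param Y observations x elements data matrix.
#' @param design a [Design-class].
#' @return numeric t map (length = elements), with attribute `df`.
#' @export
fitGlm <- function(Y, design) {
  Y <- as.matrix(Y)
  X <- design@matrix
  if (nrow(Y) != nrow(X))
    stop("observations do not match design rows", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- design@names[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  XtXi <- chol2inv(qr.R(qx))
  beta <- XtXi %*% t(X) %*% Y
  res <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- colSums(res^2) / df
  cc <- design@contrast
  se <- sqrt(pmax(s2 * drop(t(cc) %*% XtXi %*% cc), 1e-300))
  t <- drop(cc %*% beta) / se
  attr(t, "df") <- df
  t
}

#' Global scaling by total intracranial volume
#'
#' Each subject's data are multiplied by `mean(TIV) / TIV_subject`, the
#' "global scaling" TIV correction for volume data.
#'
#' @param Y observations x elements matrix.
#' @param tiv per-subject TIV (any consistent unit), all positive.
#' @return Scaled matrix.
#' @export
globalScalingTiv <- function(Y, tiv) {
  if (any(tiv <= 0)) stop("TIV must be positive", call. = FALSE)
  Y <- as.matrix(Y)
  if (nrow(Y) != length(tiv))
    stop("tiv length must match rows of Y", call. = FALSE)
  Y * (mean(tiv) / tiv)
}

#' TFCE parameters
#'
#' Defaults follow the published TFCE recommendations: E = 0.5, H = 2 for
#' 3-D grids and E = 1, H = 2 for surface meshes; 100 threshold steps.
#'
#' @param E extent exponent.
#' @param H height exponent.
#' @param n_steps threshold steps.
#' @param connectivity grid connectivity (6, 18, 26).
#' @return A [TfceParams-class].
#' @export
tfceParams <- function(E = 0.5, H = 2, n_steps = 100L, connectivity = 26L) {
  new("TfceParams", E = E, H = H, nSteps = as.integer(n_steps),
      connectivity = as.integer(connectivity))
}

## CSR adjacency + extent weights for a grid or a mesh
tfceTopology <- function(stat, params, mesh = NULL) {
  if (!is.null(mesh)) {
    e <- meshEdges(meshFaces(mesh))
    nv <- nrow(meshVertices(mesh))
    deg_list <- split(c(e[, 2], e[, 1]) - 1L, c(e[, 1], e[, 2]))
    off <- integer(nv + 1)
    idx <- integer(0)
    nbr <- vector("list", nv)
    nbr[as.integer(names(deg_list))] <- deg_list
    lens <- lengths(nbr)
    off <- c(0L, cumsum(lens))
    idx <- unlist(nbr, use.names = FALSE)
    if (is.null(idx)) idx <- integer(0)
    list(offsets = off, neighbours = as.integer(idx),
         weights = meshVertexAreas(meshVertices(mesh), meshFaces(mesh)))
  } else {
    dm <- dim(stat)
    csr <- cpp_grid_csr(dm, params@connectivity)
    list(offsets = csr$offsets, neighbours = csr$neighbours,
         weights = rep(1, prod(dm)))
  }
}

#' Threshold-free cluster enhancement
#'
#' `TFCE(v) = sum_h e_v(h)^E h^H dh` over thresholds `h = dh ... h_v` with
#' `dh = max(stat)/n_steps`, clusters formed by the configured grid
#' connectivity or by mesh edge adjacency (extent = member area). With
#' `two_sided = TRUE` the negative tail is enhanced on the negated map and
#' subtracted.
#'
#' @param stat a 3-D array / [Volume-class], or a numeric vector when `mesh`
#'   is given.
#' @param params a [TfceParams-class].
#' @param mesh optional [SurfaceMesh-class] for surface maps.
#' @param two_sided enhance both tails.
#' @return Enhanced map, same shape as the input.
#' @export
tfceEnhance <- function(stat, params = tfceParams(), mesh = NULL,
                        two_sided = FALSE) {
  vol <- NULL
  if (is(stat, "Volume")) { vol <- stat; stat <- volData(stat) }
  a <- if (is.null(mesh)) as.array(stat) else as.numeric(stat)
  if (any(!is.finite(a))) stop("stat map must be finite", call. = FALSE)
  topo <- tfceTopology(a, params, mesh)
  enh <- function(x) cpp_tfce(as.double(pmax(x, 0)), topo$offsets,
                              topo$neighbours, topo$weights, params@E,
                              params@H, params@nSteps)
  out <- enh(as.vector(a))
  if (two_sided) out <- out - enh(-as.vector(a))
  if (!is.null(mesh)) return(out)
  out <- array(out, dim(a))
  if (!is.null(vol)) newData(vol, out) else out
}

## all within-block permutations if their number is <= cap, else NULL
enumerateBlockPermutations <- function(blocks, cap) {
  sizes <- table(blocks)
  total <- prod(factorial(as.numeric(sizes)))
  if (!is.finite(total) || total > cap) return(NULL)
  permsOf <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in permsOf(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  byblock <- lapply(split(seq_along(blocks), blocks), permsOf)
  grids <- expand.grid(lapply(byblock, seq_along))
  lapply(seq_len(nrow(grids)), function(r) {
    idx <- integer(length(blocks))
    for (b in seq_along(byblock)) {
      members <- split(seq_along(blocks), blocks)[[b]]
      idx[members] <- byblock[[b]][[grids[r, b]]]
    }
    idx
  })
}

#' Permutation-based family-wise error control of TFCE maps
#'
#' Freedman-Lane permutation: the reduced (nuisance-only) model is fitted,
#' its residuals are permuted within exchangeability blocks, and the full
#' model is refitted on each permuted dataset. The corrected p-value is
#' `p(v) = (1 + #{perm max-TFCE >= observed TFCE(v)}) / (n_perm + 1)`.
#' One-tailed when the design is one-sided. If fewer distinct permutations
#' exist than requested, they are enumerated exactly (noted in the result).
#'
#' @param Y observations x elements data matrix.
#' @param design a [Design-class].
#' @param params a [TfceParams-class].
#' @param n_perm number of permutations (>= 100 recommended).
#' @param seed RNG seed.
#' @param mesh optional [SurfaceMesh-class] for surface data.
#' @param dims optional grid dimensions when Y columns are voxels.
#' @return list: `p_corr` (corrected p per element), `tfce_obs`, `t_obs`,
#'   `null_max` (permutation max-TFCE distribution), `exact`.
#' @export
permutationFwe <- function(Y, design, params = tfceParams(), n_perm = 500L,
                           seed = 1L, mesh = NULL, dims = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  two_sided <- design@tail == "two"
  shapeStat <- function(t) {
    if (!is.null(mesh)) t else array(t, if (is.null(dims)) c(length(t), 1, 1)
                                     else dims)
  }
  enh <- function(t) {
    e <- tfceEnhance(shapeStat(t), params, mesh = mesh, two_sided = FALSE)
    ep <- as.vector(if (is.null(mesh)) e else e)
    if (two_sided) {
      en <- tfceEnhance(shapeStat(-t), params, mesh = mesh, two_sided = FALSE)
      pmax(ep, as.vector(en))
    } else ep
  }
  t_obs <- fitGlm(Y, design)
  tfce_obs <- enh(t_obs)
  ## Freedman-Lane: residualize on nuisance columns
  idx_int <- which(design@contrast != 0)
  Z <- design@matrix[, -idx_int, drop = FALSE]
  gam <- qr.solve(Z, Y)
  R <- Y - Z %*% gam
  fitted_red <- Z %*% gam
  perms <- enumerateBlockPermutations(design@blocks, n_perm)
  exact <- !is.null(perms)
  if (!exact) {
    perms <- withSeed(seed, lapply(seq_len(n_perm), function(i) {
      idx <- seq_len(n)
      for (b in unique(design@blocks)) {
        members <- which(design@blocks == b)
        idx[members] <- members[sample(length(members))]
      }
      idx
    }))
  }
  null_max <- vapply(perms, function(idx) {
    Ystar <- fitted_red + R[idx, , drop = FALSE]
    max(enh(fitGlm(Ystar, design)))
  }, 0)
  np <- length(null_max)
  p_corr <- vapply(tfce_obs, function(v) (1 + sum(null_max >= v)) / (np + 1),
                   0)
  list(p_corr = p_corr, tfce_obs = tfce_obs, t_obs = t_obs,
       null_max = null_max, exact = exact)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure at level `q` (via [stats::p.adjust()]), returning the
#' rejection mask and the adaptive p-value threshold.
#'
#' @param p p-values in [0, 1].
#' @param q FDR level.
#' @return list: `reject` logical mask, `threshold` (largest rejected p, 0
#'   if none), `n_rejected`.
#' @export
fdrBh <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  adj <- p.adjust(p, method = "BH")
  reject <- adj <= q
  list(reject = reject,
       threshold = if (any(reject)) max(p[reject]) else 0,
       n_rejected = sum(reject))
}
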