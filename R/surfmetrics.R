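## The four folding measures on central-surface meshes: gyrification
## (absolute mean curvature), sulcal depth (distance to the enclosing hull),
## fractal dimension (from band-limited spherical-harmonic reconstructions)
## and the local surface ratio.

#' Gyrification: absolute mean curvature
#'
#' Per-vertex absolute mean curvature |H| (1/mm) from the discrete cotangent
#' Laplace-Beltrami mean-curvature normal, averaged over a local
#' neighbourhood by surface smoothing.
#'
#' @param mesh a clean [SurfaceMesh-class].
#' @param average_fwhm_mm neighbourhood averaging FWHM, mm (default 3).
#' @return A [VertexScalars-class] in 1/mm.
#' @export
gyrification <- function(mesh, average_fwhm_mm = 3) {
  fa <- meshFaceAreas(meshVertices(mesh), meshFaces(mesh))
  if (any(fa < 1e-12))
    stop("mesh has degenerate faces", call. = FALSE)
  h <- abs(meshMeanCurvature(mesh))
  s <- new("VertexScalars", values = h, name = "gyrification", units = "1/mm")
  if (average_fwhm_mm > 0) s <- smoothSurfaceScalar(mesh, s, average_fwhm_mm)
  s@name <- "gyrification"
  s
}

#' Sulcal depth: distance to the enclosing hull
#'
#' Per-vertex Euclidean distance from the central surface to its enclosing
#' convex hull, computed as the minimum over the support planes spanned by
#' the mesh's own outward vertex normals (a rotation-covariant direction
#' set, so the measure is exactly invariant under rigid motion). Zero on
#' convex surfaces; non-negative everywhere.
#'
#' @param mesh a closed [SurfaceMesh-class].
#' @param sqrt_transform apply a square-root transform (default off).
#' @return A [VertexScalars-class] in mm.
#' @export
sulcalDepth <- function(mesh, sqrt_transform = FALSE) {
  v <- meshVertices(mesh)
  dirs <- meshVertexNormals(v, meshFaces(mesh))
  depth <- rep(Inf, nrow(v))
  chunk <- 256L
  for (s in seq(1, nrow(dirs), by = chunk)) {
    d <- dirs[s:min(s + chunk - 1L, nrow(dirs)), , drop = FALSE]
    proj <- v %*% t(d)                      # V x k
    h <- apply(proj, 2, max)                # support function
    depth <- pmin(depth, apply(sweep(proj, 2, h, "-") * -1, 1, min))
  }
  depth <- pmax(depth, 0)
  if (sqrt_transform) depth <- sqrt(depth)
  new("VertexScalars", values = depth, name = "sulcal_depth",
      units = if (sqrt_transform) "sqrt(mm)" else "mm")
}

#' Spherical parameterization of a genus-0 mesh
#'
#' Iterative Laplacian inflation with per-step projection to the unit
#' sphere, followed by tangential area-distortion relaxation. Returns the
#' map and the per-vertex area-distortion ratio (spherical / original,
#' normalised to mean 1).
#'
#' @param mesh a genus-0 [SurfaceMesh-class].
#' @param n_iter inflation iterations.
#' @param relax_iter distortion-relaxation iterations.
#' @return A [SphereMap-class].
#' @export
sphericalParameterize <- function(mesh, n_iter = 10L, relax_iter = 60L) {
  if (mesh@genus != 0L)
    stop("spherical parameterization requires genus 0, got ", mesh@genus,
         call. = FALSE)
  v <- meshVertices(mesh)
  f <- meshFaces(mesh)
  e <- meshEdges(f)
  nv <- nrow(v)
  a0 <- meshVertexAreas(v, f)
  ctr <- colSums(v * a0) / sum(a0)
  x <- sweep(v, 2, ctr)
  rad <- sqrt(rowSums(x^2))
  x <- x / pmax(rad, 1e-12)
  ## an already-spherical mesh maps by pure radial projection
  if (diff(range(rad)) / mean(rad) < 1e-6) {
    as_ <- meshVertexAreas(x, f)
    distortion <- (as_ / sum(as_)) / (a0 / sum(a0))
    return(new("SphereMap", coords = x, areaDistortion = distortion))
  }
  L <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(nv, nv))
  deg <- pmax(tabulate(c(e[, 1], e[, 2]), nbins = nv), 1)
  ## inflation: mild tangential Laplacian smoothing with reprojection; the
  ## radial projection of a star-shaped surface is already bijective, so a
  ## few iterations suffice to regularise badly shaped triangles
  for (it in seq_len(n_iter)) {
    xc <- as.matrix(L %*% x) / deg
    x <- x + 0.2 * (xc - x)
    x <- x / pmax(sqrt(rowSums(x^2)), 1e-12)
  }
  ## area-distortion relaxation: vertices migrate towards expanded regions
  ## (high spherical-to-original area ratio), vacating compressed ones
  for (it in seq_len(relax_iter)) {
    as_ <- meshVertexAreas(x, f)
    ratio <- (as_ / sum(as_)) / (a0 / sum(a0))
    w <- pmin(pmax(ratio, 1e-3), 1e3)
    xc <- as.matrix(L %*% (x * w)) / as.vector(L %*% w)
    x2 <- x + 0.3 * (xc - x)
    x2 <- x2 / pmax(sqrt(rowSums(x2^2)), 1e-12)
    x <- x2
  }
  as_ <- meshVertexAreas(x, f)
  distortion <- (as_ / sum(as_)) / (a0 / sum(a0))
  new("SphereMap", coords = x, areaDistortion = distortion)
}

## count faces whose spherical orientation is flipped (negative signed
## volume of the spherical triangle w.r.t. the origin)
sphereFlippedFaces <- function(map, faces) {
  x <- map@coords
  a <- x[faces[, 1], , drop = FALSE]
  b <- x[faces[, 2], , drop = FALSE]
  cc <- x[faces[, 3], , drop = FALSE]
  s <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
       a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
       a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  sum(s <= 0)
}

## real orthonormal spherical-harmonic basis evaluated at unit vectors;
## returns V x (lmax+1)^2 matrix, using pracma's associated Legendre
shBasis <- function(coords, lmax) {
  ct <- pmin(1, pmax(-1, coords[, 3]))
  phi <- atan2(coords[, 2], coords[, 1])
  nb <- (lmax + 1L)^2
  B <- matrix(0, nrow(coords), nb)
  col <- 1L
  for (l in 0:lmax) {
    P <- pracma::legendre(l, ct)           # (l+1) x V, rows m = 0..l
    if (is.null(dim(P))) P <- matrix(P, nrow = 1)
    for (m in -l:l) {
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      Pm <- P[am + 1, ]
      B[, col] <- if (m > 0) sqrt(2) * nrm * Pm * cos(m * phi)
        else if (m < 0) sqrt(2) * nrm * Pm * sin(am * phi)
        else nrm * Pm
      col <- col + 1L
    }
  }
  B
}

#' Fractal dimension from spherical-harmonic reconstructions
#'
#' Vertex coordinates are expanded in spherical harmonics on the sphere map;
#' band-limited surfaces are reconstructed at degrees l = 2, 4, ..., l_max
#' and the fractal dimension is `2 + slope` of log(reconstructed area)
#' against log(l) over the scaling regime `l in [l_lo, l_max]`. A perfectly
#' smooth sphere has constant areas and FD = 2.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param map its [SphereMap-class] (from [sphericalParameterize()]).
#' @param l_max maximum SH degree (>= 8; default 32; reduced if the mesh has
#'   too few vertices to support the basis).
#' @param l_lo lower edge of the scaling regime (default 8).
#' @return scalar FD, with attribute `areas` (per-degree reconstructed areas).
#' @export
fractalDimension <- function(mesh, map, l_max = 32L, l_lo = 8L) {
  if (l_max < 8) stop("l_max must be >= 8", call. = FALSE)
  v <- meshVertices(mesh)
  f <- meshFaces(mesh)
  nv <- nrow(v)
  l_max <- min(l_max, max(8L, floor(sqrt(nv / 2)) - 1L))
  B <- shBasis(map@coords, l_max)
  w <- meshVertexAreas(map@coords, f)
  ## weighted least squares with a small ridge for stability
  BtW <- t(B * w)
  G <- BtW %*% B
  diag(G) <- diag(G) + 1e-8 * mean(diag(G))
  coef <- solve(G, BtW %*% v)
  degs <- seq(2L, l_max, by = 2L)
  areas <- vapply(degs, function(l) {
    keep <- rep(0:l_max, times = 2 * (0:l_max) + 1) <= l
    sum(meshFaceAreas(B[, keep, drop = FALSE] %*% coef[keep, , drop = FALSE],
                      f))
  }, 0)
  sel <- degs >= l_lo
  fit <- stats::lm.fit(cbind(1, log(degs[sel])), log(areas[sel]))
  fd <- 2 + unname(fit$coefficients[2])
  attr(fd, "areas") <- setNames(areas, degs)
  fd
}

#' Local surface ratio
#'
#' Per-vertex ratio between the mesh area contained in a Euclidean ball of
#' radius `radius_mm` and the area of a disk with the same radius; boundary
#' triangles are clipped by recursive subdivision. A flat patch gives 1;
#' folding gives values above 1.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param radius_mm ball radius (default 20 mm).
#' @param vertices integer vertex subset (default all).
#' @param depth clipping subdivision depth.
#' @return A [VertexScalars-class] (dimensionless) over the queried
#'   vertices; the vertex subset is stored in the attribute `vertices`.
#' @export
surfaceRatio <- function(mesh, radius_mm = 20, vertices = NULL, depth = 3L) {
  v <- meshVertices(mesh)
  if (is.null(vertices)) vertices <- seq_len(nrow(v))
  r <- cpp_surface_ratio(v, meshFaces(mesh), as.integer(vertices),
                         radius_mm, as.integer(depth))
  out <- new("VertexScalars", values = as.numeric(r), name = "surface_ratio",
             units = "")
  attr(out, "vertices") <- as.integer(vertices)
  out
}
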