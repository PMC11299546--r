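test_that("GLM t statistics match the pooled two-sample formula", {
  ## groups {1,2,3} vs {4,5,6}: pooled-variance two-sample t = -3.674
  des <- makeDesign(rep(c("A", "B"), each = 3), tail = "two")
  Y <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  t1 <- as.numeric(fitGlm(Y, des))
  expect_equal(t1, -3 / sqrt(1 * (1 / 3 + 1 / 3)), tolerance = 1e-6)
  expect_equal(t1, -3.674, tolerance = 1e-3)
  ## the group contrast is orthogonal to a constant shift
  set.seed(2)
  Yr <- matrix(rnorm(6 * 8), 6)
  expect_equal(fitGlm(Yr + 5, des), fitGlm(Yr, des), tolerance = 1e-9)
  ## duplicated regressor is rejected as rank deficient
  X <- cbind(des@matrix, dup = des@matrix[, 2])
  expect_error(new("Design", matrix = X, names = c(des@names, "dup"),
                   contrast = c(des@contrast, 0), blocks = des@blocks,
                   tail = "two"),
               "full column rank")
  ## residuals orthogonal to the design
  set.seed(1)
  Y3 <- matrix(rnorm(6 * 50), 6)
  b <- qr.solve(des@matrix, Y3)
  res <- Y3 - des@matrix %*% b
  expect_lt(max(abs(t(des@matrix) %*% res)), 1e-8)
})

test_that("global scaling removes TIV proportionality", {
  Y <- matrix(rnorm(8 * 10, 100, 1), 8, 10)
  expect_equal(globalScalingTiv(Y, rep(3, 8)), Y)
  sc <- globalScalingTiv(Y, c(rep(1, 7), 2 * mean(rep(1, 7)) * 8 - 7))
  ## subject with TIV = 2 x mean has data halved
  tiv <- c(1, 1, 1, 1, 1, 1, 1, 1) * 1000
  tiv[5] <- 2 * mean(tiv[-5]) # approx; recompute exactly below
  tiv <- rep(1000, 8); tiv[5] <- 2000
  sc <- globalScalingTiv(Y, tiv)
  expect_equal(sc[5, ], Y[5, ] * mean(tiv) / 2000)
  expect_error(globalScalingTiv(Y, c(rep(1, 7), 0)), "positive")
  ## cohort built proportional to TIV decorrelates after scaling
  set.seed(3)
  tiv2 <- runif(30, 1200, 1800)
  Y2 <- outer(tiv2, runif(20, 0.4, 0.6)) + rnorm(600, 0, 1)
  s2 <- globalScalingTiv(Y2, tiv2)
  expect_lt(abs(cor(rowSums(s2), tiv2)), 0.2)
  expect_gt(abs(cor(rowSums(Y2), tiv2)), 0.95)
})

test_that("TFCE matches a brute-force threshold-summation oracle", {
  oracle <- function(a, E, H, nsteps, conn = 26) {
    dm <- dim(a)
    vmax <- max(pmax(a, 0))
    if (vmax <= 0) return(array(0, dm))
    dh <- vmax / nsteps
    out <- array(0, dm)
    csr <- brainmorph:::cpp_grid_csr(dm, conn)
    for (s in 1:nsteps) {
      h <- s * dh
      sup <- as.vector(a) >= h
      if (!any(sup)) next
      el <- c()
      for (v in which(sup)) {
        nb <- csr$neighbours[seq.int(csr$offsets[v] + 1,
                                     csr$offsets[v + 1])] + 1L
        nb <- nb[sup[nb] & nb > v]
        if (length(nb)) el <- c(el, rbind(v, nb))
      }
      g <- igraph::make_empty_graph(n = prod(dm), directed = FALSE)
      if (length(el)) g <- igraph::add_edges(g, el)
      comp <- igraph::components(g)
      sizes <- comp$csize[comp$membership]
      out[sup] <- out[sup] + sizes[sup]^E * h^H * dh
    }
    out
  }
  set.seed(42)
  a <- array(rnorm(12^3), c(12, 12, 12))
  p <- tfceParams(E = 0.5, H = 2, n_steps = 50, connectivity = 26)
  mine <- tfceEnhance(a, p)
  expect_equal(mine, oracle(a, 0.5, 2, 50), tolerance = 1e-8)
  ## mesh variant vs the same oracle logic on edge adjacency
  mesh <- icosphere(2, radius = 10)
  set.seed(7)
  vals <- rnorm(nrow(meshVertices(mesh)))
  pm <- tfceParams(E = 1, H = 2, n_steps = 40)
  em <- tfceEnhance(vals, pm, mesh = mesh)
  ## oracle on the mesh: per threshold, components of suprathreshold
  ## vertices weighted by vertex area
  va <- brainmorph:::meshVertexAreas(meshVertices(mesh), meshFaces(mesh))
  e <- brainmorph:::meshEdges(meshFaces(mesh))
  dh <- max(vals) / 40
  orc <- numeric(length(vals))
  for (s in 1:40) {
    h <- s * dh
    sup <- vals >= h
    if (!any(sup)) next
    keep <- sup[e[, 1]] & sup[e[, 2]]
    g <- igraph::graph_from_edgelist(e[keep, , drop = FALSE],
                                     directed = FALSE)
    g <- igraph::add_vertices(g, length(vals) - igraph::vcount(g))
    comp <- igraph::components(g)
    ext <- rowsum(va * sup, comp$membership)[comp$membership]
    orc[sup] <- orc[sup] + ext[sup]^1 * h^2 * dh
  }
  expect_equal(em, orc, tolerance = 1e-8)
})

test_that("TFCE closed form, zero map and monotonicity hold", {
  z <- array(0, c(8, 8, 8))
  expect_true(all(tfceEnhance(z, tfceParams()) == 0))
  ## isolated voxel of height 2: sum over thresholds of 1^E h^H dh
  b <- array(0, c(9, 9, 9)); b[5, 5, 5] <- 2
  e <- tfceEnhance(b, tfceParams(n_steps = 100))
  dh <- 2 / 100
  expect_equal(e[5, 5, 5], sum(((1:100) * dh)^2 * dh), tolerance = 1e-10)
  ## monotonicity over random perturbations
  set.seed(11)
  a <- array(rnorm(10^3), c(10, 10, 10))
  p <- tfceParams(n_steps = 30)
  base <- tfceEnhance(a, p)
  mx <- which.max(a)
  for (i in 1:20) {
    v <- sample(setdiff(seq_len(1000), mx), 1)
    a2 <- a
    a2[v] <- a2[v] + runif(1, 0, 0.9 * (max(a) - a2[v]))
    expect_true(all(tfceEnhance(a2, p) - base >= -1e-9))
  }
})

test_that("permutation p-values respect their floor and block structure", {
  set.seed(4)
  Y <- matrix(rnorm(12 * 50), 12)
  des <- makeDesign(rep(c("A", "B"), 6), blocks = rep(1:2, each = 6))
  r <- permutationFwe(Y, des, tfceParams(n_steps = 30), n_perm = 99,
                      seed = 2, dims = c(50, 1, 1))
  expect_true(all(r$p_corr >= 1 / 100))
  expect_false(r$exact)
  ## reordering observations together with blocks leaves p-values unchanged
  ord <- sample(12)
  des2 <- makeDesign(rep(c("A", "B"), 6)[ord],
                     blocks = rep(1:2, each = 6)[ord])
  r2 <- permutationFwe(Y[ord, ], des2, tfceParams(n_steps = 30),
                       n_perm = 99, seed = 2, dims = c(50, 1, 1))
  expect_equal(sort(r$t_obs), sort(r2$t_obs), tolerance = 1e-10)
  ## small designs enumerate exactly
  des3 <- makeDesign(rep(c("A", "B"), 2))
  r3 <- permutationFwe(matrix(rnorm(4 * 5), 4), des3,
                       tfceParams(n_steps = 20), n_perm = 500, seed = 1,
                       dims = c(5, 1, 1))
  expect_true(r3$exact)
  expect_identical(length(r3$null_max), 24L) # 4! permutations
})

test_that("BH-FDR matches the hand example and an exhaustive oracle", {
  r <- fdrBh(c(0.001, 0.01, 0.02, 0.03, 0.5), q = 0.05)
  expect_identical(r$n_rejected, 4L)
  expect_identical(fdrBh(rep(1, 10), 0.05)$n_rejected, 0L)
  ## exhaustive step-up oracle on random vectors
  oracle <- function(p, q) {
    n <- length(p)
    o <- order(p)
    k <- which(p[o] <= q * seq_len(n) / n)
    if (!length(k)) return(logical(n))
    p <= p[o][max(k)]
  }
  set.seed(8)
  for (i in 1:100) {
    p <- runif(sample(5:40, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    expect_identical(fdrBh(p, q)$reject, oracle(p, q))
  }
})
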