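test_that("posterior covariance reduces to the plain genotype covariance on
           certain genotypes", {
  set.seed(40)
  g <- matrix(sample(0:2, 200, replace = TRUE), 40, 5)
  cmat <- covariance_from_posteriors(g)
  f <- rowMeans(g) / 2
  x <- g - 2 * f
  expect_equal(cmat, (crossprod(x) / 40 + t(crossprod(x) / 40)) / 2,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("posterior covariance matches direct summation and is equivariant", {
  set.seed(41)
  M <- 50; n <- 5
  p1 <- matrix(runif(M * n), M, n); p2 <- matrix(runif(M * n), M, n)
  p0 <- matrix(runif(M * n), M, n)
  tot <- p0 + p1 + p2
  p0 <- p0 / tot; p1 <- p1 / tot; p2 <- p2 / tot
  gp <- structure(list(p0 = p0, p1 = p1, p2 = p2,
                       eg = p1 + 2 * p2, eg2 = p1 + 4 * p2,
                       f = runif(M)), class = "geno_posterior")
  w <- runif(M)
  cmat <- covariance_from_posteriors(gp, weights = w)
  expect_lt(max(abs(cmat - covariance_direct(gp$eg, gp$eg2, gp$f, w))), 1e-10)
  expect_equal(cmat, t(cmat))
  # permuting individuals permutes rows and columns identically
  perm <- c(3, 1, 5, 2, 4)
  gp_p <- gp
  for (nm in c("p0", "p1", "p2", "eg", "eg2")) gp_p[[nm]] <- gp[[nm]][, perm]
  cp <- covariance_from_posteriors(gp_p, weights = w)
  expect_equal(cp, cmat[perm, perm], tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(covariance_from_posteriors(gp, weights = rep(0, M)),
               "degenerate")
})

test_that("PCA projection: axis recovery, eigen residuals, sign convention", {
  cmat <- diag(c(3, 2, 1))
  pr <- pca_project(cmat)
  expect_equal(abs(pr$coords[, 1]), c(sqrt(3), 0, 0))
  # returned pairs satisfy C v = lambda v
  set.seed(42)
  a <- matrix(rnorm(49), 7, 7); cmat2 <- crossprod(a)
  pr2 <- pca_project(cmat2)
  e <- eigen(cmat2, symmetric = TRUE)
  for (k in 1:2) {
    v <- pr2$coords[, k] / sqrt(e$values[k])
    expect_lt(max(abs(cmat2 %*% v - e$values[k] * v)), 1e-8)
    expect_gt(v[which.max(abs(v))], 0)  # deterministic sign
  }
  # identical rows produce identical coordinates within clusters
  g <- cbind(matrix(1, 4, 3), matrix(0, 4, 3)) + 0
  cc <- covariance_from_posteriors(g, diag_method = "naive")
  prc <- pca_project(cc)
  expect_lt(max(dist(prc$coords[1:3, ])), 1e-6)
  expect_error(pca_project(matrix(c(1, NA, NA, 1), 2)), "finite")
})

test_that("Procrustes alignment recovers constructed transforms", {
  set.seed(43)
  x <- matrix(rnorm(40), 20, 2)
  # identity: zero residual
  id <- procrustes_align(x, x)
  expect_lt(id$rss, 1e-20)
  expect_equal(id$scale, 1, tolerance = 1e-12)
  # 90-degree rotation and doubling are undone exactly
  rot90 <- matrix(c(0, -1, 1, 0), 2)
  y <- 2 * x %*% rot90 + matrix(c(3, -1), 20, 2, byrow = TRUE)
  al <- procrustes_align(y, x)
  expect_lt(al$rss, 1e-18)
  # optimality: residual never exceeds the unaligned sum of squares
  z <- matrix(rnorm(40), 20, 2)
  expect_lte(procrustes_align(z, x)$rss, sum((x - z)^2) + 1e-12)
  expect_error(procrustes_align(matrix(1, 5, 2), x[1:5, ]), "degenerate")
})

test_that("Procrustes alignment agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(44)
  x <- matrix(rnorm(60), 30, 2)
  y <- matrix(rnorm(60), 30, 2)
  ours <- procrustes_align(y, x)
  ref <- vegan::procrustes(x, y)
  center <- function(m) sweep(m, 2, colMeans(m))
  expect_equal(center(ours$aligned), center(unclass(ref$Yrot)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(ours$rss, sum(stats::residuals(ref)^2), tolerance = 1e-8)
})

test_that("structure decision model separates well-separated clusters", {
  set.seed(45)
  centers <- matrix(c(0, 0, 4, 0, 2, 4), 3, 2, byrow = TRUE)
  labels <- rep(paste0("pop", 1:3), each = 30)
  coords <- centers[rep(1:3, each = 30), ] + matrix(rnorm(180, sd = 0.3), 90, 2)
  m <- fit_structure_model(coords, labels)
  expect_equal(mean(as.character(stats::predict(m, coords)) == labels), 1)
  # determinism: refitting the same data gives an identical decision map
  m2 <- fit_structure_model(coords, labels)
  g1 <- grid_compare(m, m2, coords)
  expect_equal(g1$mislabel_fraction, 0)
  # decision map agrees with nearest-centroid labels away from boundaries
  grid <- g1$grid
  d2 <- apply(grid, 1, function(pt) sort(colSums((t(centers) - pt)^2))[1:2])
  ncl <- apply(grid, 1, function(pt)
    which.min(colSums((t(centers) - pt)^2)))
  clear <- d2[2, ] > 1.5 * d2[1, ]  # cells away from decision boundaries
  agree <- as.integer(factor(as.character(g1$labels_known),
                             paste0("pop", 1:3))) == ncl
  expect_gt(mean(agree[clear]), 0.95)
  expect_error(fit_structure_model(coords, rep("pop1", 90)), "two populations")
})

test_that("grid comparison quantifies disagreement regions", {
  set.seed(46)
  labels <- rep(c("a", "b", "c"), each = 20)
  coords <- matrix(rnorm(120, sd = 0.25), 60, 2) +
    matrix(c(0, 0, 3, 0, 1.5, 3), 3, 2, byrow = TRUE)[rep(1:3, each = 20), ]
  m1 <- fit_structure_model(coords, labels)
  # swapping two labels mislabels roughly those populations' region share
  labels_sw <- labels
  labels_sw[labels == "b"] <- "c"; labels_sw[labels == "c"] <- "b"
  m2 <- fit_structure_model(coords, labels_sw)
  cmp <- grid_compare(m1, m2, coords, grid_size = c(40, 40))
  share_bc <- mean(g <- as.character(cmp$labels_known) %in% c("b", "c"))
  expect_equal(cmp$mislabel_fraction, share_bc, tolerance = 1e-12)
  expect_equal(dim(cmp$grid), c(1600L, 2L))
})

test_that("the full chain yields a zero mislabel fraction without uncertainty", {
  set.seed(47)
  ppp <- 15L
  fr <- draw_ancestral_freqs(sim_config(800, n_individuals = 45))
  fr <- draw_subpop_freqs(fr, structure_config(0.3, 0.05, ppp, 1))
  g <- do.call(cbind, lapply(1:3, function(k)
    draw_genotypes(fr$freq_subpop[, k], ppp)))
  labels <- rep(paste0("pop", 1:3), each = ppp)
  pk <- pca_project(covariance_from_posteriors(g))
  mk <- fit_structure_model(pk$coords, labels)
  # point-mass posteriors, unit weights: identical covariance, PCA, model
  saf <- saf_posterior(genolik_from_genotypes(g), prior = "uniform")
  gp <- genotype_posterior(genolik_from_genotypes(g), rowMeans(g) / 2)
  cs <- covariance_from_posteriors(gp, f = rowMeans(g) / 2,
                                   weights = rep(1, 800))
  ps <- pca_project(cs)
  pro <- procrustes_align(ps$coords, pk$coords)
  expect_lt(pro$rss, 1e-12)
  ms <- fit_structure_model(pro$aligned, labels)
  expect_equal(grid_compare(mk, ms, pk$coords)$mislabel_fraction, 0)
  expect_identical(saf$p_variable > 0.5,
                   rowSums(g) > 0 & rowSums(g) < 2 * 45)
})
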