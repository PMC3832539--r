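#' Genotype covariance matrix from posterior expectations
#'
#' Individual-by-individual covariance of genotypes about twice the per-site
#' allele frequency,
#' `C[a,b] = sum_s w_s (E[g_as] - 2 f_s)(E[g_bs] - 2 f_s) / sum_s w_s`,
#' with `E[g]` the posterior-mean genotype and weights `w_s` the per-site
#' probability of being variable. The per-site variance normalisation
#' `f (1 - f)` is deliberately not applied: it over-weights rare variants,
#' whose frequencies are the least confidently estimated at low depth. On the
#' diagonal the posterior second moment `E[g^2]` replaces `E[g]^2`
#' (`diag_method = "second_moment"`), since the outer product of posterior
#' means understates self-covariance under genotype uncertainty; the naive
#' variant is available for comparison.
#'
#' With point-mass posteriors (known genotypes) and unit weights this is the
#' plain unnormalised genotype covariance.
#'
#' @param gp a `geno_posterior` object from [genotype_posterior()], or a
#'   bare sites x individuals matrix of genotypes / posterior-mean genotypes.
#' @param f per-site allele frequencies used for centring; defaults to the
#'   frequencies stored in `gp` (or sample means for a bare matrix).
#' @param weights per-site weights, typically `p_variable`; default 1.
#' @param diag_method `"second_moment"` (default) or `"naive"`.
#' @return individuals x individuals covariance matrix.
#' @export
covariance_from_posteriors <- function(gp, f = NULL, weights = NULL,
                                       diag_method = c("second_moment", "naive")) {
  diag_method <- match.arg(diag_method)
  if (is.matrix(gp)) {
    eg <- gp
    eg2 <- gp^2
    if (is.null(f)) f <- rowMeans(gp) / 2
  } else {
    stopifnot(inherits(gp, "geno_posterior"))
    eg <- gp$eg; eg2 <- gp$eg2
    if (is.null(f)) f <- gp$f
  }
  M <- nrow(eg)
  if (is.null(weights)) weights <- rep(1, M)
  stopifnot(length(f) == M, length(weights) == M, all(weights >= 0))
  wsum <- sum(weights)
  if (wsum <= 0) stop("zero total site weight: degenerate input")
  x <- eg - 2 * f
  cmat <- crossprod(x * weights, x) / wsum
  if (diag_method == "second_moment") {
    # E[(g - 2f)^2] = E[g^2] - 2 E[g] 2f + (2f)^2; replaces E[g]^2 terms
    diag(cmat) <- colSums(weights * (eg2 - 4 * f * eg + 4 * f^2)) / wsum
  }
  cmat <- (cmat + t(cmat)) / 2
  attr(cmat, "weights_sum") <- wsum
  cmat
}

#' Project individuals onto the first two principal components
#'
#' Eigendecomposition of the covariance matrix; individuals are placed at the
#' top-two eigenvectors scaled by the square roots of their eigenvalues.
#' Sign convention: within each component the coordinate of largest magnitude
#' is positive, making the output deterministic.
#'
#' @param cmat symmetric covariance matrix from
#'   [covariance_from_posteriors()].
#' @return list of class `pca_proj` with `coords` (individuals x 2),
#'   `values` (all eigenvalues) and `var_explained` (first two, as fractions
#'   of the total positive eigenvalue mass).
#' @export
pca_project <- function(cmat) {
  if (any(!is.finite(cmat))) stop("non-finite covariance entries")
  e <- eigen(cmat, symmetric = TRUE)
  v <- e$vectors[, 1:2, drop = FALSE]
  for (k in 1:2) if (v[which.max(abs(v[, k])), k] < 0) v[, k] <- -v[, k]
  coords <- sweep(v, 2L, sqrt(pmax(e$values[1:2], 0)), `*`)
  colnames(coords) <- c("PC1", "PC2")
  structure(list(coords = coords, values = e$values,
                 var_explained = pmax(e$values[1:2], 0) /
                   sum(pmax(e$values, 0))),
            class = "pca_proj")
}

#' @export
print.pca_proj <- function(x, ...) {
  cat(sprintf("PCA projection of %d individuals; PC1/PC2 explain %.1f%% / %.1f%%\n",
              nrow(x$coords), 100 * x$var_explained[1], 100 * x$var_explained[2]))
  invisible(x)
}

#' Procrustes alignment of one PC configuration onto another
#'
#' Finds the translation, rotation (reflection permitted) and uniform scale
#' of the source configuration minimising the sum of squared distances to
#' the target: rotation from the SVD of the centred cross-product, scale
#' from the trace ratio. Used to place sequencing-based PC coordinates on
#' the known-genotype plane before any comparison.
#'
#' @param coords_src source configuration (n x 2), e.g. sequencing-based PCs.
#' @param coords_target target configuration (n x 2), e.g. known-genotype
#'   PCs for the same individuals.
#' @return list of class `procrustes_fit`: `aligned` coordinates, `rotation`,
#'   `scale`, `translation` and the residual sum of squares `rss`.
#' @export
procrustes_align <- function(coords_src, coords_target) {
  coords_src <- as.matrix(coords_src); coords_target <- as.matrix(coords_target)
  stopifnot(all(dim(coords_src) == dim(coords_target)))
  mu_s <- colMeans(coords_src); mu_t <- colMeans(coords_target)
  xs <- sweep(coords_src, 2L, mu_s); xt <- sweep(coords_target, 2L, mu_t)
  ss <- sum(xs^2)
  if (ss == 0) stop("degenerate source configuration (all points identical)")
  sv <- svd(crossprod(xs, xt))
  rot <- sv$u %*% t(sv$v)
  scl <- sum(sv$d) / ss
  aligned <- scl * xs %*% rot
  aligned <- sweep(aligned, 2L, mu_t, `+`)
  structure(list(aligned = aligned, rotation = rot, scale = scl,
                 translation = mu_t - scl * as.vector(mu_s %*% rot),
                 rss = sum((coords_target - aligned)^2)),
            class = "procrustes_fit")
}

#' Fit a decision model of population structure on the PC plane
#'
#' Multi-class support vector machine (radial kernel, fixed soft-margin cost)
#' on the 2-D coordinates, with population labels as classes. Training is
#' deterministic given the data.
#'
#' @param coords individuals x 2 coordinate matrix.
#' @param labels per-individual population labels.
#' @param kernel,cost SVM kernel and soft-margin constant (see
#'   [e1071::svm()]).
#' @return a fitted `e1071::svm` model.
#' @export
fit_structure_model <- function(coords, labels, kernel = "radial", cost = 1) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("at least two populations required")
  coords <- as.matrix(coords)
  colnames(coords) <- c("PC1", "PC2")
  e1071::svm(x = coords, y = labels, kernel = kernel, cost = cost,
             scale = FALSE)
}

#' Compare two structure models over a regular grid of the PC plane
#'
#' Partitions the bounding box of the reference (known-genotype) coordinates
#' into an equal grid, predicts the population at every cell centre under
#' both models, and reports the proportion of cells where they disagree —
#' the structure-prediction error surface.
#'
#' @param model_known,model_seq fitted models from [fit_structure_model()],
#'   trained on the shared (Procrustes-aligned) plane.
#' @param coords_known reference coordinates whose bounding box defines the
#'   grid.
#' @param grid_size `c(rows, cols)`; defaults to the dense 50 x 50 grid.
#' @return list of class `grid_prediction`: `grid` (cell-centre coordinates),
#'   `labels_known`, `labels_seq`, `mislabel_fraction`, `grid_size`.
#' @export
grid_compare <- function(model_known, model_seq, coords_known,
                         grid_size = c(50, 50)) {
  stopifnot(length(grid_size) == 2L, all(grid_size >= 2))
  rng1 <- range(coords_known[, 1]); rng2 <- range(coords_known[, 2])
  grid <- as.matrix(expand.grid(
    PC1 = seq(rng1[1], rng1[2], length.out = grid_size[1]),
    PC2 = seq(rng2[1], rng2[2], length.out = grid_size[2])))
  lk <- stats::predict(model_known, grid)
  ls <- stats::predict(model_seq, grid)
  structure(list(grid = grid, labels_known = lk, labels_seq = ls,
                 mislabel_fraction = mean(as.character(lk) != as.character(ls)),
                 grid_size = as.integer(grid_size)),
            class = "grid_prediction")
}

#' @export
print.grid_prediction <- function(x, ...) {
  cat(sprintf("Structure decision maps on a %d x %d grid: %.2f%% of cells mislabelled\n",
              x$grid_size[1], x$grid_size[2], 100 * x$mislabel_fraction))
  invisible(x)
}

#' Plot a grid comparison of structure predictions
#'
#' Cells are coloured by the reference-model population; cells where the two
#' models disagree are overplotted in grey.
#'
#' @param x a `grid_prediction` from [grid_compare()].
#' @param ... passed to [plot()].
#' @export
plot.grid_prediction <- function(x, ...) {
  cols <- grDevices::hcl.colors(nlevels(x$labels_known), "Dark 3")
  plot(x$grid, col = cols[as.integer(x$labels_known)], pch = 15, cex = 0.6,
       xlab = "PC1", ylab = "PC2", ...)
  bad <- as.character(x$labels_known) != as.character(x$labels_seq)
  if (any(bad)) graphics::points(x$grid[bad, , drop = FALSE], col = "grey40",
                                 pch = 15, cex = 0.6)
  invisible(x)
}
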