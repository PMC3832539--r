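#' Genotype likelihoods from allele read counts
#'
#' For a cell with `a` ancestral and `d` derived reads, the log-likelihood of
#' genotype `g` (derived copies) is `a * log(1 - q_g) + d * log(q_g)` with
#' per-read derived probabilities `q = (eps, 1/2, 1 - eps)` and `eps` the
#' two-allele flip probability of the error channel. Reads are conditionally
#' independent given the genotype. Cells with no reads carry equal
#' log-likelihoods (zero information).
#'
#' @param reads a `read_counts` object from [simulate_reads()], or a list with
#'   integer matrices `anc` and `der`.
#' @param error_rate per-read error rate assumed by the model; defaults to the
#'   rate recorded in `reads`.
#' @param error_model error channel convention; defaults to the one recorded
#'   in `reads`.
#' @return a `genolik` object: list of three sites x individuals matrices of
#'   log-likelihoods (`ll0`, `ll1`, `ll2`).
#' @export
genotype_likelihoods <- function(reads, error_rate = NULL, error_model = NULL) {
  a <- reads$anc; d <- reads$der
  stopifnot(is.matrix(a), is.matrix(d), all(dim(a) == dim(d)))
  if (any(a < 0) || any(d < 0)) stop("read counts must be non-negative")
  if (is.null(error_rate)) error_rate <- reads$error_rate
  if (is.null(error_model)) error_model <- reads$error_model
  if (is.null(error_rate) || is.null(error_model))
    stop("error_rate/error_model not supplied and not recorded in the reads")
  eps <- flip_prob(error_rate, error_model)
  xlog <- function(n, p) {  # n * log(p) with the 0 * log(0) = 0 convention
    out <- n * log(p)
    out[n == 0] <- 0
    out
  }
  gl <- list(ll0 = xlog(a, 1 - eps) + xlog(d, eps),
             ll1 = (a + d) * log(0.5),
             ll2 = xlog(a, eps) + xlog(d, 1 - eps))
  gl$n_sites <- nrow(a); gl$n_ind <- ncol(a)
  gl$error_rate <- error_rate; gl$error_model <- error_model
  class(gl) <- "genolik"
  gl
}

#' @export
print.genolik <- function(x, ...) {
  cat(sprintf("Genotype log-likelihoods: %d sites x %d individuals (error %g, %s)\n",
              x$n_sites, x$n_ind, x$error_rate, x$error_model))
  invisible(x)
}

#' Point-mass genotype likelihoods from known genotypes
#'
#' Encodes certain genotypes as degenerate likelihoods (0 on the true
#' genotype, `-Inf` elsewhere). Useful for uncertainty-free reductions: every
#' probabilistic estimator in the package collapses to its known-genotype
#' counterpart on this input.
#'
#' @param g integer genotype matrix (sites x individuals).
#' @return a `genolik` object.
#' @export
genolik_from_genotypes <- function(g) {
  stopifnot(all(g %in% 0:2))
  mk <- function(k) {
    m <- matrix(-Inf, nrow(g), ncol(g))
    m[g == k] <- 0
    m
  }
  gl <- list(ll0 = mk(0L), ll1 = mk(1L), ll2 = mk(2L),
             n_sites = nrow(g), n_ind = ncol(g),
             error_rate = 0, error_model = "flip")
  class(gl) <- "genolik"
  gl
}

# linear-scale per-cell-normalised likelihoods (each cell rescaled by its max
# so the largest of the three values is 1); list of three matrices
gl_linear <- function(gl) {
  mx <- pmax(gl$ll0, gl$ll1, gl$ll2)
  list(g0 = exp(gl$ll0 - mx), g1 = exp(gl$ll1 - mx), g2 = exp(gl$ll2 - mx))
}

#' Sample allele frequency likelihood (dynamic programming)
#'
#' Computes, for every site, the likelihood of each possible number
#' `j = 0, ..., 2N` of derived chromosomes in the sample of `N` diploids, by
#' the standard individual-by-individual dynamic programming: genotype
#' configurations with total derived count `j` are weighted as a
#' hypergeometric draw of `j` derived chromosomes among `2N` (combinatorial
#' factor `C(2, g)` per individual, divided by `C(2N, j)`), and each
#' configuration contributes the product of its genotype likelihoods. Runs in
#' O(N^2) per site with per-step rescaling for numerical safety.
#'
#' @param gl a `genolik` object.
#' @return numeric matrix, sites x (2N+1); rows normalised to sum to 1
#'   (relative likelihood only).
#' @export
saf_likelihood <- function(gl) {
  stopifnot(inherits(gl, "genolik"))
  lin <- gl_linear(gl)
  saf_dp_cpp(lin$g0, lin$g1, lin$g2)
}

#' Maximum-likelihood allele frequency per site (EM)
#'
#' Maximises the Hardy-Weinberg mixture likelihood
#' `sum_i log sum_g L_i(g) HWE(g | f)` over `f` in `[0, 1]` by EM, iterating
#' the posterior-mean update `f <- mean(E[g | f]) / 2` until `|delta f| < tol`
#' or `max_iter` iterations. EM is run from the raw derived-read fraction and
#' from two spread-out starting points (the mixture likelihood can carry a
#' second mode on pathological input); the highest-likelihood solution is
#' kept per site. Sites without any reads are returned as `f = 0` and
#' flagged.
#'
#' @param gl a `genolik` object.
#' @param reads optional `read_counts` used for the data-driven start;
#'   without it the first start is 0.2 at every site.
#' @param tol convergence tolerance on the frequency.
#' @param max_iter maximum EM iterations per start.
#' @return numeric vector of ML frequencies, with a logical attribute
#'   `no_data` flagging read-free sites.
#' @export
estimate_allele_freq_ml <- function(gl, reads = NULL, tol = 1e-8,
                                    max_iter = 1000L) {
  stopifnot(inherits(gl, "genolik"))
  lin <- gl_linear(gl)
  no_data <- rowSums(lin$g0 != lin$g1 | lin$g1 != lin$g2) == 0
  if (!is.null(reads)) {
    der <- rowSums(reads$der)
    tot <- der + rowSums(reads$anc)
    f0 <- ifelse(tot > 0, der / tot, 0.2)
    f0 <- pmin(pmax(f0, 1e-4), 1 - 1e-4)
  } else {
    f0 <- rep(0.2, gl$n_sites)
  }
  M <- gl$n_sites
  hwe_ll <- function(f) {
    rowSums(log(lin$g0 * (1 - f)^2 + lin$g1 * 2 * f * (1 - f) +
                  lin$g2 * f^2))
  }
  f <- em_freq_cpp(lin$g0, lin$g1, lin$g2, f0, tol, as.integer(max_iter))
  ll <- hwe_ll(f)
  for (start in c(0.05, 0.8)) {
    f_alt <- em_freq_cpp(lin$g0, lin$g1, lin$g2, rep(start, M), tol,
                         as.integer(max_iter))
    ll_alt <- hwe_ll(f_alt)
    better <- ll_alt > ll + 1e-12
    f[better] <- f_alt[better]
    ll[better] <- ll_alt[better]
  }
  f[no_data] <- 0
  attr(f, "no_data") <- no_data
  f
}

.sfs_weight_cache <- new.env(parent = emptyenv())

# P(j derived of 2N | site variable, f ~ truncated Exp(rate) on (0,1)):
# binomial mixed over the spectrum, by trapezoidal quadrature on a
# log-then-linear frequency grid (dense near 0 where steep spectra live).
sfs_mixture_weights <- function(n2, rate) {
  f <- unique(c(exp(seq(log(1e-6), log(0.1), length.out = 300)),
                seq(0.1, 1 - 1e-9, length.out = 200)))
  dens <- rate * exp(-rate * f) / (1 - exp(-rate))
  dw <- diff(f)
  quad <- dens * (c(dw / 2, 0) + c(0, dw / 2))
  w <- as.numeric(outer(0:n2, f, function(j, ff) stats::dbinom(j, n2, ff)) %*% quad)
  w / sum(w)
}

#' Fit the spectrum-mixture prior for the sample allele frequency
#'
#' Maximum-likelihood fit of the two-parameter prior
#' `p_j = (1 - a) I(j = 0) + a w_j(r)`, where `a` is the proportion of
#' variable sites and `w_j(r)` is the binomial mixture of a truncated
#' exponential frequency spectrum with rate `r` — the sampling distribution
#' of the derived-chromosome count implied by the package's own population
#' model. The rate is profiled over a log-spaced grid and `a` maximised by
#' golden-section search at each rate. Constraining the prior to this family
#' makes the empirical-Bayes fit well identified even at 1X depth, where an
#' unconstrained spectrum EM is too weakly informed per frequency class.
#'
#' @param lik SAF likelihood matrix (sites x 2N+1) from [saf_likelihood()].
#' @param rates candidate spectrum rates (profile grid).
#' @return list with the prior vector `p`, the fitted proportion of variable
#'   sites `a`, the fitted `rate` and the maximised `loglik`.
#' @export
fit_sfs_mixture <- function(lik,
                            rates = exp(seq(log(4), log(160),
                                            length.out = 16))) {
  n2 <- ncol(lik) - 1L
  W <- vapply(rates, function(r) {
    key <- sprintf("%d_%.6g", n2, r)
    if (is.null(.sfs_weight_cache[[key]]))
      .sfs_weight_cache[[key]] <- sfs_mixture_weights(n2, r)
    .sfs_weight_cache[[key]]
  }, numeric(n2 + 1L))
  Tm <- lik %*% W  # per site: P(data | variable, rate)
  L0 <- lik[, 1L]
  best <- list(loglik = -Inf)
  for (ri in seq_along(rates)) {
    op <- stats::optimize(function(a) sum(log((1 - a) * L0 + a * Tm[, ri])),
                          c(1e-6, 1 - 1e-6), maximum = TRUE, tol = 1e-6)
    if (op$objective > best$loglik)
      best <- list(loglik = op$objective, a = op$maximum, rate = rates[ri],
                   ri = ri)
  }
  p <- (1 - best$a) * c(1, numeric(n2)) + best$a * W[, best$ri]
  list(p = p, a = best$a, rate = best$rate, loglik = best$loglik)
}

#' Maximum-likelihood site frequency spectrum (EM across sites)
#'
#' Estimates the global spectrum `p` over derived-chromosome counts
#' `j = 0..2N` maximising `sum_s log sum_j p_j L_s(j)`, where `L_s` are the
#' per-site SAF likelihoods, by EM across sites. This is the empirical-Bayes
#' spectrum used as the default SAF prior: with most sites monomorphic it
#' concentrates mass at `j = 0`, letting the posterior discriminate genuine
#' variants from scattered sequencing-error reads — which per-site
#' likelihoods alone cannot do at low depth.
#'
#' @param lik SAF likelihood matrix (sites x 2N+1) from [saf_likelihood()].
#' @param tol EM convergence tolerance (max absolute change in any `p_j`).
#' @param max_iter maximum EM iterations.
#' @return numeric vector of length 2N+1 summing to 1.
#' @export
estimate_sfs <- function(lik, tol = 1e-6, max_iter = 100L) {
  K <- ncol(lik)
  sfs_em_cpp(lik, rep(1 / K, K), tol, as.integer(max_iter))
}

#' Sample allele frequency posterior and probability of being variable
#'
#' Combines the SAF likelihood with a prior over the derived-chromosome
#' count and normalises. The default prior `"sfs_mixture"` is the
#' two-parameter spectrum-mixture fit of [fit_sfs_mixture()] (empirical
#' Bayes within the package's own population-model family); alternatives are
#' the unconstrained spectrum EM ([estimate_sfs()]), Hardy-Weinberg
#' (binomial(2N, f)) at the per-site ML frequency, a flat prior, and the
#' neutral `1/j` prior, for sensitivity analysis. A fully specified prior
#' vector can also be supplied via `prior_weights`. The per-site probability
#' of being variable is `1 - post[0] - post[2N]`, the posterior mass off the
#' two monomorphic counts — the SNP-calling statistic.
#'
#' @param gl a `genolik` object (or a precomputed SAF likelihood matrix, in
#'   which case `n_ind` must be given).
#' @param prior `"sfs_mixture"`, `"sfs_em"`, `"hwe_from_f_ml"`, `"uniform"`
#'   or `"neutral_1_over_j"`.
#' @param prior_weights optional prior vector of length 2N+1 overriding
#'   `prior` (e.g. a mixture fit shared across windows).
#' @param f_ml per-site ML frequencies; computed via
#'   [estimate_allele_freq_ml()] when missing and needed.
#' @param reads optional `read_counts` passed through to the EM initialiser.
#' @param n_ind number of diploids when `gl` is a bare likelihood matrix.
#' @return a `saf_fit` object: list with the posterior matrix `post`
#'   (sites x 2N+1), `p_variable`, `f_ml`, the `prior_weights` actually used
#'   (for the global priors) and `n_ind`.
#' @export
saf_posterior <- function(gl,
                          prior = c("sfs_mixture", "sfs_em", "hwe_from_f_ml",
                                    "uniform", "neutral_1_over_j"),
                          f_ml = NULL, reads = NULL, n_ind = NULL,
                          prior_weights = NULL) {
  prior <- if (is.null(prior_weights)) match.arg(prior) else "supplied"
  if (inherits(gl, "genolik")) {
    lik <- saf_likelihood(gl)
    n_ind <- gl$n_ind
    if (is.null(f_ml) && prior == "hwe_from_f_ml")
      f_ml <- estimate_allele_freq_ml(gl, reads = reads)
  } else {
    lik <- gl
    if (is.null(n_ind)) stop("n_ind required with a bare likelihood matrix")
    if (ncol(lik) != 2 * n_ind + 1) stop("likelihood matrix width != 2N+1")
    if (is.null(f_ml) && prior == "hwe_from_f_ml")
      stop("f_ml required for the HWE prior with a bare likelihood matrix")
  }
  if (any(rowSums(lik) == 0)) stop("all-zero likelihood row: degenerate input")
  K <- 2L * n_ind + 1L
  j <- 0:(K - 1L)
  if (prior == "hwe_from_f_ml") {
    fl <- pmin(pmax(f_ml, 1e-12), 1 - 1e-12)
    lpost <- log(lik) + outer(log(fl), j) + outer(log1p(-fl), rev(j)) +
      rep(lchoose(K - 1L, j), each = nrow(lik))
    lpost <- lpost - apply(lpost, 1L, max)
    post <- exp(lpost)
  } else {
    if (is.null(prior_weights))
      prior_weights <- switch(prior,
        sfs_mixture = fit_sfs_mixture(lik)$p,
        sfs_em = estimate_sfs(lik),
        uniform = rep(1 / K, K),
        neutral_1_over_j = {
          w <- c(1, 1 / j[-1]); w / sum(w)
        })
    if (length(prior_weights) != K || any(prior_weights < 0))
      stop("prior_weights must be a non-negative vector of length 2N+1")
    post <- lik * rep(prior_weights, each = nrow(lik))
  }
  post <- post / rowSums(post)
  out <- list(post = post,
              p_variable = pmax(0, 1 - post[, 1L] - post[, K]),
              f_ml = if (is.null(f_ml)) rep(NA_real_, nrow(post)) else as.numeric(f_ml),
              prior_weights = prior_weights,
              n_ind = n_ind, prior = prior)
  class(out) <- "saf_fit"
  out
}

#' @export
print.saf_fit <- function(x, ...) {
  cat(sprintf("SAF posterior: %d sites, %d diploids, prior = %s\n",
              nrow(x$post), x$n_ind, x$prior))
  cat(sprintf("  mean P(variable) = %.4f\n", mean(x$p_variable)))
  invisible(x)
}

#' @export
summary.saf_fit <- function(object, ...) {
  mode_j <- max.col(object$post, ties.method = "first") - 1L
  out <- list(n_sites = nrow(object$post), n_ind = object$n_ind,
              prior = object$prior,
              p_variable = summary(object$p_variable),
              posterior_mode = table(factor(mode_j > 0 & mode_j < 2 * object$n_ind,
                                            c(FALSE, TRUE),
                                            c("monomorphic", "variable"))))
  class(out) <- "summary.saf_fit"
  out
}

#' @export
print.summary.saf_fit <- function(x, ...) {
  cat(sprintf("SAF posterior over %d sites (%d diploids, prior %s)\n",
              x$n_sites, x$n_ind, x$prior))
  cat("P(variable):\n"); print(x$p_variable)
  cat("Posterior-mode classification:\n"); print(x$posterior_mode)
  invisible(x)
}

#' Genotype posteriors under a Hardy-Weinberg prior
#'
#' Per-cell posterior `P(g | data) \propto L(g) HWE(g | f)` at the per-site
#' allele frequency `f` (typically the ML estimate). The prior is floored at
#' `1e-12` so a boundary frequency cannot zero out a genotype that carries
#' all the likelihood.
#'
#' @param gl a `genolik` object.
#' @param f per-site allele frequencies.
#' @return a `geno_posterior` object: list of three sites x individuals
#'   matrices `p0`, `p1`, `p2` plus posterior moments `eg` (`E[g]`) and
#'   `eg2` (`E[g^2]`).
#' @export
genotype_posterior <- function(gl, f) {
  stopifnot(inherits(gl, "genolik"), length(f) == gl$n_sites)
  lin <- gl_linear(gl)
  pr0 <- pmax((1 - f)^2, 1e-12)
  pr1 <- pmax(2 * f * (1 - f), 1e-12)
  pr2 <- pmax(f^2, 1e-12)
  p0 <- lin$g0 * pr0
  p1 <- lin$g1 * pr1
  p2 <- lin$g2 * pr2
  tot <- p0 + p1 + p2
  p0 <- p0 / tot; p1 <- p1 / tot; p2 <- p2 / tot
  out <- list(p0 = p0, p1 = p1, p2 = p2,
              eg = p1 + 2 * p2, eg2 = p1 + 4 * p2, f = as.numeric(f))
  class(out) <- "geno_posterior"
  out
}
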