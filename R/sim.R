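#' Simulation configuration for independent diallelic sites
#'
#' Bundles the parameters of the site simulator: number of sites, probability
#' that a site is variable in the (ancestral) population, shape of the site
#' frequency spectrum, diploid sample size, inbreeding coefficient, mean
#' per-individual sequencing depth and per-read error rate.
#'
#' The ancestral derived-allele frequency of a variable site is drawn from an
#' exponential density truncated to (0, 1), a convenient stand-in for the
#' strongly rare-skewed spectrum expected under neutrality in a large
#' population. `exp_rate` controls the skew; the default of 44 puts the mean
#' derived-allele frequency of variable sites near 0.023 (see the package
#' vignette for how this default was fixed). Under `sfs_model =
#' "expansion_skewed"` the density is squared and renormalised, which for the
#' exponential family simply doubles the rate — the classic excess of rare
#' variants left by a population expansion.
#'
#' @param n_sites number of independent diallelic sites.
#' @param prob_variable probability in `[0, 1]` that a site is variable in the
#'   population.
#' @param sfs_model `"neutral_exponential"` or `"expansion_skewed"`.
#' @param exp_rate positive rate of the truncated exponential ancestral
#'   frequency density.
#' @param n_individuals number of diploid individuals to simulate.
#' @param inbreeding_F individual inbreeding coefficient in `[0, 1]`
#'   (0 = Hardy-Weinberg).
#' @param mean_depth mean of the Poisson per-individual per-site read depth.
#' @param error_rate per-read sequencing error rate.
#' @param error_model `"flip"` (an erroneous read reports the other allele of
#'   the diallelic pair, flip probability = `error_rate`) or `"four_base"`
#'   (errors land uniformly on the three other bases; off-allele reads are
#'   discarded, so the effective flip probability among retained reads is
#'   `(error_rate/3) / (1 - 2*error_rate/3)`).
#' @param seed optional integer seed recorded in the configuration.
#' @return an object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_sites,
                       prob_variable = 0.1,
                       sfs_model = c("neutral_exponential", "expansion_skewed"),
                       exp_rate = 44,
                       n_individuals = 1000L,
                       inbreeding_F = 0,
                       mean_depth = 1,
                       error_rate = 0.01,
                       error_model = c("flip", "four_base"),
                       seed = NULL) {
  sfs_model <- match.arg(sfs_model)
  error_model <- match.arg(error_model)
  stopifnot(length(n_sites) == 1L, n_sites >= 1)
  if (prob_variable < 0 || prob_variable > 1)
    stop("prob_variable must lie in [0, 1]")
  if (exp_rate <= 0) stop("exp_rate must be positive")
  if (inbreeding_F < 0 || inbreeding_F > 1)
    stop("inbreeding_F must lie in [0, 1]")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must lie in [0, 0.5)")
  cfg <- list(n_sites = as.integer(n_sites), prob_variable = prob_variable,
              sfs_model = sfs_model, exp_rate = exp_rate,
              n_individuals = as.integer(n_individuals),
              inbreeding_F = inbreeding_F, mean_depth = mean_depth,
              error_rate = error_rate, error_model = error_model, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [sim_config()].
#'
#' @param file path to a YAML file.
#' @return a `sim_config` object.
#' @export
sim_config_from_yaml <- function(file) {
  do.call(sim_config, yaml::read_yaml(file))
}

#' Three-population subdivision configuration
#'
#' Parameters of the hierarchical island model used for the structure
#' analyses: three populations, with population 1 splitting from the common
#' ancestor at `fst_deep` and populations 2 and 3 splitting from their own
#' intermediate ancestor at `fst_shallow`.
#'
#' @param fst_deep,fst_shallow differentiation levels in (0, 1) for the deep
#'   and shallow splits of the three-population hierarchy.
#' @param n_per_pop number of sequenced individuals per population.
#' @param depth_per_sample mean sequencing depth per sampled individual.
#' @return an object of class `structure_config`.
#' @export
structure_config <- function(fst_deep, fst_shallow, n_per_pop,
                             depth_per_sample) {
  if (fst_deep <= 0 || fst_deep >= 1 || fst_shallow <= 0 || fst_shallow >= 1)
    stop("F_ST values must lie in (0, 1)")
  structure(list(fst_deep = fst_deep, fst_shallow = fst_shallow,
                 n_per_pop = as.integer(n_per_pop),
                 depth_per_sample = depth_per_sample, n_pops = 3L),
            class = "structure_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Site simulator configuration\n")
  cat(sprintf("  sites: %d  P(variable): %g  SFS: %s (rate %g)\n",
              x$n_sites, x$prob_variable, x$sfs_model, x$exp_rate))
  cat(sprintf("  individuals: %d  F: %g  depth: %gX  error: %g (%s)\n",
              x$n_individuals, x$inbreeding_F, x$mean_depth, x$error_rate,
              x$error_model))
  invisible(x)
}

# exponential density truncated to (0,1); squaring the density doubles the
# rate (exp(-r f)^2 = exp(-2 r f)), so the expansion-skewed model is the same
# family at rate 2r.
rtruncexp <- function(n, rate) {
  u <- stats::runif(n)
  -log(1 - u * (1 - exp(-rate))) / rate
}

#' Draw ancestral population allele frequencies
#'
#' Each site is independently variable with probability `prob_variable`;
#' variable sites receive a derived-allele frequency from the truncated
#' exponential density (rate doubled under the expansion-skewed model),
#' invariable sites have frequency exactly 0.
#'
#' @param cfg a [sim_config()] object.
#' @return a `freq_table`: data frame with columns `freq` and `is_variable`.
#' @export
draw_ancestral_freqs <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  rate <- if (cfg$sfs_model == "expansion_skewed") 2 * cfg$exp_rate else cfg$exp_rate
  variable <- stats::runif(cfg$n_sites) < cfg$prob_variable
  freq <- numeric(cfg$n_sites)
  nv <- sum(variable)
  if (nv > 0) {
    f <- rtruncexp(nv, rate)
    # keep variable-site frequencies strictly inside (0,1)
    f[f <= 0] <- .Machine$double.eps
    freq[variable] <- f
  }
  out <- data.frame(freq = freq, is_variable = variable)
  class(out) <- c("freq_table", "data.frame")
  out
}

#' Draw subpopulation allele frequencies (Balding-Nichols model)
#'
#' Subpopulation frequencies are Beta-distributed with mean equal to the
#' ancestral frequency `p` and variance `F_ST * p * (1 - p)`, i.e. shape
#' parameters `p (1 - F_ST) / F_ST` and `(1 - p)(1 - F_ST) / F_ST`. Two draws
#' at `fst_deep` give population 1's frequency and the ancestral frequency of
#' the (2, 3) pair; the latter seeds two further draws at `fst_shallow`.
#' Invariable sites stay fixed at 0 in every population.
#'
#' @param freq a `freq_table` from [draw_ancestral_freqs()].
#' @param scfg a [structure_config()].
#' @return the `freq_table` with an added matrix column `freq_subpop`
#'   (sites x 3).
#' @export
draw_subpop_freqs <- function(freq, scfg) {
  stopifnot(inherits(freq, "freq_table"), inherits(scfg, "structure_config"))
  n <- nrow(freq)
  sub <- matrix(0, n, 3L)
  v <- freq$is_variable
  if (any(v)) {
    p <- freq$freq[v]
    pop1 <- rbalding_nichols(p, scfg$fst_deep)
    anc23 <- rbalding_nichols(p, scfg$fst_deep)
    sub[v, 1L] <- pop1
    sub[v, 2L] <- rbalding_nichols(anc23, scfg$fst_shallow)
    sub[v, 3L] <- rbalding_nichols(anc23, scfg$fst_shallow)
  }
  freq$freq_subpop <- sub
  freq
}

# Balding-Nichols draw; frequencies at the boundary (possible when the Beta
# shapes are < 1) are left as-is: a site fixed within a subpopulation is a
# legitimate outcome of drift.
rbalding_nichols <- function(p, fst) {
  if (fst <= 0 || fst >= 1) stop("F_ST must lie in (0, 1)")
  ratio <- (1 - fst) / fst
  stats::rbeta(length(p), p * ratio, (1 - p) * ratio)
}

#' Draw diploid genotypes given allele frequencies
#'
#' Genotypes count derived-allele copies (0, 1 or 2). With inbreeding
#' coefficient `F` the genotype probabilities at frequency `p` are
#' `((1-p)^2 + F p (1-p), 2 p (1-p) (1-F), p^2 + F p (1-p))`; `F = 0` is
#' Hardy-Weinberg.
#'
#' @param freq per-site allele frequencies (numeric vector) or a `freq_table`.
#' @param n_individuals number of diploid individuals.
#' @param inbreeding_F inbreeding coefficient in `[0, 1]`.
#' @return integer matrix, sites x individuals, values in `{0, 1, 2}`.
#' @export
draw_genotypes <- function(freq, n_individuals, inbreeding_F = 0) {
  if (inherits(freq, "freq_table")) freq <- freq$freq
  if (any(freq < 0 | freq > 1)) stop("frequencies must lie in [0, 1]")
  if (inbreeding_F < 0 || inbreeding_F > 1)
    stop("inbreeding_F must lie in [0, 1]")
  M <- length(freq)
  n_individuals <- as.integer(n_individuals)
  pq <- freq * (1 - freq)
  p1 <- 2 * pq * (1 - inbreeding_F)
  p2 <- freq^2 + inbreeding_F * pq
  u <- matrix(stats::runif(M * n_individuals), M, n_individuals)
  g <- matrix(0L, M, n_individuals)
  g[u < p1 + p2] <- 1L
  g[u < p2] <- 2L
  g
}

# flip probability of the two-allele error channel implied by the error model
flip_prob <- function(error_rate, error_model) {
  switch(error_model,
         flip = error_rate,
         four_base = (error_rate / 3) / (1 - 2 * error_rate / 3),
         stop("unknown error model"))
}

#' Simulate sequencing reads for a genotype matrix
#'
#' Per-cell read depth is Poisson(`mean_depth`); each read samples one of the
#' individual's two alleles and is miscalled according to the error model
#' (see [sim_config()]). Under `"four_base"`, reads miscalled to an
#' off-allele base are discarded, thinning the realised depth by
#' `2 * error_rate / 3`.
#'
#' @param g integer genotype matrix (sites x individuals).
#' @param mean_depth Poisson mean depth per individual per site.
#' @param error_rate per-read error rate.
#' @param error_model `"flip"` or `"four_base"`.
#' @return a `read_counts` object: list with integer matrices `anc` and `der`
#'   of ancestral- and derived-allele read counts.
#' @export
simulate_reads <- function(g, mean_depth, error_rate = 0.01,
                           error_model = c("flip", "four_base")) {
  error_model <- match.arg(error_model)
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must lie in [0, 0.5)")
  M <- nrow(g); N <- ncol(g)
  depth <- matrix(stats::rpois(M * N, mean_depth), M, N)
  if (error_model == "four_base" && error_rate > 0) {
    keep <- stats::rbinom(M * N, as.vector(depth), 1 - 2 * error_rate / 3)
    depth <- matrix(keep, M, N)
  }
  eps <- flip_prob(error_rate, error_model)
  # P(read = derived | genotype): hets emit either allele with prob 1/2, which
  # the symmetric flip channel leaves at 1/2
  pder <- c(eps, 0.5, 1 - eps)[as.vector(g) + 1L]
  der <- matrix(stats::rbinom(M * N, as.vector(depth), pder), M, N)
  out <- list(anc = depth - der, der = der,
              error_rate = error_rate, error_model = error_model)
  class(out) <- "read_counts"
  out
}

#' @export
print.read_counts <- function(x, ...) {
  cat(sprintf("Read counts: %d sites x %d individuals, mean depth %.3f (%s error %g)\n",
              nrow(x$anc), ncol(x$anc), mean(x$anc + x$der),
              x$error_model, x$error_rate))
  invisible(x)
}

#' Total per-site sequencing depth
#' @param reads a `read_counts` object.
#' @return integer vector of per-site read totals across individuals.
#' @export
total_depth <- function(reads) {
  stopifnot(inherits(reads, "read_counts"))
  as.integer(rowSums(reads$anc) + rowSums(reads$der))
}
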