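test_that("genotype likelihoods match hand-computed per-read products", {
  rd <- list(anc = matrix(c(0L, 0L, 3L), 1), der = matrix(c(0L, 4L, 3L), 1))
  gl <- genotype_likelihoods(rd, error_rate = 0.01, error_model = "flip")
  # no reads: the three log-likelihoods are equal
  expect_equal(gl$ll0[1, 1], gl$ll1[1, 1])
  expect_equal(gl$ll1[1, 1], gl$ll2[1, 1])
  # (0 ancestral, 4 derived): exact values and ordering
  expect_equal(gl$ll2[1, 2], 4 * log(0.99))
  expect_equal(gl$ll1[1, 2], 4 * log(0.5))
  expect_equal(gl$ll0[1, 2], 4 * log(0.01))
  expect_true(gl$ll2[1, 2] > gl$ll1[1, 2] && gl$ll1[1, 2] > gl$ll0[1, 2])
  # balanced counts (k, k): heterozygote maximal under symmetric flip < 0.5
  expect_true(gl$ll1[1, 3] > gl$ll0[1, 3] && gl$ll1[1, 3] > gl$ll2[1, 3])
})

test_that("SAF dynamic programming equals exhaustive enumeration for N <= 4", {
  set.seed(10)
  for (N in 1:4) {
    gl <- rand_genolik(60, N)
    expect_lt(max(abs(saf_likelihood(gl) - saf_enumerate(gl))), 1e-9)
  }
})

test_that("SAF likelihood concentrates correctly in degenerate cases", {
  # all individuals certainly homozygous ancestral -> mass at j = 0
  gl <- genolik_from_genotypes(matrix(0L, 3, 5))
  lik <- saf_likelihood(gl)
  expect_equal(lik[, 1], rep(1, 3))
  # one certain het among certain hom-ancestral -> mass at j = 1
  g <- matrix(0L, 1, 5); g[1, 3] <- 1L
  lik1 <- saf_likelihood(genolik_from_genotypes(g))
  expect_equal(as.vector(lik1[1, ]), c(0, 1, rep(0, 9)))
})

test_that("SAF DP stays finite and normalised for N = 1000 at 1X", {
  set.seed(11)
  fr <- draw_ancestral_freqs(sim_config(40, n_individuals = 1000))
  g <- draw_genotypes(fr, 1000)
  rd <- simulate_reads(g, 1, 0.01)
  lik <- saf_likelihood(genotype_likelihoods(rd))
  expect_true(all(is.finite(lik)))
  expect_equal(rowSums(lik), rep(1, 40), tolerance = 1e-12)
})

test_that("EM allele frequencies match a grid-search oracle", {
  set.seed(12)
  gl <- rand_genolik(40, 3)
  f_em <- estimate_allele_freq_ml(gl)
  grid <- seq(0, 1, by = 0.001)
  for (s in 1:40) {
    lls <- vapply(grid, function(f) hwe_loglik(gl, s, f), numeric(1))
    f_grid <- grid[which.max(lls)]
    # the frequencies agree, or the surface is flat enough that the attained
    # log-likelihoods are equivalent (EM cannot distinguish flat optima)
    expect_true(abs(f_em[s] - f_grid) < 2e-3 ||
                  max(lls) - hwe_loglik(gl, s, f_em[s]) < 1e-4)
  }
})

test_that("EM allele frequency closed forms on certain genotypes", {
  g <- matrix(c(0L, 1L, 2L, 2L, 1L, 0L, 0L, 0L), 2, 4, byrow = TRUE)
  gl <- genolik_from_genotypes(g)
  f <- estimate_allele_freq_ml(gl)
  expect_equal(as.numeric(f), rowSums(g) / 8, tolerance = 1e-5)
  # all certainly hom-ancestral -> 0
  f0 <- estimate_allele_freq_ml(genolik_from_genotypes(matrix(0L, 2, 4)))
  expect_equal(as.numeric(f0), c(0, 0), tolerance = 1e-9)
  # site with no reads anywhere is flagged and reported as 0
  rd <- list(anc = matrix(0L, 1, 3), der = matrix(0L, 1, 3))
  fe <- estimate_allele_freq_ml(genotype_likelihoods(rd, 0.01, "flip"))
  expect_equal(as.numeric(fe), 0)
  expect_true(attr(fe, "no_data")[1])
})

test_that("SAF posteriors normalise and respond to the prior as expected", {
  set.seed(13)
  N <- 2
  gl <- rand_genolik(200, N)
  for (pr in c("uniform", "neutral_1_over_j", "hwe_from_f_ml")) {
    saf <- saf_posterior(gl, prior = pr)
    expect_equal(rowSums(saf$post), rep(1, 200), tolerance = 1e-10)
    expect_true(all(saf$p_variable >= 0 & saf$p_variable <= 1))
    expect_equal(saf$p_variable,
                 pmax(0, 1 - saf$post[, 1] - saf$post[, 2 * N + 1]))
  }
  # uniform prior: posterior proportional to the likelihood (enumeration oracle)
  saf_u <- saf_posterior(gl, prior = "uniform")
  expect_lt(max(abs(saf_u$post - saf_enumerate(gl))), 1e-9)
  # likelihood concentrated at j = 3 stays at j = 3 under a flat prior
  g <- matrix(0L, 1, 2); g[1, 1] <- 1L; g[1, 2] <- 2L
  saf3 <- saf_posterior(genolik_from_genotypes(g), prior = "uniform")
  expect_equal(as.vector(saf3$post[1, ]), c(0, 0, 0, 1, 0))
})

test_that("HWE-prior SAF posterior equals brute-force Bayes at N = 2", {
  set.seed(14)
  N <- 2
  gl <- rand_genolik(50, N)
  f <- estimate_allele_freq_ml(gl)
  saf <- saf_posterior(gl, prior = "hwe_from_f_ml", f_ml = f)
  lik <- saf_enumerate(gl)
  pri <- t(vapply(f, function(ff) dbinom(0:(2 * N), 2 * N, ff), numeric(2 * N + 1)))
  brute <- lik * pmax(pri, 0)
  brute <- brute / rowSums(brute)
  expect_lt(max(abs(saf$post - brute)), 1e-9)
})

test_that("spectrum-mixture prior recovers the simulated spectrum parameters", {
  set.seed(15)
  cfg <- sim_config(4000, prob_variable = 0.1, exp_rate = 44,
                    n_individuals = 50, mean_depth = 5)
  fr <- draw_ancestral_freqs(cfg)
  g <- draw_genotypes(fr, 50)
  rd <- simulate_reads(g, 5, 0.01)
  lik <- saf_likelihood(genotype_likelihoods(rd))
  fit <- fit_sfs_mixture(lik)
  expect_lt(abs(fit$a - 0.1), 0.03)
  expect_gt(fit$rate, 20); expect_lt(fit$rate, 90)
  expect_equal(sum(fit$p), 1, tolerance = 1e-9)
})

test_that("probability of being variable vanishes on invariable-only input", {
  set.seed(16)
  g <- matrix(0L, 300, 30)
  rd <- simulate_reads(g, 5, 0.01)
  saf <- saf_posterior(genotype_likelihoods(rd))
  expect_lt(mean(saf$p_variable), 0.02)
})

test_that("genotype posteriors: prior return, certainty, and algebraic identity", {
  M <- 1; N <- 1
  # flat likelihood, f = 0.5 -> posterior is the prior (0.25, 0.5, 0.25)
  gl_flat <- structure(list(ll0 = matrix(0, M, N), ll1 = matrix(0, M, N),
                            ll2 = matrix(0, M, N), n_sites = M, n_ind = N,
                            error_rate = 0, error_model = "flip"),
                       class = "genolik")
  gp <- genotype_posterior(gl_flat, 0.5)
  expect_equal(c(gp$p0[1, 1], gp$p1[1, 1], gp$p2[1, 1]), c(0.25, 0.5, 0.25))
  # certain genotype overrides any interior frequency
  gp2 <- genotype_posterior(genolik_from_genotypes(matrix(2L, 1, 1)), 0.3)
  expect_equal(c(gp2$p0[1, 1], gp2$p1[1, 1], gp2$p2[1, 1]), c(0, 0, 1))
  # counts (0,4) at eps 0.01, f = 0.1: direct formula vs normalised product
  rd <- list(anc = matrix(0L, 1, 1), der = matrix(4L, 1, 1))
  gl <- genotype_likelihoods(rd, 0.01, "flip")
  gp3 <- genotype_posterior(gl, 0.1)
  direct <- c(0.01^4 * 0.81, 0.5^4 * 0.18, 0.99^4 * 0.01)
  direct <- direct / sum(direct)
  expect_equal(c(gp3$p0[1, 1], gp3$p1[1, 1], gp3$p2[1, 1]), direct,
               tolerance = 1e-12)
  # posterior moments are consistent
  expect_equal(gp3$eg[1, 1], gp3$p1[1, 1] + 2 * gp3$p2[1, 1])
  expect_equal(gp3$eg2[1, 1], gp3$p1[1, 1] + 4 * gp3$p2[1, 1])
})

test_that("posterior-mode allele counts are consistent at high depth", {
  set.seed(17)
  cfg <- sim_config(600, prob_variable = 1, exp_rate = 5,
                    n_individuals = 20, mean_depth = 50)
  fr <- draw_ancestral_freqs(cfg)
  g <- draw_genotypes(fr, 20)
  rd <- simulate_reads(g, 50, 0.01)
  saf <- saf_posterior(genotype_likelihoods(rd))
  mode_j <- max.col(saf$post, ties.method = "first") - 1L
  expect_gt(mean(mode_j == rowSums(g)), 0.99)
})
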