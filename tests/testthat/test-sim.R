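test_that("configuration objects validate their parameters", {
  expect_error(sim_config(100, prob_variable = 1.5), "prob_variable")
  expect_error(sim_config(100, exp_rate = -1), "exp_rate")
  expect_error(sim_config(100, inbreeding_F = 2), "inbreeding_F")
  expect_error(sim_config(100, mean_depth = 0), "mean_depth")
  expect_error(structure_config(0, 0.1, 10, 1), "F_ST")
  expect_error(structure_config(1.2, 0.1, 10, 1), "F_ST")
  expect_s3_class(sim_config(100), "sim_config")
})

test_that("ancestral frequencies: variability fraction, support and degenerate cases", {
  set.seed(1)
  cfg <- sim_config(1e5, prob_variable = 0.1, exp_rate = 10)
  fr <- draw_ancestral_freqs(cfg)
  # fraction of variable sites ~ Binomial(n, 0.1), 3 sigma
  expect_lt(abs(mean(fr$is_variable) - 0.1), 3 * sqrt(0.1 * 0.9 / 1e5))
  expect_true(all(fr$freq[fr$is_variable] > 0 & fr$freq[fr$is_variable] < 1))
  expect_true(all(fr$freq[!fr$is_variable] == 0))
  fr0 <- draw_ancestral_freqs(sim_config(1000, prob_variable = 0))
  expect_true(all(fr0$freq == 0))
})

test_that("expansion skew squares the frequency density (rate doubles)", {
  set.seed(2)
  r <- 6
  cfg <- sim_config(2e5, prob_variable = 1, sfs_model = "expansion_skewed",
                    exp_rate = r)
  f <- draw_ancestral_freqs(cfg)$freq
  # closed-form mean of Exp(2r) truncated to (0,1), computed independently
  r2 <- 2 * r
  m_expected <- 1 / r2 - exp(-r2) / (1 - exp(-r2))
  expect_lt(abs(mean(f) - m_expected), 4 * sd(f) / sqrt(length(f)))
})

test_that("Balding-Nichols subpopulation draws have the stated moments", {
  set.seed(3)
  p <- 0.3; fst <- 0.1
  fr <- structure(data.frame(freq = rep(p, 1e5),
                             is_variable = rep(TRUE, 1e5)),
                  class = c("freq_table", "data.frame"))
  scfg <- structure_config(fst, 1e-6, 10, 1)
  sub <- draw_subpop_freqs(fr, scfg)$freq_subpop
  v_expected <- fst * p * (1 - p)  # 0.021
  expect_lt(abs(mean(sub[, 1]) - p), 3 * sqrt(v_expected / 1e5))
  expect_lt(abs(var(sub[, 1]) - v_expected), 0.05 * v_expected)
  # F_ST -> 0: pops 2 and 3 concentrate at their shared intermediate ancestor
  expect_lt(max(abs(sub[, 2] - sub[, 3])), 0.01)
  # invariable sites stay fixed in every population
  fr$is_variable[1] <- FALSE; fr$freq[1] <- 0
  sub0 <- draw_subpop_freqs(fr, scfg)$freq_subpop
  expect_equal(sub0[1, ], c(0, 0, 0))
})

test_that("genotype draws follow the inbreeding-parameterised trinomial", {
  set.seed(4)
  n <- 1e5
  g0 <- draw_genotypes(rep(0.5, 1), n, inbreeding_F = 0)
  tab <- tabulate(as.vector(g0) + 1L, 3L) / n
  expect_lt(max(abs(tab - c(0.25, 0.5, 0.25))), 3 * sqrt(0.25 / n))
  g1 <- draw_genotypes(rep(0.5, 1), n, inbreeding_F = 1)
  expect_equal(sum(g1 == 1L), 0L)
  gF <- draw_genotypes(rep(0.5, 1), n, inbreeding_F = 0.3)
  expect_lt(abs(mean(gF == 1L) - 0.35), 3 * sqrt(0.35 * 0.65 / n))
  expect_error(draw_genotypes(0.5, 10, inbreeding_F = -0.1), "inbreeding_F")
})

test_that("read simulation: Poisson depth, error channel symmetry, edge cases", {
  set.seed(5)
  g <- matrix(1L, 1, 2e5)  # all hets
  rd <- simulate_reads(g, mean_depth = 3, error_rate = 0.2)
  depth <- as.vector(rd$anc + rd$der)
  expect_lt(abs(mean(depth) - 3), 3 * sqrt(3 / 2e5))
  # hets emit derived reads at exactly 1/2 under any symmetric flip
  nread <- sum(depth)
  expect_lt(abs(sum(rd$der) / nread - 0.5), 3 * sqrt(0.25 / nread))
  # error-free homozygote produces only ancestral reads
  g0 <- matrix(0L, 10, 10)
  rd0 <- simulate_reads(g0, 2, error_rate = 0)
  expect_true(all(rd0$der == 0L))
  # zero-depth cells carry (0, 0)
  expect_true(any(rd0$anc + rd0$der == 0L))
  expect_error(simulate_reads(g0, 2, error_rate = 0.7), "error_rate")
})

test_that("four-base error convention thins depth and flips at e/3 among retained", {
  set.seed(6)
  g <- matrix(0L, 1, 2e5)
  e <- 0.3
  rd <- simulate_reads(g, 5, error_rate = e, error_model = "four_base")
  depth <- sum(rd$anc + rd$der)
  expect_lt(abs(depth / 1e6 - (1 - 2 * e / 3)), 3 * sqrt(5 / 2e5))
  flip <- (e / 3) / (1 - 2 * e / 3)
  expect_lt(abs(sum(rd$der) / depth - flip), 3 * sqrt(flip / depth))
})

test_that("simulation is bitwise-reproducible under a fixed seed", {
  run <- function() {
    set.seed(99)
    cfg <- sim_config(500, n_individuals = 20)
    fr <- draw_ancestral_freqs(cfg)
    g <- draw_genotypes(fr, 20)
    rd <- simulate_reads(g, 2, 0.01)
    list(fr, g, rd)
  }
  expect_identical(run(), run())
})
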