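# Independent brute-force oracles used to check the package's estimators.
# These deliberately use naive algorithms (full enumeration, direct loops,
# exhaustive scans) and never share code with the implementation.

# random genotype-likelihood object (log scale)
rand_genolik <- function(M, N) {
  mk <- function() matrix(log(runif(M * N)), M, N)
  structure(list(ll0 = mk(), ll1 = mk(), ll2 = mk(),
                 n_sites = M, n_ind = N,
                 error_rate = 0.01, error_model = "flip"),
            class = "genolik")
}

# SAF likelihood by full enumeration of all 3^N genotype configurations,
# grouped by total derived count with hypergeometric configuration weights
saf_enumerate <- function(gl) {
  M <- gl$n_sites; N <- gl$n_ind
  combs <- as.matrix(expand.grid(rep(list(0:2), N)))
  out <- matrix(0, M, 2 * N + 1)
  for (s in seq_len(M)) {
    L <- rbind(exp(gl$ll0[s, ]), exp(gl$ll1[s, ]), exp(gl$ll2[s, ]))
    for (r in seq_len(nrow(combs))) {
      g <- combs[r, ]
      w <- prod(choose(2, g)) * prod(L[cbind(g + 1L, seq_len(N))])
      out[s, sum(g) + 1L] <- out[s, sum(g) + 1L] + w
    }
    out[s, ] <- out[s, ] / choose(2 * N, 0:(2 * N))
    out[s, ] <- out[s, ] / sum(out[s, ])
  }
  out
}

# genotype-posterior covariance by direct per-entry summation
covariance_direct <- function(eg, eg2, f, w) {
  n <- ncol(eg)
  cmat <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    acc <- 0
    for (s in seq_len(nrow(eg))) {
      acc <- acc + if (a == b)
        w[s] * (eg2[s, a] - 4 * f[s] * eg[s, a] + 4 * f[s]^2)
      else
        w[s] * (eg[s, a] - 2 * f[s]) * (eg[s, b] - 2 * f[s])
    }
    cmat[a, b] <- acc / sum(w)
  }
  cmat
}

# best achievable |#called - true_count| over every possible cut (exhaustive)
threshold_scan_best <- function(p, true_count) {
  cand <- sort(unique(c(0, p, 1)))
  min(vapply(cand, function(t) abs(sum(p > t) - true_count), numeric(1)))
}

# Hardy-Weinberg mixture log-likelihood of an allele frequency at one site
hwe_loglik <- function(gl, s, f) {
  l0 <- exp(gl$ll0[s, ]); l1 <- exp(gl$ll1[s, ]); l2 <- exp(gl$ll2[s, ])
  sum(log(l0 * (1 - f)^2 + l1 * 2 * f * (1 - f) + l2 * f^2))
}

# window-level S and H recount, naive site-by-site loop
diversity_recount <- function(g, windows) {
  S <- H <- numeric(length(unique(windows)))
  for (w in sort(unique(windows))) {
    idx <- which(windows == w)
    seg <- 0; het <- 0
    for (s in idx) {
      f <- sum(g[s, ]) / (2 * ncol(g))
      if (f > 0 && f < 1) seg <- seg + 1
      het <- het + 2 * f * (1 - f)
    }
    S[w] <- seg / length(idx); H[w] <- het / length(idx)
  }
  list(S = S, H = H)
}
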