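#' Split sites into contiguous non-overlapping windows
#'
#' Windows are contiguous, disjoint and cover all sites; when `n_windows`
#' does not divide `n_sites` the last window absorbs the remainder.
#'
#' @param n_sites number of sites.
#' @param n_windows number of windows (at most `n_sites`).
#' @return integer vector of length `n_sites` mapping each site to a window.
#' @export
site_windows <- function(n_sites, n_windows) {
  n_sites <- as.integer(n_sites); n_windows <- as.integer(n_windows)
  if (n_windows < 1L || n_windows > n_sites)
    stop("n_windows must lie in [1, n_sites]")
  base <- n_sites %/% n_windows
  sizes <- rep(base, n_windows)
  sizes[n_windows] <- sizes[n_windows] + n_sites %% n_windows
  rep.int(seq_len(n_windows), sizes)
}

#' Window-level diversity from known genotypes
#'
#' Per window: `S`, the proportion of segregating sites, and `H`, the mean
#' expected heterozygosity `2 f (1 - f)` at the sample allele frequency `f`.
#' A site segregates when its sample frequency is strictly between 0 and 1;
#' `indicator = "heterozygote"` instead uses the literal
#' at-least-one-heterozygote rule, which misses polymorphic configurations
#' composed solely of opposite homozygotes.
#'
#' @param g integer genotype matrix (sites x individuals).
#' @param windows window map from [site_windows()].
#' @param indicator segregating-site rule, `"frequency"` (default) or
#'   `"heterozygote"`.
#' @param small_sample_correction multiply `H` by `2N / (2N - 1)`.
#' @return data frame with columns `window`, `S`, `H` and attribute
#'   `source = "known_genotypes"`.
#' @export
diversity_known <- function(g, windows, indicator = c("frequency", "heterozygote"),
                            small_sample_correction = FALSE) {
  indicator <- match.arg(indicator)
  stopifnot(nrow(g) == length(windows))
  n2 <- 2 * ncol(g)
  f <- rowSums(g) / n2
  seg <- if (indicator == "frequency") f > 0 & f < 1
         else rowSums(g == 1L) > 0
  h <- 2 * f * (1 - f)
  if (small_sample_correction) h <- h * n2 / (n2 - 1)
  out <- data.frame(window = sort(unique(windows)),
                    S = as.numeric(tapply(seg, windows, mean)),
                    H = as.numeric(tapply(h, windows, mean)))
  attr(out, "source") <- "known_genotypes"
  out
}

#' Window-level diversity from sample-allele-frequency posteriors
#'
#' Posterior-expected analogues of the known-genotype statistics: per window,
#' `S` is the mean probability of being variable, and `H` the mean of
#' `sum_j post[j] * 2 (j/2N) (1 - j/2N)`.
#'
#' @param saf a `saf_fit` object from [saf_posterior()].
#' @param windows window map from [site_windows()].
#' @param small_sample_correction multiply `H` by `2N / (2N - 1)`.
#' @return data frame with columns `window`, `S`, `H` and attribute
#'   `source = "sequencing"`.
#' @export
diversity_seq <- function(saf, windows, small_sample_correction = FALSE) {
  stopifnot(inherits(saf, "saf_fit"), nrow(saf$post) == length(windows))
  n2 <- 2 * saf$n_ind
  jf <- (0:n2) / n2
  hsite <- as.numeric(saf$post %*% (2 * jf * (1 - jf)))
  if (small_sample_correction) hsite <- hsite * n2 / (n2 - 1)
  out <- data.frame(window = sort(unique(windows)),
                    S = as.numeric(tapply(saf$p_variable, windows, mean)),
                    H = as.numeric(tapply(hsite, windows, mean)))
  attr(out, "source") <- "sequencing"
  out
}

#' Standardised bias between sequencing-based and known-genotype estimates
#'
#' Per window, `delta = (estimate_seq - estimate_known) / estimate_known` for
#' both `S` and `H`. Positive values indicate over-estimation. Windows whose
#' known-genotype denominator is zero are dropped with a warning.
#'
#' @param est_seq,est_known window-level data frames from [diversity_seq()]
#'   and [diversity_known()] over the same windows.
#' @return data frame with columns `window`, `delta_S`, `delta_H`.
#' @export
standardized_bias <- function(est_seq, est_known) {
  stopifnot(nrow(est_seq) == nrow(est_known),
            all(est_seq$window == est_known$window))
  ok <- est_known$S > 0 & est_known$H > 0
  if (!all(ok))
    warning(sum(!ok), " window(s) with zero known-genotype diversity dropped")
  data.frame(window = est_known$window[ok],
             delta_S = (est_seq$S[ok] - est_known$S[ok]) / est_known$S[ok],
             delta_H = (est_seq$H[ok] - est_known$H[ok]) / est_known$H[ok])
}

# top-k / bottom-k indices with ties broken by (window) index
top_k_idx <- function(x, k, decreasing = TRUE) {
  ord <- order(x, seq_along(x), decreasing = c(decreasing, FALSE),
               method = "radix")
  ord[seq_len(k)]
}

#' Recovery of diversity outlier windows
#'
#' How well the sequencing-based window series identifies the extremes of the
#' known-genotype series: counts of shared top-`k` and bottom-`k` windows
#' (ties broken by window index) and the Spearman rank correlation between
#' the two series.
#'
#' @param x_known,x_seq per-window statistics (e.g. `H`) from known genotypes
#'   and from sequencing data.
#' @param k number of extreme windows per tail.
#' @return list with `top_overlap`, `bottom_overlap`, `rank_correlation`.
#' @export
outlier_recovery <- function(x_known, x_seq, k) {
  stopifnot(length(x_known) == length(x_seq), 2 * k <= length(x_known))
  list(top_overlap = length(intersect(top_k_idx(x_known, k, TRUE),
                                      top_k_idx(x_seq, k, TRUE))),
       bottom_overlap = length(intersect(top_k_idx(x_known, k, FALSE),
                                         top_k_idx(x_seq, k, FALSE))),
       rank_correlation = stats::cor(x_known, x_seq, method = "spearman"))
}
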