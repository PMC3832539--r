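#' Dynamic SNP-calling threshold
#'
#' Chooses the probability-of-being-variable cut-off that makes the number of
#' called sites (`p_variable > t`, strict) as close as possible to the known
#' number of truly variable sites — the optimal trade-off between
#' over-calling and under-calling. Ties are broken toward the larger
#' threshold (fewer calls).
#'
#' Candidate thresholds are, by default, a regular probability grid of step
#' `grid_step` (plus 0 and 1): scanning every observed `p_variable` value
#' instead (`candidates = "exact"`) lets the threshold descend into the mass
#' of near-zero probabilities at numerically tiny values purely to balance
#' the count, admitting junk calls that no analyst would accept; the grid
#' confines the scan to meaningful probability levels while costing at most
#' one grid step of resolution.
#'
#' @param p_variable per-site probabilities of being variable.
#' @param true_count known number of variable sites.
#' @param candidates `"grid"` (default) or `"exact"` (all observed values).
#' @param grid_step grid resolution for `candidates = "grid"`.
#' @return the selected threshold, with attribute `n_called`.
#' @export
dynamic_threshold <- function(p_variable, true_count,
                              candidates = c("grid", "exact"),
                              grid_step = 0.01) {
  candidates <- match.arg(candidates)
  if (length(p_variable) == 0L) stop("empty p_variable")
  if (any(p_variable < 0 | p_variable > 1)) stop("probabilities outside [0, 1]")
  cand <- if (candidates == "grid") seq(0, 1, by = grid_step)
          else sort(unique(c(0, p_variable, 1)))
  sp <- sort(p_variable)
  n_called <- length(sp) - findInterval(cand, sp)  # #{p > t} per candidate
  diffs <- abs(n_called - true_count)
  best <- which(diffs == min(diffs))
  pick <- best[length(best)]  # candidates ascend: last = largest threshold
  structure(cand[pick], n_called = n_called[pick])
}

#' Call SNPs at a threshold and score against the truth
#'
#' Sites with `p_variable` strictly above the threshold are called variable.
#' Scores the calls against per-site truth flags (population- or sample-level
#' variability): confusion counts, false-positive rate `FP/(FP+TN)`,
#' false-negative rate `FN/(TP+FN)`, precision `TP/(TP+FP)` and recall
#' `TP/(TP+FN)`. Precision with no calls is reported as 1 (with a warning);
#' fixed thresholds such as 0.90/0.95/0.99 are passed directly.
#'
#' @param p_variable per-site probabilities of being variable.
#' @param threshold calling cut-off in `[0, 1]`.
#' @param truth logical per-site truth flags.
#' @param truth_level label recorded in the result, `"population"` or
#'   `"sample"`.
#' @param eval_mask optional logical mask restricting which sites are scored
#'   (e.g. from [depth_filter()] or [maf_restrict()]); calls are still made
#'   on all sites.
#' @return an object of class `snp_call` (a named list of the threshold,
#'   per-site calls, confusion counts and the four rates).
#' @export
call_and_score <- function(p_variable, threshold, truth,
                           truth_level = c("population", "sample"),
                           eval_mask = NULL) {
  truth_level <- match.arg(truth_level)
  stopifnot(length(p_variable) == length(truth))
  if (threshold < 0 || threshold > 1) stop("threshold outside [0, 1]")
  calls <- p_variable > threshold
  keep <- if (is.null(eval_mask)) rep(TRUE, length(calls)) else eval_mask
  stopifnot(length(keep) == length(calls))
  tp <- sum(calls & truth & keep); fp <- sum(calls & !truth & keep)
  fn <- sum(!calls & truth & keep); tn <- sum(!calls & !truth & keep)
  precision <- if (tp + fp == 0L) {
    warning("no calls: precision reported as 1")
    1
  } else tp / (tp + fp)
  out <- list(threshold = as.numeric(threshold), calls = calls,
              tp = tp, fp = fp, fn = fn, tn = tn,
              fp_rate = if (fp + tn == 0L) 0 else fp / (fp + tn),
              fn_rate = if (tp + fn == 0L) 0 else fn / (tp + fn),
              precision = precision,
              recall = if (tp + fn == 0L) 0 else tp / (tp + fn),
              truth_level = truth_level)
  class(out) <- "snp_call"
  out
}

#' @export
print.snp_call <- function(x, ...) {
  cat(sprintf("SNP calls at threshold %.3g (%s-level truth)\n",
              x$threshold, x$truth_level))
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  precision %.3f  recall %.3f  FP rate %.4f  FN rate %.3f\n",
              x$precision, x$recall, x$fp_rate, x$fn_rate))
  invisible(x)
}

#' Total-depth site filter
#'
#' Retains sites whose total sequencing depth (summed over individuals) is at
#' least the given empirical percentile of the per-site totals (order
#' statistic; `percentile = 0` retains everything).
#'
#' @param depth per-site total depths, or a `read_counts` object.
#' @param percentile percentile in `[0, 100)` below which sites are dropped.
#' @return logical retention mask.
#' @export
depth_filter <- function(depth, percentile) {
  if (inherits(depth, "read_counts")) depth <- total_depth(depth)
  if (percentile < 0 || percentile >= 100)
    stop("percentile must lie in [0, 100)")
  if (percentile == 0) return(rep(TRUE, length(depth)))
  depth >= stats::quantile(depth, percentile / 100, type = 1, names = FALSE)
}

#' Restrict evaluation to common variants
#'
#' Mask of sites whose minor allele frequency exceeds `min_maf` at the chosen
#' truth level (population frequencies or sample frequencies). Invariable
#' sites (frequency 0 or 1) always pass: the restriction removes rare true
#' variants from the evaluation, not the negatives.
#'
#' @param freq per-site true derived-allele frequencies.
#' @param min_maf minor-allele-frequency cut-off (strict).
#' @return logical evaluation mask.
#' @export
maf_restrict <- function(freq, min_maf = 0.01) {
  stopifnot(all(freq >= 0 & freq <= 1))
  maf <- pmin(freq, 1 - freq)
  maf == 0 | maf > min_maf
}
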