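#' Constant-total-coverage design tables
#'
#' The study designs trade per-sample depth against sample size at a fixed
#' total sequencing effort: for the single-population analyses 1X/1000,
#' 2X/500, 10X/100 and 50X/20 (total 1000X); for the three-population
#' structure analyses 1X/40, 2X/20, 10X/4 and 20X/2 per population (total
#' 40X per population).
#'
#' @return data frame of designs (`depth` and `n`, or `depth` and
#'   `n_per_pop`).
#' @export
default_designs <- function() {
  data.frame(depth = c(1, 2, 10, 50), n = c(1000L, 500L, 100L, 20L))
}

#' @rdname default_designs
#' @export
default_structure_designs <- function() {
  data.frame(depth = c(1, 2, 10, 20), n_per_pop = c(40L, 20L, 4L, 2L))
}

#' Default three-population subdivision levels
#'
#' High, medium and low genetic subdivision as (deep, shallow) F_ST pairs:
#' (0.4, 0.1), (0.3, 0.05), (0.1, 0.02).
#'
#' @return named list of length-2 F_ST vectors.
#' @export
default_fst_levels <- function() {
  list(high = c(0.4, 0.1), medium = c(0.3, 0.05), low = c(0.1, 0.02))
}

check_constant_product <- function(depth, n) {
  prod <- depth * n
  if (length(unique(round(prod, 8))) != 1L)
    stop("designs must share a constant depth x sample-size product; got ",
         paste(prod, collapse = ", "))
  invisible(prod[1])
}

# one simulated window analysed end-to-end: frequencies -> genotypes ->
# reads -> genotype likelihoods -> ML frequencies -> SAF posterior
analyze_window <- function(n_sites, prob_variable, sfs_model, exp_rate,
                           n_ind, depth, error_rate, error_model,
                           inbreeding_F, pool_size = NULL, pool_idx = NULL) {
  cfg <- sim_config(n_sites = n_sites, prob_variable = prob_variable,
                    sfs_model = sfs_model, exp_rate = exp_rate,
                    n_individuals = n_ind, inbreeding_F = inbreeding_F,
                    mean_depth = depth, error_rate = error_rate,
                    error_model = error_model)
  freq <- draw_ancestral_freqs(cfg)
  if (is.null(pool_size)) {
    g_pool <- draw_genotypes(freq, n_ind, inbreeding_F)
    g_sub <- g_pool
  } else {
    g_pool <- draw_genotypes(freq, pool_size, inbreeding_F)
    g_sub <- g_pool[, pool_idx, drop = FALSE]
  }
  reads <- simulate_reads(g_sub, depth, error_rate, error_model)
  gl <- genotype_likelihoods(reads)
  saf <- saf_posterior(gl)
  list(freq = freq, g_pool = g_pool, g_sub = g_sub, reads = reads, saf = saf)
}

#' SNP-calling experiment across constant-coverage designs
#'
#' For each design and each window, simulates sites, computes per-site
#' probabilities of being variable, calls SNPs under one or more threshold
#' modes (the dynamic count-matching threshold and/or fixed cut-offs, all
#' scored on the same simulated data) and scores them against the truth.
#'
#' @param designs data frame with columns `depth` and `n`; the product must
#'   be constant across rows.
#' @param n_windows,sites_per_window number and size of independent windows.
#' @param prob_variable,sfs_model,exp_rate,error_rate,error_model,inbreeding_F
#'   simulator settings (see [sim_config()]).
#' @param threshold_modes list whose elements are `"dynamic"` or numeric
#'   fixed cut-offs, e.g. `list("dynamic", 0.95)`.
#' @param truth_level `"population"` (variability in the population the
#'   sample was drawn from) or `"sample"` (variability among the sequenced
#'   individuals).
#' @param depth_percentile drop sites below this total-depth percentile from
#'   the evaluation (0 = keep all).
#' @param min_maf restrict the evaluation to common variants (0 = keep all).
#' @param seed integer seed; the whole experiment is reproducible from it.
#' @return object of class `snp_experiment`: list with the per-window
#'   results data frame (`windows`) and the design/simulator settings.
#' @export
run_snp_experiment <- function(designs = default_designs(),
                               n_windows = 100L, sites_per_window = 500L,
                               prob_variable = 0.1,
                               sfs_model = "neutral_exponential",
                               exp_rate = 44, error_rate = 0.01,
                               error_model = "flip", inbreeding_F = 0,
                               threshold_modes = list("dynamic"),
                               truth_level = c("population", "sample"),
                               depth_percentile = 0, min_maf = 0,
                               seed = NULL) {
  truth_level <- match.arg(truth_level)
  check_constant_product(designs$depth, designs$n)
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", nrow(designs) * n_windows * length(threshold_modes))
  r <- 0L
  for (d in seq_len(nrow(designs))) {
    depth <- designs$depth[d]; n_ind <- designs$n[d]
    for (w in seq_len(n_windows)) {
      an <- analyze_window(sites_per_window, prob_variable, sfs_model,
                           exp_rate, n_ind, depth, error_rate, error_model,
                           inbreeding_F)
      truth <- if (truth_level == "population") an$freq$is_variable
               else {
                 fs <- rowSums(an$g_sub) / (2 * n_ind)
                 fs > 0 & fs < 1
               }
      truth_freq <- if (truth_level == "population") an$freq$freq
                    else rowSums(an$g_sub) / (2 * n_ind)
      mask <- depth_filter(an$reads, depth_percentile) &
        maf_restrict(truth_freq, min_maf)
      pv <- an$saf$p_variable
      for (mode in threshold_modes) {
        thr <- if (identical(mode, "dynamic"))
          dynamic_threshold(pv, sum(truth)) else as.numeric(mode)
        sc <- call_and_score(pv, thr, truth, truth_level, eval_mask = mask)
        r <- r + 1L
        rows[[r]] <- data.frame(
          depth = depth, n = n_ind, window = w,
          mode = if (identical(mode, "dynamic")) "dynamic"
                 else sprintf("fixed_%g", mode),
          threshold = sc$threshold, tp = sc$tp, fp = sc$fp, fn = sc$fn,
          tn = sc$tn, fp_rate = sc$fp_rate, fn_rate = sc$fn_rate,
          precision = sc$precision, recall = sc$recall)
      }
    }
  }
  out <- list(windows = do.call(rbind, rows), designs = designs,
              settings = list(n_windows = n_windows,
                              sites_per_window = sites_per_window,
                              prob_variable = prob_variable,
                              sfs_model = sfs_model, exp_rate = exp_rate,
                              error_rate = error_rate,
                              error_model = error_model,
                              inbreeding_F = inbreeding_F,
                              truth_level = truth_level,
                              depth_percentile = depth_percentile,
                              min_maf = min_maf, seed = seed))
  class(out) <- "snp_experiment"
  out
}

#' Summarise a SNP-calling experiment
#'
#' Mean and standard deviation of precision and recall (and FP/FN rates)
#' across windows, per design and threshold mode.
#'
#' @param object a `snp_experiment`.
#' @param ... unused.
#' @return data frame with one row per design x mode.
#' @export
summary.snp_experiment <- function(object, ...) {
  w <- object$windows
  key <- paste(w$depth, w$n, w$mode)
  first <- !duplicated(key)
  agg <- function(x, f)
    vapply(key[first], function(k) f(x[key == k]), numeric(1), USE.NAMES = FALSE)
  out <- data.frame(depth = w$depth[first], n = w$n[first],
                    mode = w$mode[first],
                    precision_mean = agg(w$precision, mean),
                    precision_sd = agg(w$precision, stats::sd),
                    recall_mean = agg(w$recall, mean),
                    recall_sd = agg(w$recall, stats::sd),
                    fp_rate_mean = agg(w$fp_rate, mean),
                    fn_rate_mean = agg(w$fn_rate, mean))
  out[order(out$mode, out$depth), ]
}

#' @export
print.snp_experiment <- function(x, ...) {
  s <- x$settings
  cat(sprintf("SNP-calling experiment: %d windows x %d sites, %s-level truth\n",
              s$n_windows, s$sites_per_window, s$truth_level))
  print(summary(x), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Nucleotide-diversity experiment across constant-coverage designs
#'
#' For each design and window, simulates genotypes for the full pool of
#' individuals, takes the known-genotype diversity of the pool as the truth,
#' sequences a fixed subsample (drawn once per design, without replacement)
#' at the design depth, estimates `S` and `H` from the SAF posteriors, and
#' reports the per-window standardised biases.
#'
#' @inheritParams run_snp_experiment
#' @param pool_size size of the simulated individual pool whose known
#'   genotypes define the truth.
#' @return object of class `diversity_experiment` with a per-window data
#'   frame (`windows`: known and sequencing-based `S`/`H` plus `delta_S`,
#'   `delta_H`).
#' @export
run_diversity_experiment <- function(designs = default_designs(),
                                     n_windows = 100L,
                                     sites_per_window = 500L,
                                     prob_variable = 0.1,
                                     sfs_model = "neutral_exponential",
                                     exp_rate = 44, error_rate = 0.01,
                                     error_model = "flip", inbreeding_F = 0,
                                     pool_size = 1000L, seed = NULL) {
  check_constant_product(designs$depth, designs$n)
  if (any(designs$n > pool_size)) stop("design sample size exceeds the pool")
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", nrow(designs) * n_windows)
  r <- 0L
  for (d in seq_len(nrow(designs))) {
    depth <- designs$depth[d]; n_ind <- designs$n[d]
    pool_idx <- sample.int(pool_size, n_ind)
    for (w in seq_len(n_windows)) {
      an <- analyze_window(sites_per_window, prob_variable, sfs_model,
                           exp_rate, n_ind, depth, error_rate, error_model,
                           inbreeding_F, pool_size = pool_size,
                           pool_idx = pool_idx)
      wmap <- site_windows(sites_per_window, 1L)
      known <- diversity_known(an$g_pool, wmap)
      seq_est <- diversity_seq(an$saf, wmap)
      bias <- standardized_bias(seq_est, known)
      r <- r + 1L
      rows[[r]] <- data.frame(
        depth = depth, n = n_ind, window = w,
        S_known = known$S, H_known = known$H,
        S_seq = seq_est$S, H_seq = seq_est$H,
        delta_S = if (nrow(bias)) bias$delta_S else NA_real_,
        delta_H = if (nrow(bias)) bias$delta_H else NA_real_)
    }
  }
  out <- list(windows = do.call(rbind, rows), designs = designs,
              settings = list(n_windows = n_windows,
                              sites_per_window = sites_per_window,
                              prob_variable = prob_variable,
                              sfs_model = sfs_model, exp_rate = exp_rate,
                              error_rate = error_rate,
                              error_model = error_model,
                              inbreeding_F = inbreeding_F,
                              pool_size = pool_size, seed = seed))
  class(out) <- "diversity_experiment"
  out
}

#' @export
print.diversity_experiment <- function(x, ...) {
  w <- x$windows
  key <- paste(w$depth, w$n)
  first <- !duplicated(key)
  agg <- function(v)
    vapply(key[first], function(k) stats::median(v[key == k], na.rm = TRUE),
           numeric(1), USE.NAMES = FALSE)
  s <- data.frame(depth = w$depth[first], n = w$n[first],
                  median_delta_S = agg(w$delta_S),
                  median_delta_H = agg(w$delta_H))
  cat(sprintf("Diversity experiment: %d windows x %d sites, pool of %d\n",
              x$settings$n_windows, x$settings$sites_per_window,
              x$settings$pool_size))
  print(s[order(s$depth), ], digits = 3, row.names = FALSE)
  invisible(x)
}

#' Population-structure experiment across constant-coverage designs
#'
#' For each subdivision level, simulates a three-population pool of known
#' genotypes (hierarchical Balding-Nichols model) and its reference PCA/SVM
#' decision map; then, for each design and replicate, resamples individuals
#' without replacement, sequences them at the design depth, rebuilds the
#' decision map from genotype posteriors (covariance weighted by the
#' probability of being variable, PCA, Procrustes alignment onto the
#' reference plane, SVM) and records the proportion of grid cells whose
#' predicted population differs from the reference map.
#'
#' @inheritParams run_snp_experiment
#' @param fst_levels named list of `(deep, shallow)` F_ST pairs.
#' @param designs data frame with columns `depth` and `n_per_pop`.
#' @param n_replicates resampling replicates per level x design.
#' @param n_sites number of independent sites.
#' @param pool_per_pop pool individuals per population.
#' @param grid_size grid dimensions for the decision-map comparison.
#' @param variable_only simulate only population-variable sites.
#' @return object of class `structure_experiment` with per-replicate results
#'   (`replicates`) and, for each level x design, the replicate of median
#'   accuracy's grid maps (`median_maps`).
#' @export
run_structure_experiment <- function(fst_levels = default_fst_levels(),
                                     designs = default_structure_designs(),
                                     n_replicates = 100L, n_sites = 10000L,
                                     prob_variable = 0.1,
                                     sfs_model = "neutral_exponential",
                                     exp_rate = 44, error_rate = 0.01,
                                     error_model = "flip",
                                     pool_per_pop = 40L,
                                     grid_size = c(50, 50),
                                     variable_only = FALSE, seed = NULL) {
  check_constant_product(designs$depth, designs$n_per_pop)
  if (any(designs$n_per_pop > pool_per_pop))
    stop("design sample size exceeds the per-population pool")
  if (!is.null(seed)) set.seed(seed)
  rows <- list(); maps <- list()
  for (lev in names(fst_levels)) {
    fst <- fst_levels[[lev]]
    cfg <- sim_config(n_sites = n_sites,
                      prob_variable = if (variable_only) 1 else prob_variable,
                      sfs_model = sfs_model, exp_rate = exp_rate,
                      n_individuals = 3L * pool_per_pop,
                      mean_depth = 1, error_rate = error_rate,
                      error_model = error_model)
    freq <- draw_ancestral_freqs(cfg)
    freq <- draw_subpop_freqs(freq, structure_config(fst[1], fst[2], pool_per_pop, 1))
    g_pool <- do.call(cbind, lapply(1:3, function(k)
      draw_genotypes(freq$freq_subpop[, k], pool_per_pop)))
    labels <- rep(paste0("pop", 1:3), each = pool_per_pop)
    cov_known <- covariance_from_posteriors(g_pool)
    pca_known <- pca_project(cov_known)
    model_known <- fit_structure_model(pca_known$coords, labels)
    for (d in seq_len(nrow(designs))) {
      depth <- designs$depth[d]; npp <- designs$n_per_pop[d]
      mf <- numeric(n_replicates)
      rep_results <- vector("list", n_replicates)
      for (rep_i in seq_len(n_replicates)) {
        idx <- as.vector(vapply(0:2, function(k)
          k * pool_per_pop + sample.int(pool_per_pop, npp),
          integer(npp)))
        g_sub <- g_pool[, idx, drop = FALSE]
        reads <- simulate_reads(g_sub, depth, error_rate, error_model)
        gl <- genotype_likelihoods(reads)
        f_ml <- estimate_allele_freq_ml(gl, reads = reads)
        saf <- saf_posterior(gl, f_ml = f_ml)
        gp <- genotype_posterior(gl, f_ml)
        cov_seq <- covariance_from_posteriors(gp, weights = saf$p_variable)
        pca_seq <- pca_project(cov_seq)
        pro <- procrustes_align(pca_seq$coords, pca_known$coords[idx, , drop = FALSE])
        model_seq <- fit_structure_model(pro$aligned, labels[idx])
        cmp <- grid_compare(model_known, model_seq, pca_known$coords, grid_size)
        mf[rep_i] <- cmp$mislabel_fraction
        rep_results[[rep_i]] <- cmp
      }
      rows[[length(rows) + 1L]] <- data.frame(
        level = lev, fst_deep = fst[1], fst_shallow = fst[2],
        depth = depth, n_per_pop = npp,
        replicate = seq_len(n_replicates), mislabel_fraction = mf)
      # export the replicate whose accuracy sits at the distribution median
      med_i <- which.min(abs(mf - stats::median(mf)))
      maps[[paste(lev, depth, npp, sep = "_")]] <- rep_results[[med_i]]
    }
  }
  out <- list(replicates = do.call(rbind, rows), designs = designs,
              median_maps = maps,
              settings = list(fst_levels = fst_levels,
                              n_replicates = n_replicates, n_sites = n_sites,
                              prob_variable = prob_variable,
                              sfs_model = sfs_model, exp_rate = exp_rate,
                              error_rate = error_rate,
                              error_model = error_model,
                              pool_per_pop = pool_per_pop,
                              grid_size = grid_size,
                              variable_only = variable_only, seed = seed))
  class(out) <- "structure_experiment"
  out
}

#' @export
print.structure_experiment <- function(x, ...) {
  w <- x$replicates
  key <- paste(w$level, w$depth)
  first <- !duplicated(key)
  s <- data.frame(level = w$level[first], depth = w$depth[first],
                  n_per_pop = w$n_per_pop[first],
                  median_mislabel = vapply(key[first], function(k)
                    stats::median(w$mislabel_fraction[key == k]),
                    numeric(1), USE.NAMES = FALSE))
  cat(sprintf("Structure experiment: %d sites, %d replicates per design\n",
              x$settings$n_sites, x$settings$n_replicates))
  print(s[order(s$level, s$depth), ], digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write an experiment manifest
#'
#' Records the settings, seed, a hash of the configuration and the package
#' version alongside exported tables, so a run can be reproduced exactly.
#'
#' @param experiment an experiment object from the `run_*_experiment`
#'   functions.
#' @param file output JSON path.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(experiment, file) {
  cfg_json <- jsonlite::toJSON(experiment$settings, auto_unbox = TRUE,
                               digits = NA)
  man <- list(class = class(experiment)[1],
              settings = experiment$settings,
              config_hash = sprintf("%08x",
                                    sum(utf8ToInt(cfg_json) *
                                          (seq_along(utf8ToInt(cfg_json)) %% 97 + 1)) %%
                                      .Machine$integer.max),
              package_version = as.character(utils::packageVersion("ngsdesign")))
  jsonlite::write_json(man, file, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man)
}
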