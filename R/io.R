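#' Write genotype likelihoods in BEAGLE text format
#'
#' One row per site: marker id, the two allele codes (0 = ancestral,
#' 1 = derived), then three genotype-likelihood values per individual,
#' normalised to sum to one within each cell.
#'
#' @param gl a `genolik` object.
#' @param file output path.
#' @export
write_beagle <- function(gl, file) {
  stopifnot(inherits(gl, "genolik"))
  lin <- gl_linear(gl)
  tot <- lin$g0 + lin$g1 + lin$g2
  M <- gl$n_sites; N <- gl$n_ind
  vals <- matrix(0, M, 3L * N)
  vals[, seq(1L, 3L * N, 3L)] <- lin$g0 / tot
  vals[, seq(2L, 3L * N, 3L)] <- lin$g1 / tot
  vals[, seq(3L, 3L * N, 3L)] <- lin$g2 / tot
  hdr <- c("marker", "allele1", "allele2",
           paste0("Ind", rep(seq_len(N) - 1L, each = 3L)))
  out <- cbind(paste0("sim_", seq_len(M)), "0", "1",
               formatC(vals, format = "g", digits = 6))
  utils::write.table(rbind(hdr, out), file, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read BEAGLE-format genotype likelihoods
#'
#' @param file path to a BEAGLE genotype-likelihood text file.
#' @return a `genolik` object (log scale; the error model of the producer is
#'   not recoverable from the format and is recorded as `NA`).
#' @export
read_beagle <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         check.names = FALSE)
  vals <- as.matrix(d[, -(1:3), drop = FALSE])
  if (ncol(vals) %% 3L != 0L) stop("malformed BEAGLE file")
  N <- ncol(vals) %/% 3L
  gl <- list(ll0 = log(vals[, seq(1L, 3L * N, 3L), drop = FALSE]),
             ll1 = log(vals[, seq(2L, 3L * N, 3L), drop = FALSE]),
             ll2 = log(vals[, seq(3L, 3L * N, 3L), drop = FALSE]),
             n_sites = nrow(vals), n_ind = N,
             error_rate = NA_real_, error_model = NA_character_)
  class(gl) <- "genolik"
  gl
}

#' Write the true-frequency table as TSV
#'
#' Columns: site, ancestral frequency, variability flag, and (when present)
#' the per-subpopulation frequencies.
#'
#' @param freq a `freq_table`.
#' @param file output path.
#' @export
write_freq_table <- function(freq, file) {
  stopifnot(inherits(freq, "freq_table"))
  out <- data.frame(site = seq_len(nrow(freq)), freq = freq$freq,
                    is_variable = freq$is_variable)
  if (!is.null(freq$freq_subpop)) {
    sub <- freq$freq_subpop
    colnames(sub) <- paste0("freq_pop", seq_len(ncol(sub)))
    out <- cbind(out, sub)
  }
  utils::write.table(out, file, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(file)
}

#' Write true genotypes as a minimal VCF
#'
#' Diallelic sites with the ancestral allele as REF; the INFO field carries
#' the true population derived-allele frequency.
#'
#' @param g integer genotype matrix (sites x individuals).
#' @param freq per-site true frequencies (numeric vector or `freq_table`).
#' @param file output path.
#' @export
write_vcf_truth <- function(g, freq, file) {
  if (inherits(freq, "freq_table")) freq <- freq$freq
  stopifnot(nrow(g) == length(freq))
  gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow(g), ncol(g))
  lines <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=AF,Number=1,Type=Float,Description=\"True derived allele frequency\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT",
                     paste0("ind", seq_len(ncol(g)))), collapse = "\t"),
             paste("sim1", seq_len(nrow(g)), ".", "A", "C", ".", "PASS",
                   sprintf("AF=%g", freq), "GT",
                   apply(gt, 1L, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, file)
  invisible(file)
}

#' Write a per-window results table as TSV
#'
#' @param x a data frame (e.g. the `windows` element of an experiment).
#' @param file output path.
#' @export
write_window_table <- function(x, file) {
  utils::write.table(x, file, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(file)
}
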