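Package: ngsdesign
Title: Sequencing Depth Versus Sample Size in Genotype-Likelihood-Based
    Population Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and estimation toolkit for studying how per-sample
    sequencing depth and sample size, at a fixed total sequencing effort,
    affect population-genetic inference from low-coverage sequencing data.
    Simulates independent diallelic sites (exponential ancestral site
    frequency spectrum, Hardy-Weinberg or inbred genotypes, Balding-Nichols
    population subdivision, Poisson read depth, uniform sequencing error),
    computes genotype likelihoods and the sample allele frequency
    likelihood by dynamic programming, estimates per-site allele
    frequencies by EM, and derives window-level nucleotide diversity,
    probabilistic SNP calls with dynamic or fixed thresholds, and
    population-structure predictions from genotype-posterior covariance
    matrices (PCA, Procrustes alignment, SVM decision maps).
License: MIT
Encoding: UTF-8
Imports: Rcpp, e1071, stats, utils, yaml, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
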