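Package: nciimap
Title: Epistatic Association Mapping of Heterosis in Partial North Carolina II Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for dissecting heterosis with F1 hybrids from (partial)
    North Carolina II mating designs. Builds partial-NCII cross schedules,
    simulates inbred parental genotypes on a linkage map and deduces F1
    genotypes, computes the four dependent variables used in heterosis
    mapping (trait phenotype, general and specific combining ability, and
    mid-parent heterosis), constructs the joint additive-dominance-epistasis
    design matrix with environment interactions and population-structure
    covariates, and fits it by a fast empirical Bayesian LASSO with greedy
    basis selection under a normal-exponential-Gamma prior. Includes LD score
    regression on a binarized trait to diagnose population-structure
    inflation, and Monte Carlo drivers for power, heterosis-ranking and
    mating-proportion experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, yaml, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
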