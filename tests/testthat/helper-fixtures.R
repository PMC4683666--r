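# small in-code fixtures shared across test files

# a tiny one-chromosome map
tiny_map <- function(markers = 5, length_cM = 40) genome_map(1, length_cM, markers)

# deterministic parents: explicit dosage matrix (homozygous)
tiny_parents <- function(map = tiny_map()) {
  geno <- rbind(
    M1 = c(2, 2, 0, 0, 2),
    M2 = c(0, 2, 2, 0, 0),
    P1 = c(2, 0, 0, 2, 2),
    P2 = c(0, 0, 2, 2, 0))
  colnames(geno) <- map$marker
  genotype_table(geno, map, role = "parent")
}

# a small simulated population with one strong additive QTL, for fit tests
sim_additive_pop <- function(n = 60, markers = 6, h2 = 0.3, seed = 1) {
  map <- genome_map(1, 100, markers)
  parents <- simulate_parents(map, n, p = 0.5, seed = seed)
  qtl <- calibrate_effects(
    qtl_model(data.frame(type = "a", marker1 = map$marker[3],
                         marker2 = NA, h2 = h2),
              mu = 0, sigma2_e = 1), map)
  y <- simulate_phenotypes(parents, qtl)
  list(map = map, parents = parents, qtl = qtl, y = y)
}

# brute-force penalized per-effect objective used as an oracle:
# l(s2) = 0.5*(-log(1+s2*S) + Q^2*s2/(1+s2*S)) - lambda*s2
ell_oracle <- function(s2, S, Q, lambda)
  0.5 * (-log1p(s2 * S) + Q^2 * s2 / (1 + s2 * S)) - lambda * s2
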