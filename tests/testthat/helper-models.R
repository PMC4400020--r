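# Shared builders for the test suite.

neutral_model <- function(n = 20, mu = 1e-4, c_h = 0.2, shape = "concave",
                          scenario = scenario_linked()) {
  build_model(n, mu, fitness = fitness_spec(c_h, shape),
              scenario = scenario)
}

# gamete matrix with a single point mass
point_gametes <- function(model, allele, p) {
  x <- matrix(0, length(model$scenario$alleles), model$half + 1L,
              dimnames = list(model$scenario$alleles, 0:model$half))
  x[allele, p + 1L] <- 1
  x
}

# diploid matrix with a single point mass
point_cells <- function(model, genotype, i) {
  D <- matrix(0, length(model$scenario$genotypes), model$n + 1L,
              dimnames = list(model$scenario$genotypes, 0:model$n))
  D[genotype, i + 1L] <- 1
  D
}

# mirror a distribution matrix in its mutant-count index (haplotype relabel)
mirror_counts <- function(mat) {
  out <- mat[, rev(seq_len(ncol(mat))), drop = FALSE]
  colnames(out) <- colnames(mat)
  out
}

# rescale a linked-scenario gamete matrix so each mating type carries half
# the population (the fixed point the life cycle itself maintains)
balance_types <- function(g) {
  t1 <- sum(g[c("U1", "B1"), ])
  g[c("U1", "B1"), ] <- g[c("U1", "B1"), ] / (2 * t1)
  g["B2", ] <- g["B2", ] / (2 * sum(g["B2", ]))
  g
}

# Per-cell CLT envelope for Monte-Carlo state distributions: individuals of
# one MC generation are positively correlated (shared pairing pool,
# selection resampling with replacement), so cell counts are overdispersed
# relative to multinomial by a factor of about 3; cells with tiny
# expectation are skipped.
expect_mc_distribution <- function(emp, det, N, inflate = 3) {
  pr <- as.vector(det)
  obs <- as.vector(emp)
  keep <- pr * N >= 5
  bound <- 4 * sqrt(inflate * pr[keep] * (1 - pr[keep]) / N)
  expect_true(all(abs(obs[keep] - pr[keep]) < bound))
}

# generations until the uniparentally transmitting genotype(s) fix
generations_to_fixation <- function(n, mu, c_h = 0.2, shape = "concave",
                                    scenario = scenario_linked(),
                                    intro_placement = "homoplasmic_wild") {
  cfg <- run_config(n = n, mu = mu, fitness = fitness_spec(c_h, shape),
                    scenario = scenario, intro_placement = intro_placement)
  run <- simulate_upi(cfg, stop_when_fixed = TRUE)
  expect_true(run$fixation)
  run$generations_to_final
}
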