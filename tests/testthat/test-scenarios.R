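test_that("the linked scenario has the basic-model structure", {
  sc <- scenario_linked()
  expect_setequal(sc$alleles, c("U1", "B1", "B2"))
  expect_length(sc$genotypes, 2)
  pairs <- lapply(sc$rules, `[[`, "pair")
  # same-mating-type pairings (incl. U1 x B1) are absent, hence inviable
  expect_false(list(c("U1", "B1")) %in% pairs)
  expect_equal(unname(sc$uni_prob), c(1, 0))
})

test_that("recombination scenario emits recombinant alleles at rate P_r", {
  sc <- scenario_recombination(P_r = 0.3, uu_regime = "biparental")
  am <- sc$allele_map
  expect_equal(unname(am["U1B2", c("U1", "B2", "U2", "B1")]),
               c(0.35, 0.35, 0.15, 0.15))
  expect_equal(unname(am["U2B1", c("U2", "B1", "U1", "B2")]),
               c(0.35, 0.35, 0.15, 0.15))
  # inheritance-homozygous genotypes are unaffected by recombination
  expect_equal(unname(am["U1U2", ]), c(0.5, 0.5, 0, 0))
  expect_equal(unname(am["B1B2", ]), c(0, 0, 0.5, 0.5))
  expect_error(scenario_recombination(P_r = 0.7), "P_r")
  expect_error(scenario_recombination(0.5, uu_regime = "nope"))
})

test_that("scenario mating-rule mass balance accounts for inviable pairings", {
  set.seed(11)
  scenarios <- list(scenario_linked(),
                    scenario_recombination(0.5, "biparental"),
                    scenario_no_mating_types("uniparental"),
                    scenario_physarum(0.3),
                    scenario_didymium(0.4, 0.4, 0.2))
  for (sc in scenarios) {
    m <- build_model(8, 1e-3, fitness = fitness_spec(0.2), scenario = sc)
    g <- matrix(runif(length(sc$alleles) * 5), length(sc$alleles), 5,
                dimnames = list(sc$alleles, 0:4))
    g <- g / sum(g)
    res <- mate(g, m)
    f <- allele_frequencies(g)
    viable_expected <- 0
    for (r in sc$rules) {
      k <- if (r$pair[1] == r$pair[2]) 1 else 2
      viable_expected <- viable_expected + k * f[r$pair[1]] * f[r$pair[2]]
    }
    expect_equal(res$viable_mass, unname(viable_expected),
                 tolerance = 1e-12)
  }
})

test_that("leaky uniparental inheritance reduces to the limiting cases", {
  m_linked <- neutral_model(n = 8, mu = 1e-3)
  m_p0 <- build_model(8, 1e-3, fitness = fitness_spec(0.2),
                      scenario = scenario_physarum(0))
  m_p1 <- build_model(8, 1e-3, fitness = fitness_spec(0.2),
                      scenario = scenario_physarum(1))
  set.seed(5)
  g <- matrix(runif(3 * 5), 3, 5,
              dimnames = list(m_linked$scenario$alleles, 0:4))
  g <- g / sum(g)
  # P_b = 0: identical dynamics to the linked model
  expect_equal(unclass(step_generation(g, m_p0)$gametes),
               unclass(step_generation(g, m_linked)$gametes),
               tolerance = 1e-14)
  # P_b = 1: U1 x B2 fully biparental, no transmission difference
  res <- mate(g, m_p1)
  conv <- unname(convolve(g["U1", ], rev(g["B2", ]), type = "open"))
  expect_equal(unname(res$cells["U1B2", ]),
               conv * 2 / res$viable_mass, tolerance = 1e-12)
  expect_equal(unname(m_p1$scenario$uni_prob["U1B2"]), 0)
})

test_that("didymium constructor validates and weights donors", {
  expect_error(scenario_didymium(0.5, 0.4, 0.2), "sum to 1")
  sc <- scenario_didymium(0.6, 0.2, 0.2)
  expect_equal(unname(sc$uni_prob["U1U2"]), 0.8)
  comps <- sc$rules[[3]]$components
  expect_equal(vapply(comps, `[[`, numeric(1), "prob"), c(0.6, 0.2, 0.2))
})

test_that("didymium equilibrium depends only on P_b, not the donor split", {
  runs <- lapply(list(c(0.7, 0.1), c(0.4, 0.4)), function(sp) {
    cfg <- run_config(n = 8, mu = 1e-3,
                      fitness = fitness_spec(0.2, "linear"),
                      scenario = scenario_didymium(sp[1], sp[2], 0.2))
    simulate_upi(cfg)
  })
  expect_equal(runs[[1]]$equilibrium_upi_freq,
               runs[[2]]$equilibrium_upi_freq, tolerance = 1e-6)
  expect_equal(runs[[1]]$equilibrium_genotype_freq,
               runs[[2]]$equilibrium_genotype_freq, tolerance = 1e-6)
})

test_that("physarum equilibrium biparental frequency equals P_b once U1B2 fixes", {
  P_b <- 0.1
  cfg <- run_config(n = 8, mu = 1e-3, fitness = fitness_spec(0.2, "linear"),
                    scenario = scenario_physarum(P_b))
  run <- simulate_upi(cfg)
  expect_gt(unname(run$equilibrium_genotype_freq["U1B2"]), 1 - 1e-6)
  expect_equal(1 - run$equilibrium_upi_freq, P_b, tolerance = 1e-6)
})

test_that("without mating types UB matches the recombination-run U1B2 + U2B1", {
  fit <- fitness_spec(0.2, "concave")
  cfg_rec <- run_config(n = 8, mu = 1e-3, fitness = fit,
                        scenario = scenario_recombination(0.5, "biparental"))
  cfg_nmt <- run_config(n = 8, mu = 1e-3, fitness = fit,
                        scenario = scenario_no_mating_types("biparental"))
  run_rec <- simulate_upi(cfg_rec)
  run_nmt <- simulate_upi(cfg_nmt)
  expect_equal(unname(run_nmt$equilibrium_genotype_freq["UB"]),
               unname(run_rec$equilibrium_genotype_freq["U1B2"] +
                      run_rec$equilibrium_genotype_freq["U2B1"]),
               tolerance = 1e-4)
  # and the recombinant-genotype symmetry behind it
  expect_equal(unname(run_rec$equilibrium_genotype_freq["U1B2"]),
               unname(run_rec$equilibrium_genotype_freq["U2B1"]),
               tolerance = 1e-6)
})

test_that("dominant-U transmission drives uniparental inheritance to fixation", {
  # UB matings are themselves uniparental, so a rare B allele rides along
  # almost neutrally (its frequency decays only through the vanishing
  # B x B matings): uniparental *transmission* fixes long before the last
  # trace of B is gone
  cfg <- run_config(n = 8, mu = 1e-3, fitness = fitness_spec(0.2, "concave"),
                    scenario = scenario_no_mating_types("uniparental"))
  run <- simulate_upi(cfg, stop_when_fixed = TRUE)
  expect_true(run$fixation)
  expect_equal(run$equilibrium_upi_freq, 1, tolerance = 1e-6)
  expect_gt(unname(run$equilibrium_genotype_freq["UU"]), 0.99)
  expect_lt(unname(run$equilibrium_genotype_freq["BB"]), 1e-6)
})

test_that("mitosis scenario validates timing and reduces to linked at d = 0", {
  expect_error(scenario_mitosis(5, "midway"), "even")
  sc0 <- scenario_mitosis(0)
  m0 <- build_model(8, 1e-3, fitness = fitness_spec(0.2), scenario = sc0)
  ml <- neutral_model(n = 8, mu = 1e-3)
  set.seed(9)
  g <- matrix(runif(3 * 5), 3, 5, dimnames = list(sc0$alleles, 0:4))
  g <- g / sum(g)
  expect_equal(unclass(step_generation(g, m0)$gametes),
               unclass(step_generation(g, ml)$gametes), tolerance = 1e-14)
})
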