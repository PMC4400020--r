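test_that("biparental mating convolves parental mutant counts", {
  m <- neutral_model(n = 4)
  g <- point_gametes(m, "B1", 1)
  g["B2", 1] <- 1   # B2 homoplasmic wild
  g <- g / sum(g)
  res <- mate(g, m)
  expect_equal(sum(res$cells), 1)
  expect_equal(res$cells["B1B2", "1"], 1)   # point masses convolve to p+q
})

test_that("uniparental mating doubles the donor and ignores the recipient", {
  m <- neutral_model(n = 4)
  # homoplasmic-mutant donor
  g <- point_gametes(m, "U1", 2)
  g["B2", 2] <- 1   # heteroplasmic recipient, discarded
  g <- g / sum(g)
  res <- mate(g, m)
  expect_equal(res$cells["U1B2", "4"], 1)
  # heteroplasmic donor: doubling kernel row
  g <- point_gametes(m, "U1", 1)
  g["B2", 1] <- 1
  g <- g / sum(g)
  res <- mate(g, m)
  expect_equal(unname(res$cells["U1B2", ]), c(0, 0.25, 0.5, 0.25, 0))
})

test_that("mating renormalises over viable pairings and flags degeneracy", {
  m <- neutral_model(n = 4)
  # equal U1/B2 mix: pair mass 2 * 0.5 * 0.5 = 0.5 of all random unions
  g <- point_gametes(m, "U1", 0)
  g["B2", 1] <- 1
  g <- g / sum(g)
  res <- mate(g, m)
  expect_equal(res$viable_mass, 0.5)
  expect_equal(sum(res$cells), 1)
  # same-mating-type-only population cannot mate
  g_bad <- point_gametes(m, "U1", 0)
  g_bad["B1", 1] <- 1
  g_bad <- g_bad / sum(g_bad)
  expect_error(mate(g_bad, m), "degenerate")
})

test_that("mutation stage propagates the kernel and conserves mass", {
  m <- neutral_model(n = 2, mu = 0.1)
  m0 <- build_model(2, 0, fitness = fitness_spec(0.2),
                    scenario = scenario_linked())
  D <- point_cells(m, "B1B2", 0)
  expect_equal(mutate_cells(D, m0), D)  # zero rates: identity
  out <- mutate_cells(D, m)
  expect_equal(unname(out["B1B2", ]), c(0.81, 0.18, 0.01))
  expect_equal(sum(out), 1)
})

test_that("mutation commutes with haplotype relabelling at symmetric rates", {
  m <- neutral_model(n = 6, mu = 0.05)
  set.seed(8)
  D <- matrix(runif(2 * 7), 2, 7, dimnames = list(m$scenario$genotypes, 0:6))
  D <- D / sum(D)
  a <- mutate_cells(mirror_counts(D), m)
  b <- mirror_counts(mutate_cells(D, m))
  expect_equal(a, b, tolerance = 1e-14)
})

test_that("selection reweights by fitness and renormalises", {
  # n = 2, concave, c_h = 0.5: fitness (1, 0.5, 1)
  m <- neutral_model(n = 2, c_h = 0.5)
  D <- point_cells(m, "B1B2", 0)
  D["B1B2", ] <- c(0.5, 0.5, 0)
  res <- select_cells(D, m)
  expect_equal(unname(res$cells["B1B2", ]), c(2 / 3, 1 / 3, 0))
  expect_equal(unname(res$mean_fitness["B1B2"]), 0.75)
  expect_equal(res$sigma, 0.75)
  # homoplasmic populations are untouched and have unit mean fitness
  Dh <- point_cells(m, "U1B2", 2)
  resh <- select_cells(Dh, m)
  expect_equal(resh$cells, Dh)
  expect_equal(unname(resh$mean_fitness["U1B2"]), 1)
  # flat fitness: identity transform
  m0 <- neutral_model(n = 2, c_h = 0)
  res0 <- select_cells(D, m0)
  expect_equal(res0$cells, D)
})

test_that("meiosis maps homoplasmic cells to homoplasmic gametes", {
  m <- neutral_model(n = 4)
  gam <- meiose(point_cells(m, "U1B2", 4), m)
  expect_equal(sum(gam[, "2"]), 1)     # all gametes at p = n/2
  expect_equal(unname(gam["U1", "2"]), 0.5)
  expect_equal(unname(gam["B2", "2"]), 0.5)
  gam0 <- meiose(point_cells(m, "B1B2", 0), m)
  expect_equal(sum(gam0[, "0"]), 1)
})

test_that("meiosis of a heteroplasmic cell matches exhaustive enumeration", {
  m <- neutral_model(n = 4)
  gam <- meiose(point_cells(m, "B1B2", 2), m)
  pmf <- unname(gam["B1", ] + gam["B2", ])  # total over emitted alleles
  expect_equal(pmf, enumerate_meiosis(4, 2), tolerance = 1e-12)
})

test_that("mitosis conserves mass, fixes homoplasmy, and segregates", {
  m <- neutral_model(n = 4)
  D <- point_cells(m, "B1B2", 2)
  expect_equal(mitose(D, m, 0), D)
  for (i in c(0, 4))
    expect_equal(mitose(point_cells(m, "B1B2", i), m, 7),
                 point_cells(m, "B1B2", i))
  # heteroplasmy decays like the kernel's subdominant eigenvalue (0.8036
  # at n = 4), leaving ~1.5% after 20 divisions
  seg <- mitose(D, m, 20)
  expect_equal(sum(seg), 1)
  het <- sum(seg[, c("1", "2", "3")])
  expect_lt(het, 2e-2)
  lambda <- sort(abs(eigen(upievol:::mitosis_kernel(4))$values),
                 decreasing = TRUE)[3]
  expect_gt(het, lambda^20)
  expect_lt(het, 2 * lambda^20)
  # relabel symmetry forces an even split of the homoplasmic absorbers
  expect_equal(seg[, "0"], seg[, "4"], tolerance = 1e-12)
})

test_that("every stage except mating and selection conserves mass", {
  m <- neutral_model(n = 10, mu = 0.01)
  set.seed(1)
  D <- matrix(runif(2 * 11), 2, 11,
              dimnames = list(m$scenario$genotypes, 0:10))
  D <- D / sum(D)
  expect_equal(sum(mutate_cells(D, m)), 1, tolerance = 1e-9)
  expect_equal(sum(mitose(D, m, 3)), 1, tolerance = 1e-9)
  expect_equal(sum(meiose(D, m)), 1, tolerance = 1e-9)
})

test_that("a neutral full cycle leaves allele frequencies invariant", {
  # with the two mating types balanced at one half each (the fixed point
  # the cycle itself maintains), flat fitness leaves every allele
  # frequency unchanged
  m <- neutral_model(n = 8, mu = 0.01, c_h = 0)
  set.seed(42)
  for (rep in 1:5) {
    g <- matrix(runif(3 * 5), 3, 5,
                dimnames = list(m$scenario$alleles, 0:4))
    g <- balance_types(g)
    st <- step_generation(g, m)
    expect_equal(allele_frequencies(st$gametes), allele_frequencies(g),
                 tolerance = 1e-10)
  }
  # without mating types no balancing is needed at all
  m_nmt <- build_model(8, 0.01, fitness = fitness_spec(0, "concave"),
                       scenario = scenario_no_mating_types("biparental"))
  g <- matrix(runif(2 * 5), 2, 5, dimnames = list(c("U", "B"), 0:4))
  g <- g / sum(g)
  st <- step_generation(g, m_nmt)
  expect_equal(allele_frequencies(st$gametes), allele_frequencies(g),
               tolerance = 1e-10)
})

test_that("the full cycle commutes with haplotype relabelling when neutral and symmetric", {
  m <- neutral_model(n = 8, mu = 0.01, c_h = 0.3)
  set.seed(7)
  g <- matrix(runif(3 * 5), 3, 5,
              dimnames = list(m$scenario$alleles, 0:4))
  g <- balance_types(g)
  a <- step_generation(mirror_counts(g), m)$gametes
  b <- mirror_counts(step_generation(g, m)$gametes)
  expect_equal(unclass(a), unclass(b), tolerance = 1e-12)
})

test_that("gamete mean fitness uses the rescaled fitness function", {
  m <- neutral_model(n = 20, c_h = 0.2)
  g <- point_gametes(m, "U1", 0)
  expect_equal(unname(gamete_mean_fitness(g, m)["U1"]), 1)
  # point mass at p = n/4: gamete-scale minimum, 1 - c_h
  g5 <- point_gametes(m, "B1", 5)
  expect_equal(unname(gamete_mean_fitness(g5, m)["B1"]), 0.8)
  # mirrored gamete distributions have equal mean fitness
  set.seed(3)
  gr <- matrix(runif(3 * 11), 3, 11,
               dimnames = list(m$scenario$alleles, 0:10))
  gr <- gr / sum(gr)
  expect_equal(gamete_mean_fitness(gr, m),
               gamete_mean_fitness(mirror_counts(gr), m))
})
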