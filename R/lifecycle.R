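# Life-cycle stage transforms on population distributions.
#
# A gamete-stage population is a matrix with one row per nuclear allele and
# columns for mutant counts 0..n/2; a diploid-stage population has one row
# per genotype and columns 0..n. Entries are population proportions. All
# stages conserve mass except mating (which conditions on viable pairings)
# and selection (which renormalises by mean fitness).

#' Precompute a model: scenario + kernels for a parameter set
#'
#' Builds and caches every transition kernel the life cycle needs (the
#' uniparental doubling kernel on n/2 units, the mutation kernel, the
#' composed meiosis kernel, the mitotic-division kernel when the scenario
#' uses mitosis) together with the fitness vector, so that iterating
#' generations reduces to small dense matrix products.
#'
#' @param n Even number of segregating mitochondrial units per diploid cell.
#' @param mu Wild-type to mutant mutation rate per unit per generation.
#' @param mu_b Mutant to wild-type rate; defaults to \code{mu} (neutral
#'   convention).
#' @param fitness A [fitness_spec()].
#' @param scenario A scenario object, e.g. [scenario_linked()].
#' @return An object of class \code{"upi_model"}.
#' @export
#' @examples
#' m <- build_model(n = 20, mu = 1e-4, fitness = fitness_spec(0.2, "concave"),
#'                  scenario = scenario_linked())
build_model <- function(n, mu, mu_b = mu, fitness = fitness_spec(),
                        scenario = scenario_linked()) {
  check_even(n)
  stopifnot(inherits(fitness, "fitness_spec"),
            inherits(scenario, "upi_scenario"))
  half <- n / 2L
  ai <- stats::setNames(seq_along(scenario$alleles), scenario$alleles)
  rules <- lapply(scenario$rules, function(r) {
    list(i1 = ai[[r$pair[1]]], i2 = ai[[r$pair[2]]],
         like = r$pair[1] == r$pair[2],
         gi = match(r$genotype, scenario$genotypes),
         components = lapply(r$components, function(cm) {
           if (cm$type == "uniparental") cm$donor_i <- ai[[cm$donor]]
           cm
         }))
  })
  d <- scenario$mitosis$divisions
  model <- list(
    n = n, half = half, mu = mu, mu_b = mu_b,
    fitness = fitness, scenario = scenario, rules = rules,
    Td = doubling_kernel(half),
    MutK = mutation_kernel(n, mu, mu_b),
    w = cell_fitness(0:n, n, fitness),
    wg = cell_fitness(0:half, half, fitness),
    FS = doubling_kernel(n) %*% partition_kernel(n),
    AMt = t(scenario$allele_map),
    MitHalf = NULL, MitFull = NULL)
  if (d > 0) {
    if (scenario$mitosis$timing == "midway") {
      model$MitHalf <- mitosis_kernel_pow(n, d %/% 2L)
    } else {
      model$MitFull <- mitosis_kernel_pow(n, d)
    }
  }
  class(model) <- "upi_model"
  model
}

#' @export
print.upi_model <- function(x, ...) {
  cat("Uniparental-inheritance model\n")
  cat("  n =", x$n, " mu =", x$mu, " mu_b =", x$mu_b, "\n")
  print(x$fitness)
  print(x$scenario)
  invisible(x)
}

# Discrete convolution of two mass vectors (mutant-count pooling in a
# biparental mating). Direct accumulation keeps entries exactly
# nonnegative, unlike FFT-based convolution.
conv_masses <- function(a, b) {
  la <- length(a)
  lb <- length(b)
  z <- numeric(la + lb - 1L)
  for (k in seq_len(la)) {
    ak <- a[k]
    if (ak != 0) {
      idx <- k:(k + lb - 1L)
      z[idx] <- z[idx] + ak * b
    }
  }
  z
}

new_gametes <- function(model, mat) {
  dimnames(mat) <- list(model$scenario$alleles, 0:model$half)
  structure(mat, class = "gamete_distribution")
}

#' Initial gamete population
#'
#' All gametes homoplasmic for the wild-type haplotype, evenly split
#' between the resident biparental mating types (or all carrying the single
#' B allele when there are no mating types).
#'
#' @param model A [build_model()] object.
#' @return Gamete distribution matrix (alleles x counts 0..n/2).
#' @export
init_population <- function(model) {
  sc <- model$scenario
  x <- matrix(0, length(sc$alleles), model$half + 1L)
  resident <- setdiff(grep("^B", sc$alleles, value = TRUE), sc$intro["to"])
  x[match(resident, sc$alleles), 1L] <- 1 / length(resident)
  new_gametes(model, x)
}

#' Random mating stage
#'
#' Forms the post-mating diploid distribution from a gamete distribution.
#' Each viable unordered pair of alleles contributes multinomial pair mass
#' (factor 2 for unlike pairs); biparental transmission pools the two
#' gametes' mutant counts (discrete convolution), uniparental transmission
#' doubles the donor's complement with replacement and ignores the
#' recipient's mitochondrial state, and mixtures are probability-weighted
#' combinations. Matings between identical mating types are inviable; the
#' result is renormalised over viable matings.
#'
#' @param gametes Gamete distribution matrix.
#' @param model A [build_model()] object.
#' @return List with \code{cells} (genotypes x counts 0..n, summing to 1)
#'   and \code{viable_mass} (pre-normalisation total).
#' @export
mate <- function(gametes, model) {
  n <- model$n
  D <- matrix(0, length(model$scenario$genotypes), n + 1L)
  for (r in model$rules) {
    x1 <- gametes[r$i1, ]
    x2 <- gametes[r$i2, ]
    factor2 <- if (r$like) 1 else 2
    contrib <- numeric(n + 1L)
    for (cm in r$components) {
      if (cm$prob == 0) next
      if (cm$type == "biparental") {
        contrib <- contrib + cm$prob * conv_masses(x1, x2)
      } else {
        xd <- gametes[cm$donor_i, ]
        f_other <- sum(if (cm$donor_i == r$i1) x2 else x1)
        contrib <- contrib + cm$prob * f_other *
          as.vector(xd %*% model$Td)
      }
    }
    D[r$gi, ] <- D[r$gi, ] + factor2 * contrib
  }
  viable <- sum(D)
  if (viable <= 0)
    stop("degenerate population: all mass on inviable matings",
         call. = FALSE)
  dimnames(D) <- list(model$scenario$genotypes, 0:n)
  list(cells = D / viable, viable_mass = viable)
}

#' Mutation stage
#'
#' Propagates each genotype's mutant-count distribution through the
#' mutation kernel; mass is conserved.
#'
#' @param cells Diploid distribution matrix (genotypes x counts).
#' @param model A [build_model()] object.
#' @return Diploid distribution matrix after mutation.
#' @export
mutate_cells <- function(cells, model) {
  out <- cells %*% model$MutK
  dimnames(out) <- dimnames(cells)
  out
}

#' Selection stage
#'
#' Weights every cell type by its relative fitness and renormalises the
#' whole population. Mean relative fitness per genotype is computed on the
#' pre-selection distribution.
#'
#' @param cells Diploid distribution matrix (post-mutation).
#' @param model A [build_model()] object.
#' @return List with \code{cells} (normalised post-selection distribution),
#'   \code{mean_fitness} (per genotype, \code{NaN} for absent genotypes)
#'   and \code{sigma} (population mean fitness, the normaliser).
#' @export
select_cells <- function(cells, model) {
  wt <- cells * rep(model$w, each = nrow(cells))
  gmass <- rowSums(cells)
  wbar <- rowSums(wt) / gmass
  sigma <- sum(wt)
  if (sigma <= 0)
    stop("degenerate population: zero total fitness", call. = FALSE)
  list(cells = wt / sigma, mean_fitness = wbar, sigma = sigma)
}

#' Mitotic divisions (vegetative segregation)
#'
#' Applies \code{divisions} rounds of doubling with replacement followed by
#' a without-replacement split of 2n units into daughters of n. Both
#' daughters are kept and share the same marginal law, so the population
#' distribution is the daughter distribution. Homoplasmic states are
#' absorbing; repeated divisions drive heteroplasmic mass into them.
#'
#' @param cells Diploid distribution matrix.
#' @param model A [build_model()] object.
#' @param divisions Number of divisions.
#' @return Diploid distribution matrix.
#' @export
mitose <- function(cells, model, divisions) {
  if (divisions == 0) return(cells)
  out <- cells %*% mitosis_kernel_pow(model$n, divisions)
  dimnames(out) <- dimnames(cells)
  out
}

#' Meiosis stage
#'
#' Doubles the mitochondrial complement with replacement (n to 2n), then
#' draws n/2 units without replacement for each gamete; the two steps are
#' composed into one precomputed kernel. Each genotype's mitochondrial
#' output is distributed over gamete alleles by the scenario's meiotic
#' allele map (half/half for a heterozygote, with recombinant alleles
#' receiving total weight P_r in recombination scenarios).
#'
#' @param cells Diploid distribution matrix (post-selection).
#' @param model A [build_model()] object.
#' @return Gamete distribution matrix for the next generation.
#' @export
meiose <- function(cells, model) {
  new_gametes(model, model$AMt %*% (cells %*% model$FS))
}

#' One full generation of the life cycle
#'
#' Composes mating, mutation, optional mitotic divisions, selection
#' (optionally interleaved with mitosis under midway timing) and meiosis.
#'
#' @param gametes Gamete distribution matrix.
#' @param model A [build_model()] object.
#' @return List with \code{gametes} (next generation), \code{genotype_freq}
#'   (post-mating genotype frequencies), \code{mean_fitness} (per genotype,
#'   pre-selection), \code{sigma} (population mean fitness) and
#'   \code{upi_freq} (frequency of uniparentally transmitting matings).
#' @export
step_generation <- function(gametes, model) {
  m <- mate(gametes, model)
  D <- mutate_cells(m$cells, model)
  if (!is.null(model$MitFull)) D <- D %*% model$MitFull
  if (!is.null(model$MitHalf)) D <- D %*% model$MitHalf
  s <- select_cells(D, model)
  D <- s$cells
  if (!is.null(model$MitHalf)) D <- D %*% model$MitHalf
  gf <- rowSums(m$cells)
  list(gametes = meiose(D, model),
       genotype_freq = gf,
       mean_fitness = s$mean_fitness,
       sigma = s$sigma,
       upi_freq = sum(gf * model$scenario$uni_prob))
}

#' Mean relative fitness of gametes, per allele
#'
#' Gametes are not under selection; this is a reporting quantity. A
#' gamete's fitness is the fitness a diploid cell with the same
#' mitochondrial composition would have, i.e. the cell fitness functions
#' rescaled to capacity n/2 (minimum at n/4 mutants).
#'
#' @param gametes Gamete distribution matrix.
#' @param model A [build_model()] object.
#' @return Named numeric vector of mean fitnesses per allele (\code{NaN}
#'   for absent alleles).
#' @export
gamete_mean_fitness <- function(gametes, model) {
  num <- as.vector(gametes %*% model$wg)
  den <- rowSums(gametes)
  stats::setNames(num / den, model$scenario$alleles)
}

#' Allele frequencies of a gamete distribution
#'
#' @param gametes Gamete distribution matrix.
#' @return Named numeric vector summing to 1.
#' @export
allele_frequencies <- function(gametes) {
  rowSums(gametes)
}
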