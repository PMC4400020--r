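# Orchestration: burn-in to mutation-selection equilibrium, introduction of
# the uniparental allele, iteration to the final equilibrium, summaries.

#' Run configuration
#'
#' Collects every input of a simulation: the model parameters, the
#' scenario, how and at what frequency the uniparental allele is
#' introduced, and the equilibrium criterion. Equilibrium is declared when
#' the largest absolute change of any gamete-stage proportion between
#' consecutive generations falls below \code{eq_tol}.
#'
#' @param n Even number of segregating mitochondrial units per diploid cell.
#' @param mu Wild-type to mutant mutation rate per unit per generation.
#' @param mu_b Mutant to wild-type rate. Defaults follow the direction of
#'   selection on the haplotype: \code{mu} when neutral, \code{mu/100} when
#'   deleterious, \code{100 * mu} when advantageous.
#' @param fitness A [fitness_spec()].
#' @param scenario A scenario object; default [scenario_linked()].
#' @param intro_freq Frequency at which the uniparental allele is
#'   introduced after burn-in (default 1e-2).
#' @param intro_placement \code{"homoplasmic_wild"} converts homoplasmic
#'   wild-type resident gametes; \code{"most_heteroplasmic_above_freq"}
#'   converts the most heteroplasmic resident gamete state whose proportion
#'   exceeds \code{intro_freq}.
#' @param eq_tol Equilibrium tolerance on per-type gamete proportions
#'   (default 1e-12; 1e-13 when \code{mu == 1e-10}).
#' @param max_generations Iteration guard per phase; exceeded runs are
#'   flagged, not errored.
#' @param trace_every Cadence (in generations) at which full gamete
#'   distributions are recorded in the trace (allele/genotype frequencies
#'   are recorded every generation).
#' @return An object of class \code{"run_config"}.
#' @export
#' @examples
#' cfg <- run_config(n = 20, mu = 1e-7, fitness = fitness_spec(0.2, "concave"))
run_config <- function(n = 20, mu = 1e-4, mu_b = NULL,
                       fitness = fitness_spec(),
                       scenario = scenario_linked(),
                       intro_freq = 1e-2,
                       intro_placement = c("homoplasmic_wild",
                                           "most_heteroplasmic_above_freq"),
                       eq_tol = NULL,
                       max_generations = 5e6,
                       trace_every = 10L) {
  intro_placement <- match.arg(intro_placement)
  check_even(n)
  if (is.null(mu_b)) {
    mu_b <- switch(fitness$direction,
                   neutral = mu, deleterious = mu / 100,
                   advantageous = 100 * mu)
  }
  if (mu < 0 || mu > 1 || mu_b < 0 || mu_b > 1)
    stop("mutation rates must be in [0, 1]", call. = FALSE)
  if (intro_freq < 0 || intro_freq >= 0.5)
    stop("'intro_freq' must be in [0, 0.5)", call. = FALSE)
  if (is.null(eq_tol)) eq_tol <- if (mu == 1e-10) 1e-13 else 1e-12
  if (eq_tol <= 0) stop("'eq_tol' must be > 0", call. = FALSE)
  structure(list(n = as.integer(n), mu = mu, mu_b = mu_b,
                 fitness = fitness, scenario = scenario,
                 intro_freq = intro_freq,
                 intro_placement = intro_placement,
                 eq_tol = eq_tol,
                 max_generations = max_generations,
                 trace_every = as.integer(trace_every)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration: n =", x$n, " mu =", x$mu, " mu_b =", x$mu_b,
      "\n  intro_freq =", x$intro_freq, "(", x$intro_placement, ")",
      " eq_tol =", x$eq_tol, "\n")
  print(x$fitness)
  print(x$scenario)
  invisible(x)
}

#' Iterate the life cycle until the gamete distribution is stationary
#'
#' @param gametes Gamete distribution matrix.
#' @param model A [build_model()] object.
#' @param eq_tol Equilibrium tolerance (max absolute per-type change).
#' @param max_generations Iteration guard.
#' @param record Optional function called as \code{record(gen, step)} after
#'   every generation (used internally to collect traces).
#' @param stop_when Optional predicate on the per-generation step result;
#'   iteration also stops (with \code{converged = TRUE}) when it returns
#'   \code{TRUE}.
#' @return List with \code{gametes}, \code{generations} and
#'   \code{converged}.
#' @export
run_to_equilibrium <- function(gametes, model, eq_tol = 1e-12,
                               max_generations = 5e6, record = NULL,
                               stop_when = NULL) {
  gen <- 0L
  repeat {
    if (gen >= max_generations)
      return(list(gametes = gametes, generations = gen, converged = FALSE))
    st <- step_generation(gametes, model)
    gen <- gen + 1L
    if (!is.null(record)) record(gen, st)
    delta <- max(abs(st$gametes - gametes))
    gametes <- st$gametes
    # delta < eq_tol means the distribution had already stopped changing at
    # the previous generation, so that generation is the equilibrium one
    if (delta < eq_tol)
      return(list(gametes = gametes, generations = gen - 1L,
                  converged = TRUE))
    if (!is.null(stop_when) && isTRUE(stop_when(st)))
      return(list(gametes = gametes, generations = gen, converged = TRUE))
  }
}

#' Introduce the uniparental allele into a burnt-in population
#'
#' Moves \code{intro_freq} of the population from the resident biparental
#' allele into the uniparental allele, either from the homoplasmic
#' wild-type state (default) or from the most heteroplasmic resident state
#' whose proportion exceeds \code{intro_freq} (the converted gametes keep
#' their mitochondrial state). Total mass is unchanged.
#'
#' @param gametes Gamete distribution matrix (post burn-in).
#' @param model A [build_model()] object.
#' @param intro_freq Introduction frequency.
#' @param intro_placement See [run_config()].
#' @return Gamete distribution matrix.
#' @export
introduce_upi <- function(gametes, model, intro_freq = 1e-2,
                          intro_placement = "homoplasmic_wild") {
  if (intro_freq == 0) return(gametes)
  sc <- model$scenario
  from <- match(sc$intro["from"], sc$alleles)
  to <- match(sc$intro["to"], sc$alleles)
  if (intro_placement == "homoplasmic_wild") {
    p <- 1L
  } else {
    ok <- which(gametes[from, ] > intro_freq)
    if (!length(ok))
      stop("no ", sc$intro["from"], " state has proportion above ",
           intro_freq, call. = FALSE)
    p <- max(ok)
  }
  if (gametes[from, p] < intro_freq)
    stop("state (", sc$intro["from"], ", count ", p - 1L,
         ") has insufficient mass for introduction", call. = FALSE)
  gametes[from, p] <- gametes[from, p] - intro_freq
  gametes[to, p] <- gametes[to, p] + intro_freq
  gametes
}

#' Frequency of uniparentally transmitting matings
#'
#' The expected fraction of (viable) matings whose mitochondrial
#' transmission is uniparental: post-mating genotype frequencies weighted
#' by each genotype's uniparental-transmission probability (1 for U x B
#' matings, regime-dependent for U x U, 0 for B x B). Defined per
#' transmission event, so mixture regimes count only their uniparental
#' fraction.
#'
#' @param genotype_freq Named post-mating genotype frequencies.
#' @param scenario A scenario object.
#' @return A value in \code{[0, 1]}.
#' @export
upi_frequency <- function(genotype_freq, scenario) {
  sum(genotype_freq * scenario$uni_prob[names(genotype_freq)])
}

#' Simulate the full experiment
#'
#' Initialises a homoplasmic wild-type resident population, runs it to
#' mutation-selection equilibrium (burn-in), introduces the uniparental
#' allele, and iterates to the final equilibrium. Per-generation allele and
#' genotype frequencies, mean fitnesses and the uniparental-transmission
#' frequency are recorded from the introduction onwards (generation 0 is
#' the introduction generation).
#'
#' Once the uniparental genotype has fixed, allele and genotype
#' frequencies are at their equilibrium; the only remaining movement is the
#' neutral equilibration of the haplotype frequency within the fixed
#' genotype, which proceeds at rate \code{mu} and can dominate the wall
#' time at small \code{mu}. \code{stop_when_fixed = TRUE} therefore ends
#' the post-introduction phase as soon as the mass of uniparentally
#' transmitting genotypes exceeds \code{1 - 1e-6}, without waiting for the
#' within-genotype distribution to settle.
#'
#' @param config A [run_config()].
#' @param verbose Print progress messages.
#' @param stop_when_fixed Also stop the post-introduction phase at fixation
#'   of the uniparental genotype(s) (see Details).
#' @return An object of class \code{"upi_run"}: a list with the generation
#'   counters, equilibrium frequencies, fixation flag, trace data frames
#'   and the final gamete distribution.
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(n = 20, mu = 1e-4, fitness = fitness_spec(0.2, "concave"))
#' run <- simulate_upi(cfg, stop_when_fixed = TRUE)
#' run
#' }
simulate_upi <- function(config, verbose = FALSE, stop_when_fixed = FALSE) {
  stopifnot(inherits(config, "run_config"))
  model <- build_model(config$n, config$mu, config$mu_b,
                       config$fitness, config$scenario)
  g0 <- init_population(model)
  burn <- run_to_equilibrium(g0, model, config$eq_tol,
                             config$max_generations)
  if (verbose)
    message("burn-in: ", burn$generations, " generations (converged: ",
            burn$converged, ")")
  gam <- introduce_upi(burn$gametes, model, config$intro_freq,
                       config$intro_placement)

  nA <- length(model$scenario$alleles)
  nG <- length(model$scenario$genotypes)
  cap <- 4096L
  afreq <- matrix(NA_real_, cap, nA)
  gfreq <- matrix(NA_real_, cap, nG)
  wbar <- matrix(NA_real_, cap, nG)
  wgam <- matrix(NA_real_, cap, nA)
  upif <- numeric(cap)
  snaps <- list()
  ngen <- 0L
  rec <- function(gen, st) {
    if (gen > cap) {
      cap <<- cap * 2L
      grow <- function(m) rbind(m, matrix(NA_real_, nrow(m), ncol(m)))
      afreq <<- grow(afreq); gfreq <<- grow(gfreq)
      wbar <<- grow(wbar); wgam <<- grow(wgam)
      upif <<- c(upif, numeric(length(upif)))
    }
    afreq[gen, ] <<- allele_frequencies(st$gametes)
    gfreq[gen, ] <<- st$genotype_freq
    wbar[gen, ] <<- st$mean_fitness
    wgam[gen, ] <<- gamete_mean_fitness(st$gametes, model)
    upif[gen] <<- st$upi_freq
    if (gen %% config$trace_every == 0L)
      snaps[[as.character(gen)]] <<- st$gametes
    ngen <<- gen
  }
  stop_when <- NULL
  if (stop_when_fixed) {
    upi_gi <- which(model$scenario$uni_prob > 0)
    stop_when <- function(st) sum(st$genotype_freq[upi_gi]) > 1 - 1e-6
  }
  fin <- run_to_equilibrium(gam, model, config$eq_tol,
                            config$max_generations, record = rec,
                            stop_when = stop_when)
  if (verbose)
    message("post-introduction: ", fin$generations,
            " generations (converged: ", fin$converged, ")")

  keep <- seq_len(ngen)
  afreq <- afreq[keep, , drop = FALSE]
  gfreq <- gfreq[keep, , drop = FALSE]
  wbar <- wbar[keep, , drop = FALSE]
  wgam <- wgam[keep, , drop = FALSE]
  colnames(afreq) <- colnames(wgam) <- model$scenario$alleles
  colnames(gfreq) <- colnames(wbar) <- model$scenario$genotypes

  final_gfreq <- stats::setNames(gfreq[ngen, ], model$scenario$genotypes)
  upi_geno <- model$scenario$genotypes[model$scenario$uni_prob > 0]
  structure(list(
    config = config,
    generations_burn_in = burn$generations,
    burn_in_converged = burn$converged,
    generations_to_final = fin$generations,
    final_converged = fin$converged,
    allele_freq = afreq,
    genotype_freq = gfreq,
    mean_fitness = wbar,
    gamete_fitness = wgam,
    upi_freq = upif[keep],
    gamete_snapshots = snaps,
    equilibrium_allele_freq = stats::setNames(afreq[ngen, ],
                                              model$scenario$alleles),
    equilibrium_genotype_freq = final_gfreq,
    equilibrium_upi_freq = upif[ngen],
    fixation = sum(final_gfreq[upi_geno]) > 1 - 1e-6,
    gametes = fin$gametes,
    model = model), class = "upi_run")
}

#' @export
print.upi_run <- function(x, ...) {
  cat("Uniparental-inheritance run (", x$config$scenario$name, ")\n",
      sep = "")
  cat("  burn-in:            ", x$generations_burn_in, "generations",
      if (!x$burn_in_converged) "[NOT CONVERGED]", "\n")
  cat("  post-introduction:  ", x$generations_to_final, "generations",
      if (!x$final_converged) "[NOT CONVERGED]", "\n")
  cat("  equilibrium allele frequencies:\n")
  print(round(x$equilibrium_allele_freq, 6))
  cat("  equilibrium genotype frequencies:\n")
  print(round(x$equilibrium_genotype_freq, 6))
  cat("  equilibrium UPI frequency:", round(x$equilibrium_upi_freq, 6),
      "\n")
  cat("  uniparental genotype fixed:", x$fixation, "\n")
  invisible(x)
}
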