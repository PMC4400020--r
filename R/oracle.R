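# Independent validation tools: a finite-population Monte-Carlo simulator
# of the identical life cycle, and exhaustive small-instance enumerations
# that recompute stage distributions without the kernel machinery. Used by
# the test suite to cross-check the deterministic recursion.

#' Sample a finite gamete population from a gamete distribution
#'
#' @param gametes Gamete distribution matrix (alleles x counts).
#' @param N Number of individuals.
#' @param model A [build_model()] object.
#' @return A list with integer vectors \code{allele} (index into the
#'   scenario's allele set) and \code{p} (mutant counts), of length N.
#' @export
mc_sample_population <- function(gametes, N, model) {
  probs <- as.vector(t(gametes))
  states <- sample.int(length(probs), N, replace = TRUE, prob = probs)
  ncol_g <- model$half + 1L
  list(allele = (states - 1L) %/% ncol_g + 1L,
       p = (states - 1L) %% ncol_g)
}

# viability/rule lookup table: matrix alleles x alleles -> rule index or 0
rule_lookup <- function(model) {
  nA <- length(model$scenario$alleles)
  lk <- matrix(0L, nA, nA)
  for (k in seq_along(model$rules)) {
    r <- model$rules[[k]]
    lk[r$i1, r$i2] <- k
    lk[r$i2, r$i1] <- k
  }
  lk
}

#' One stochastic generation of the life cycle
#'
#' Realises the same life cycle as [step_generation()] on N discrete
#' individuals: random union of gametes with rejection of inviable
#' pairings, per-unit mutation draws, fitness-proportional resampling of N
#' survivors, and meiosis by literal with-replacement doubling and
#' without-replacement partition. Used as a simulation oracle for the
#' deterministic recursion; seed the RNG before calling.
#'
#' @param pop A gamete population from [mc_sample_population()].
#' @param model A [build_model()] object.
#' @return A gamete population (same structure, same N).
#' @export
mc_generation <- function(pop, model) {
  N <- length(pop$p)
  n <- model$n
  half <- model$half
  lk <- rule_lookup(model)

  # --- mating: rejection-sample viable pairs (random union conditioned
  # on viability, matching the deterministic renormalisation)
  ridx <- integer(N)
  i1 <- integer(N)
  i2 <- integer(N)
  need <- seq_len(N)
  guard <- 0L
  while (length(need)) {
    guard <- guard + 1L
    if (guard > 1000L)
      stop("population extinct: no viable matings found", call. = FALSE)
    a <- sample.int(N, length(need), replace = TRUE)
    b <- sample.int(N, length(need), replace = TRUE)
    rr <- lk[cbind(pop$allele[a], pop$allele[b])]
    ok <- rr > 0L
    ridx[need[ok]] <- rr[ok]
    i1[need[ok]] <- a[ok]
    i2[need[ok]] <- b[ok]
    need <- need[!ok]
  }

  # --- transmission
  i <- integer(N)
  geno <- integer(N)
  for (k in seq_along(model$rules)) {
    r <- model$rules[[k]]
    sel <- which(ridx == k)
    if (!length(sel)) next
    geno[sel] <- r$gi
    probs <- vapply(r$components, `[[`, numeric(1), "prob")
    comp <- sample.int(length(probs), length(sel), replace = TRUE,
                       prob = probs)
    for (ci in seq_along(r$components)) {
      cm <- r$components[[ci]]
      s2 <- sel[comp == ci]
      if (!length(s2)) next
      if (cm$type == "biparental") {
        i[s2] <- pop$p[i1[s2]] + pop$p[i2[s2]]
      } else {
        # the parent carrying the donor allele donates; in like-allele
        # pairs pick either parent at random (their law is exchangeable)
        d1 <- pop$allele[i1[s2]] == cm$donor_i
        d2 <- pop$allele[i2[s2]] == cm$donor_i
        both <- d1 & d2
        pick1 <- d1 & (!both | stats::runif(length(s2)) < 0.5)
        pd <- ifelse(pick1, pop$p[i1[s2]], pop$p[i2[s2]])
        i[s2] <- pd + stats::rbinom(length(s2), half, pd / half)
      }
    }
  }

  # --- mutation: per-unit flips
  a_new <- stats::rbinom(N, n - i, model$mu)
  b_back <- stats::rbinom(N, i, model$mu_b)
  i <- i + a_new - b_back

  # --- mitosis (if the scenario includes it)
  d <- model$scenario$mitosis$divisions
  timing <- model$scenario$mitosis$timing
  mc_divide <- function(i, times) {
    for (k in seq_len(times)) {
      l <- i + stats::rbinom(N, n, i / n)
      i <- stats::rhyper(N, l, 2L * n - l, n)
    }
    i
  }
  if (d > 0 && timing == "before_selection") i <- mc_divide(i, d)
  if (d > 0 && timing == "midway") i <- mc_divide(i, d %/% 2L)

  # --- selection: fitness-proportional viability resampling
  surv <- sample.int(N, N, replace = TRUE, prob = model$w[i + 1L])
  i <- i[surv]
  geno <- geno[surv]

  if (d > 0 && timing == "midway") i <- mc_divide(i, d %/% 2L)

  # --- meiosis: double with replacement, partition without replacement,
  # then assign a gamete allele from the meiotic allele map
  l <- i + stats::rbinom(N, n, i / n)
  p <- stats::rhyper(N, l, 2L * n - l, half)
  am <- model$scenario$allele_map
  cum <- t(apply(am, 1L, cumsum))
  u <- stats::runif(N)
  allele <- max.col(cum[geno, , drop = FALSE] >= u, ties.method = "first")
  list(allele = allele, p = p)
}

#' Empirical gamete distribution of a Monte-Carlo population
#'
#' @param pop A gamete population.
#' @param model A [build_model()] object.
#' @return A matrix (alleles x counts 0..n/2) of empirical proportions.
#' @export
mc_distribution <- function(pop, model) {
  tab <- matrix(0, length(model$scenario$alleles), model$half + 1L,
                dimnames = list(model$scenario$alleles, 0:model$half))
  cnt <- table(factor(pop$allele, seq_len(nrow(tab))),
               factor(pop$p, 0:model$half))
  tab[] <- as.numeric(cnt) / length(pop$p)
  tab
}

# ---------------------------------------------------------------------------
# Exhaustive enumerations (independent of the kernel code paths). All
# enumerate equally likely elementary outcomes and aggregate, so they share
# no formula with the dbinom/dhyper constructions they check.

#' Exhaustive mutation-stage distribution
#'
#' Enumerates all 2^n per-unit flip patterns of a cell with \code{i0}
#' mutant units: each wild-type unit flips with probability \code{mu}, each
#' mutant unit with probability \code{mu_b}.
#'
#' @param n Number of units (small; intended for n <= 6).
#' @param i0 Source mutant count.
#' @param mu,mu_b Mutation rates.
#' @return Numeric vector of destination probabilities over counts 0..n.
#' @export
enumerate_mutation <- function(n, i0, mu, mu_b) {
  flip_prob <- c(rep(mu_b, i0), rep(mu, n - i0))   # per-unit flip rates
  is_mut <- c(rep(TRUE, i0), rep(FALSE, n - i0))
  out <- numeric(n + 1L)
  for (mask in 0:(2^n - 1L)) {
    flips <- as.logical(bitwAnd(mask, 2^(0:(n - 1L))))
    pr <- prod(ifelse(flips, flip_prob, 1 - flip_prob))
    dest <- sum(is_mut & !flips) + sum(!is_mut & flips)
    out[dest + 1L] <- out[dest + 1L] + pr
  }
  out
}

#' Exhaustive doubling-stage distribution
#'
#' Enumerates all m^m equally likely with-replacement draws of m unit
#' indices from a cell of m units, p of them mutant, and tallies the
#' doubled cell's mutant count.
#'
#' @param m Source capacity (small; m^m sequences are enumerated).
#' @param p Source mutant count.
#' @return Numeric vector of probabilities over counts 0..2m.
#' @export
enumerate_doubling <- function(m, p) {
  draws <- as.matrix(expand.grid(rep(list(seq_len(m)), m)))
  out <- numeric(2L * m + 1L)
  for (k in seq_len(nrow(draws))) {
    dest <- p + sum(draws[k, ] <= p)
    out[dest + 1L] <- out[dest + 1L] + 1
  }
  out / nrow(draws)
}

#' Exhaustive partition-stage distribution
#'
#' Enumerates all subsets of size n/2 of the 2n units of a doubled cell
#' (l of them mutant) and tallies the drawn mutant count.
#'
#' @param n Diploid capacity (small even number).
#' @param l Doubled-cell mutant count, 0..2n.
#' @return Numeric vector of probabilities over counts 0..n/2.
#' @export
enumerate_partition <- function(n, l) {
  half <- n / 2L
  sets <- utils::combn(2L * n, half)
  out <- numeric(half + 1L)
  for (k in seq_len(ncol(sets))) {
    dest <- sum(sets[, k] <= l)
    out[dest + 1L] <- out[dest + 1L] + 1
  }
  out / ncol(sets)
}

#' Exhaustive meiosis distribution (doubling then partition)
#'
#' Composes [enumerate_doubling()] (with-replacement doubling of n units)
#' and [enumerate_partition()] by summing over all intermediate doubled
#' counts, giving the exact gamete mutant-count law for a diploid cell with
#' \code{i} mutants.
#'
#' @param n Diploid capacity (small even number).
#' @param i Diploid mutant count.
#' @return Numeric vector of probabilities over gamete counts 0..n/2.
#' @export
enumerate_meiosis <- function(n, i) {
  dbl <- enumerate_doubling(n, i)
  out <- numeric(n / 2L + 1L)
  for (l in 0:(2L * n)) {
    if (dbl[l + 1L] > 0)
      out <- out + dbl[l + 1L] * enumerate_partition(n, l)
  }
  out
}
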