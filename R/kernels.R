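# Fitness functions and probability kernels over discrete mitochondrial states.
#
# A cell stage is described by the number of mutant segregating units it
# carries: 0..n/2 in gametes, 0..n in diploids, 0..2n after pre-meiotic
# doubling. All kernels are dense row-stochastic matrices; row = source
# mutant count, column = destination mutant count.

#' Fitness specification
#'
#' Bundles the parameters of selection acting on diploid cells: the cost of
#' heteroplasmy \code{c_h} with its shape, and (optionally) a second fitness
#' component tied to the accumulation of the mutant haplotype when that
#' haplotype is deleterious or advantageous rather than neutral.
#'
#' @param c_h Cost of heteroplasmy in \code{[0, 1]}: the maximally
#'   heteroplasmic cell (half mutant, half wild type) has relative fitness
#'   \code{1 - c_h}.
#' @param shape Shape of the heteroplasmy fitness function: one of
#'   \code{"concave"}, \code{"linear"}, \code{"convex"}.
#' @param direction Effect of the mutant haplotype itself: \code{"neutral"}
#'   (default), \code{"deleterious"}, or \code{"advantageous"}.
#' @param s Selection coefficient in \code{[0, 1)} of the non-neutral
#'   haplotype. A cell homoplasmic for the mutant haplotype has fitness
#'   \code{1 - s} when deleterious; a cell homoplasmic for wild type has
#'   fitness \code{1 - s} when advantageous. Ignored when neutral.
#' @param acc_shape Shape of the accumulation fitness component,
#'   \code{"concave"} or \code{"convex"}; ignored when neutral.
#' @return An object of class \code{"fitness_spec"}.
#' @export
#' @examples
#' fitness_spec(c_h = 0.2, shape = "concave")
#' fitness_spec(0.2, "convex", direction = "deleterious", s = 0.01)
fitness_spec <- function(c_h = 0.2, shape = c("concave", "linear", "convex"),
                         direction = c("neutral", "deleterious", "advantageous"),
                         s = 0, acc_shape = c("concave", "convex")) {
  shape <- match.arg(shape)
  direction <- match.arg(direction)
  acc_shape <- match.arg(acc_shape)
  if (!is.numeric(c_h) || length(c_h) != 1L || c_h < 0 || c_h > 1)
    stop("'c_h' must be a single number in [0, 1]", call. = FALSE)
  if (!is.numeric(s) || length(s) != 1L || s < 0 || s >= 1)
    stop("'s' must be a single number in [0, 1)", call. = FALSE)
  structure(list(c_h = c_h, shape = shape, direction = direction,
                 s = s, acc_shape = acc_shape),
            class = "fitness_spec")
}

#' @export
print.fitness_spec <- function(x, ...) {
  cat("Fitness specification\n")
  cat("  heteroplasmy cost c_h =", x$c_h, "(", x$shape, ")\n")
  if (x$direction == "neutral") {
    cat("  mutant haplotype: neutral\n")
  } else {
    cat("  mutant haplotype:", x$direction, "s =", x$s,
        "(", x$acc_shape, ")\n")
  }
  invisible(x)
}

check_count_range <- function(i, n) {
  if (any(i < 0L | i > n))
    stop("mutant count out of range 0..", n, call. = FALSE)
  invisible(TRUE)
}

check_even <- function(n) {
  if (length(n) != 1L || n < 2L || n %% 2L != 0L)
    stop("cell capacity 'n' must be a single even integer >= 2",
         call. = FALSE)
  invisible(TRUE)
}

# fitness functions also serve the gamete scale (capacity n/2, which is odd
# whenever n = 2 mod 4), so they only require a positive capacity
check_capacity <- function(n) {
  if (length(n) != 1L || n < 1L)
    stop("cell capacity 'n' must be a single integer >= 1", call. = FALSE)
  invisible(TRUE)
}

#' Relative fitness under selection against heteroplasmy
#'
#' Piecewise fitness of a cell carrying \code{i} mutant out of \code{n}
#' segregating units, symmetric about \code{n/2}. Homoplasmic cells
#' (\code{i = 0} or \code{i = n}) have fitness 1; the maximally heteroplasmic
#' cell (\code{i = n/2}) has fitness \code{1 - c_h}. With \code{x = i/(n/2)}
#' on the lower arm (mirrored above \code{n/2}), the three shapes are
#' \code{1 - c_h x^2} (concave), \code{1 - c_h x} (linear) and
#' \code{1 - c_h sqrt(x)} (convex).
#'
#' @param i Mutant count (vectorised), \code{0 <= i <= n}.
#' @param n Number of segregating units in the cell. Diploid cells use the
#'   model's even \code{n}; the gamete-rescaled fitness uses \code{n/2},
#'   which may be odd.
#' @param c_h Cost of heteroplasmy in \code{[0, 1]}.
#' @param shape \code{"concave"}, \code{"linear"} or \code{"convex"}.
#' @return Numeric vector of relative fitnesses in \code{[1 - c_h, 1]}.
#' @export
#' @examples
#' heteroplasmy_fitness(0:20, 20, c_h = 0.2, shape = "concave")
heteroplasmy_fitness <- function(i, n, c_h,
                                 shape = c("concave", "linear", "convex")) {
  shape <- match.arg(shape)
  check_capacity(n)
  check_count_range(i, n)
  if (c_h < 0 || c_h > 1)
    stop("'c_h' must be in [0, 1]", call. = FALSE)
  half <- n / 2
  x <- ifelse(i < half, i / half, (n - i) / half)
  switch(shape,
         concave = 1 - c_h * x^2,
         linear  = 1 - c_h * x,
         convex  = 1 - c_h * sqrt(x))
}

#' Relative fitness from accumulation of a non-neutral haplotype
#'
#' Second fitness component used when the mutant haplotype is itself under
#' selection. For a deleterious haplotype, fitness decreases from 1 at
#' \code{i = 0} to \code{1 - s} at \code{i = n} (concave:
#' \code{1 - s (i/n)^2}; convex: \code{1 - s sqrt(i/n)}). For an
#' advantageous haplotype the relation is mirrored: fitness increases from
#' \code{1 - s} at \code{i = 0} to 1 at \code{i = n}. Returns 1 everywhere
#' when the direction is neutral.
#'
#' @param i Mutant count (vectorised).
#' @param n Number of segregating units.
#' @param spec A [fitness_spec()].
#' @return Numeric vector of weights in \code{(0, 1]}.
#' @export
accumulation_fitness <- function(i, n, spec) {
  stopifnot(inherits(spec, "fitness_spec"))
  check_capacity(n)
  check_count_range(i, n)
  if (spec$direction == "neutral") return(rep(1, length(i)))
  x <- if (spec$direction == "deleterious") i / n else 1 - i / n
  switch(spec$acc_shape,
         concave = 1 - spec$s * x^2,
         convex  = 1 - spec$s * sqrt(x))
}

#' Total relative fitness of a diploid cell
#'
#' The product of the heteroplasmy component and, when the mutant haplotype
#' is non-neutral, the accumulation component. The multiplicative
#' composition keeps the anchor values of both components: a cell
#' homoplasmic for the wild type has fitness 1, and a cell homoplasmic for
#' a deleterious mutant has fitness \code{1 - s}.
#'
#' @inheritParams accumulation_fitness
#' @return Numeric vector of relative fitnesses.
#' @export
#' @examples
#' spec <- fitness_spec(0.2, "concave", "deleterious", s = 0.1)
#' cell_fitness(0:20, 20, spec)
cell_fitness <- function(i, n, spec) {
  stopifnot(inherits(spec, "fitness_spec"))
  w <- heteroplasmy_fitness(i, n, spec$c_h, spec$shape)
  if (spec$direction != "neutral")
    w <- w * accumulation_fitness(i, n, spec)
  w
}

#' Doubling kernel (with-replacement resampling)
#'
#' Transition kernel of the doubling step shared by uniparental mating and
#' the first step of meiosis: a cell with \code{m} units samples \code{m}
#' units with replacement from its own complement and appends them, ending
#' with \code{2m} units. A source with \code{p} mutants moves to
#' \code{p + k} where \code{k ~ Binomial(m, p/m)}.
#'
#' @param m Source capacity (number of units before doubling), \code{>= 1}.
#' @return A \code{(m+1) x (2m+1)} row-stochastic matrix; rows indexed by
#'   source counts \code{0..m}, columns by destination counts \code{0..2m}.
#' @export
doubling_kernel <- function(m) {
  if (length(m) != 1L || m < 1L) stop("'m' must be >= 1", call. = FALSE)
  K <- matrix(0, nrow = m + 1L, ncol = 2L * m + 1L)
  for (p in 0:m) {
    K[p + 1L, (p + 0:m) + 1L] <- stats::dbinom(0:m, size = m, prob = p / m)
  }
  K
}

#' Mutation kernel
#'
#' Per-generation mutation of every segregating unit: each of the
#' \code{n - i0} wild-type units mutates with probability \code{mu} and each
#' of the \code{i0} mutant units back-mutates with probability \code{mu_b},
#' independently. The destination count is \code{i0 + a - b} with
#' \code{a ~ Binomial(n - i0, mu)} and \code{b ~ Binomial(i0, mu_b)}, so
#' each row is the convolution of the two binomials and sums to 1 exactly.
#'
#' @param n Number of units in the cell.
#' @param mu Wild-type to mutant rate in \code{[0, 1]}.
#' @param mu_b Mutant to wild-type rate in \code{[0, 1]}.
#' @return An \code{(n+1) x (n+1)} row-stochastic matrix.
#' @export
mutation_kernel <- function(n, mu, mu_b = mu) {
  if (mu < 0 || mu > 1 || mu_b < 0 || mu_b > 1)
    stop("mutation rates must be in [0, 1]", call. = FALSE)
  K <- matrix(0, nrow = n + 1L, ncol = n + 1L)
  for (i0 in 0:n) {
    fwd <- stats::dbinom(0:(n - i0), size = n - i0, prob = mu)
    back <- stats::dbinom(0:i0, size = i0, prob = mu_b)
    # destination i0 + a - b: outer product accumulated along diagonals
    for (a in 0:(n - i0)) {
      dest <- (i0 + a - (0:i0)) + 1L
      K[i0 + 1L, dest] <- K[i0 + 1L, dest] + fwd[a + 1L] * back
    }
  }
  K
}

#' Meiotic partition kernel (without-replacement draw)
#'
#' Second step of meiosis: a doubled cell with \code{2n} units, \code{l} of
#' them mutant, contributes gametes of \code{n/2} units drawn without
#' replacement, so the gamete mutant count is hypergeometric.
#'
#' @param n Diploid capacity (even).
#' @return A \code{(2n+1) x (n/2+1)} row-stochastic matrix; rows indexed by
#'   doubled counts \code{0..2n}, columns by gamete counts \code{0..n/2}.
#' @export
partition_kernel <- function(n) {
  check_even(n)
  half <- n / 2
  K <- matrix(0, nrow = 2L * n + 1L, ncol = half + 1L)
  for (l in 0:(2L * n)) {
    K[l + 1L, ] <- stats::dhyper(0:half, m = l, n = 2L * n - l, k = half)
  }
  K
}

# One mitotic division: double n -> 2n with replacement, then a random
# daughter receives n of the 2n units without replacement. Both daughters
# are retained and have the same marginal law, so the daughter kernel
# represents the population after the division.
mitosis_kernel <- function(n) {
  check_even(n)
  H <- matrix(0, nrow = 2L * n + 1L, ncol = n + 1L)
  for (l in 0:(2L * n)) {
    H[l + 1L, ] <- stats::dhyper(0:n, m = l, n = 2L * n - l, k = n)
  }
  doubling_kernel(n) %*% H
}

# d mitotic divisions as a single precomputed kernel.
mitosis_kernel_pow <- function(n, d) {
  K1 <- mitosis_kernel(n)
  K <- diag(n + 1L)
  for (k in seq_len(d)) K <- K %*% K1
  K
}
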