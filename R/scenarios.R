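# Scenario assembly: which nuclear alleles and diploid genotypes exist,
# which matings are viable, how each mating transmits mitochondria, and how
# meiosis distributes nuclear alleles to gametes.
#
# A mating rule holds an unordered parent-allele pair, the resulting
# genotype, and a list of transmission components, each with a probability
# and either biparental pooling or uniparental doubling from a named donor
# allele. Mixture transmission (leaky or random-donor uniparental
# inheritance) is expressed as several components with probabilities
# summing to 1.

new_rule <- function(pair, genotype, components) {
  probs <- vapply(components, `[[`, numeric(1), "prob")
  stopifnot(abs(sum(probs) - 1) < 1e-12)
  list(pair = pair, genotype = genotype, components = components)
}

bip <- function(prob = 1) list(prob = prob, type = "biparental")
uni <- function(donor, prob = 1) list(prob = prob, type = "uniparental", donor = donor)

uu_components <- function(uu_regime, P_b, donors = c("U1", "U2")) {
  switch(uu_regime,
         uniparental = list(uni(donors[1], 0.5), uni(donors[2], 0.5)),
         biparental  = list(bip(1)),
         mixture     = c(list(bip(P_b)),
                         list(uni(donors[1], (1 - P_b) / 2),
                              uni(donors[2], (1 - P_b) / 2))),
         stop("invalid 'uu_regime': ", uu_regime, call. = FALSE))
}

new_scenario <- function(name, alleles, genotypes, rules, allele_map,
                         intro, params = list(),
                         mitosis = list(divisions = 0L,
                                        timing = "before_selection")) {
  stopifnot(identical(rownames(allele_map), genotypes),
            identical(colnames(allele_map), alleles),
            all(abs(rowSums(allele_map) - 1) < 1e-12))
  uni_prob <- vapply(genotypes, function(g) {
    r <- Filter(function(rl) rl$genotype == g, rules)
    if (!length(r)) return(0)
    sum(vapply(r[[1]]$components, function(cm)
      if (cm$type == "uniparental") cm$prob else 0, numeric(1)))
  }, numeric(1))
  structure(list(name = name, alleles = alleles, genotypes = genotypes,
                 rules = rules, allele_map = allele_map,
                 uni_prob = uni_prob, intro = intro, params = params,
                 mitosis = mitosis),
            class = "upi_scenario")
}

#' @export
print.upi_scenario <- function(x, ...) {
  cat("Scenario:", x$name, "\n")
  cat("  alleles:  ", paste(x$alleles, collapse = ", "), "\n")
  cat("  genotypes:", paste(x$genotypes, collapse = ", "), "\n")
  for (r in x$rules) {
    tr <- vapply(r$components, function(cm) {
      if (cm$type == "biparental") sprintf("biparental (p=%g)", cm$prob)
      else sprintf("uniparental from %s (p=%g)", cm$donor, cm$prob)
    }, character(1))
    cat(sprintf("  %s x %s -> %s: %s\n", r$pair[1], r$pair[2], r$genotype,
                paste(tr, collapse = " + ")))
  }
  if (x$mitosis$divisions > 0)
    cat("  mitosis:", x$mitosis$divisions, "divisions,",
        x$mitosis$timing, "\n")
  invisible(x)
}

two_way_map <- function(genotypes, alleles, splits) {
  am <- matrix(0, length(genotypes), length(alleles),
               dimnames = list(genotypes, alleles))
  for (g in names(splits)) am[g, names(splits[[g]])] <- splits[[g]]
  am
}

#' Linked mating-type and inheritance loci (basic scenario)
#'
#' Three alleles (U1, B1, B2) at a combined mating-type/inheritance locus
#' with no recombination. U1 x B2 matings are uniparental with U1 as donor;
#' B1 x B2 matings are biparental; matings within a mating type (including
#' U1 x B1) are inviable. The uniparental allele is introduced by converting
#' a small fraction of B1 gametes to U1.
#'
#' @return A scenario object consumed by [run_config()].
#' @export
#' @examples
#' scenario_linked()
scenario_linked <- function() {
  alleles <- c("U1", "B1", "B2")
  genotypes <- c("U1B2", "B1B2")
  rules <- list(
    new_rule(c("U1", "B2"), "U1B2", list(uni("U1"))),
    new_rule(c("B1", "B2"), "B1B2", list(bip())))
  am <- two_way_map(genotypes, alleles,
                    list(U1B2 = c(U1 = 0.5, B2 = 0.5),
                         B1B2 = c(B1 = 0.5, B2 = 0.5)))
  new_scenario("linked", alleles, genotypes, rules, am,
               intro = c(from = "B1", to = "U1"))
}

#' Recombination between the mating-type and inheritance loci
#'
#' Four alleles (U1, U2, B1, B2) arise once the inheritance locus can
#' recombine away from its mating-type background; genotypes are U1B2,
#' U2B1, U1U2 and B1B2. U x B matings are uniparental from the U parent,
#' B1 x B2 is biparental, and U1 x U2 transmits according to
#' \code{uu_regime}: \code{"uniparental"} (one U allele dominant; modelled
#' as a 50/50 donor choice, to which the outcome is insensitive),
#' \code{"biparental"} (each U allele enforces transmission of its own
#' mitochondria), or \code{"mixture"} (biparental with probability
#' \code{P_b}, otherwise uniparental from either parent equally). Meiosis
#' of the doubly heterozygous genotypes U1B2 and U2B1 emits recombinant
#' alleles with total probability \code{P_r}.
#'
#' @param P_r Recombination probability between the two loci, in
#'   \code{[0, 0.5]}.
#' @param uu_regime Transmission regime for U1 x U2 matings.
#' @param P_b Probability of biparental transmission in U1 x U2 matings
#'   (mixture regime only).
#' @return A scenario object.
#' @export
scenario_recombination <- function(P_r = 0.5,
                                   uu_regime = c("uniparental", "biparental",
                                                 "mixture"),
                                   P_b = 0) {
  uu_regime <- match.arg(uu_regime)
  if (P_r < 0 || P_r > 0.5)
    stop("'P_r' must be in [0, 0.5]", call. = FALSE)
  if (P_b < 0 || P_b > 1) stop("'P_b' must be in [0, 1]", call. = FALSE)
  alleles <- c("U1", "U2", "B1", "B2")
  genotypes <- c("U1B2", "U2B1", "U1U2", "B1B2")
  rules <- list(
    new_rule(c("U1", "B2"), "U1B2", list(uni("U1"))),
    new_rule(c("U2", "B1"), "U2B1", list(uni("U2"))),
    new_rule(c("U1", "U2"), "U1U2", uu_components(uu_regime, P_b)),
    new_rule(c("B1", "B2"), "B1B2", list(bip())))
  h <- (1 - P_r) / 2
  r <- P_r / 2
  am <- two_way_map(genotypes, alleles, list(
    U1B2 = c(U1 = h, B2 = h, U2 = r, B1 = r),
    U2B1 = c(U2 = h, B1 = h, U1 = r, B2 = r),
    U1U2 = c(U1 = 0.5, U2 = 0.5),
    B1B2 = c(B1 = 0.5, B2 = 0.5)))
  new_scenario("recombination", alleles, genotypes, rules, am,
               intro = c(from = "B1", to = "U1"),
               params = list(P_r = P_r, uu_regime = uu_regime, P_b = P_b))
}

#' Complete absence of mating types
#'
#' Two alleles (U, B) and universal gamete compatibility: genotypes UU, UB
#' and BB, all matings viable. U x B is uniparental from the U parent,
#' B x B biparental, U x U per \code{uu_regime} as in
#' [scenario_recombination()]. Random union of gametes uses multinomial
#' pair probabilities (a factor 2 for unlike pairs, none for like pairs).
#'
#' @inheritParams scenario_recombination
#' @return A scenario object.
#' @export
scenario_no_mating_types <- function(uu_regime = c("uniparental",
                                                   "biparental", "mixture"),
                                     P_b = 0) {
  uu_regime <- match.arg(uu_regime)
  if (P_b < 0 || P_b > 1) stop("'P_b' must be in [0, 1]", call. = FALSE)
  alleles <- c("U", "B")
  genotypes <- c("UU", "UB", "BB")
  rules <- list(
    new_rule(c("U", "U"), "UU", uu_components(uu_regime, P_b,
                                              donors = c("U", "U"))),
    new_rule(c("U", "B"), "UB", list(uni("U"))),
    new_rule(c("B", "B"), "BB", list(bip())))
  am <- two_way_map(genotypes, alleles, list(
    UU = c(U = 1), UB = c(U = 0.5, B = 0.5), BB = c(B = 1)))
  new_scenario("no_mating_types", alleles, genotypes, rules, am,
               intro = c(from = "B", to = "U"),
               params = list(uu_regime = uu_regime, P_b = P_b))
}

#' Vegetative segregation: mitotic divisions within the diploid phase
#'
#' The linked scenario extended with \code{divisions} mitotic divisions per
#' generation, each doubling the mitochondrial complement with replacement
#' and partitioning it without replacement into daughters. With
#' \code{timing = "before_selection"} all divisions precede selection
#' (segregation resolves heteroplasmy before selection can see it); with
#' \code{timing = "midway"} half the divisions happen before selection and
#' half after (requires an even \code{divisions}).
#'
#' @param divisions Number of mitotic divisions per generation, \code{>= 0}.
#' @param timing \code{"before_selection"} or \code{"midway"}.
#' @return A scenario object.
#' @export
scenario_mitosis <- function(divisions,
                             timing = c("before_selection", "midway")) {
  timing <- match.arg(timing)
  if (divisions < 0) stop("'divisions' must be >= 0", call. = FALSE)
  if (timing == "midway" && divisions %% 2L != 0L)
    stop("'midway' timing requires an even number of divisions",
         call. = FALSE)
  sc <- scenario_linked()
  sc$name <- "mitosis"
  sc$mitosis <- list(divisions = as.integer(divisions), timing = timing)
  sc$params <- list(divisions = as.integer(divisions), timing = timing)
  sc
}

#' Leaky uniparental inheritance (slime-mold style, linked loci)
#'
#' The linked scenario with imperfect mitochondrial destruction: U1 x B2
#' matings are biparental with probability \code{P_b} and uniparental from
#' U1 otherwise, as in *Physarum polycephalum* where the nuclease-based
#' elimination of one lineage occasionally fails.
#'
#' @param P_b Probability that a U1 x B2 mating transmits biparentally.
#' @return A scenario object.
#' @export
scenario_physarum <- function(P_b) {
  if (P_b < 0 || P_b > 1) stop("'P_b' must be in [0, 1]", call. = FALSE)
  sc <- scenario_linked()
  sc$name <- "physarum"
  comps <- if (P_b == 0) list(uni("U1")) else
    if (P_b == 1) list(bip()) else list(bip(P_b), uni("U1", 1 - P_b))
  sc$rules[[1]] <- new_rule(c("U1", "B2"), "U1B2", comps)
  sc$uni_prob["U1B2"] <- 1 - P_b
  sc$params <- list(P_b = P_b)
  sc
}

#' Random-donor uniparental inheritance (recombining loci)
#'
#' The recombination scenario where U1 x U2 matings inherit mitochondria
#' from U1 with probability \code{P_U1}, from U2 with probability
#' \code{P_U2}, and from both parents with probability \code{P_b}
#' (\code{P_U1 + P_U2 + P_b = 1}), as in *Didymium iridis* and
#' *Chlamydomonas reinhardtii*. The equilibrium depends only on \code{P_b},
#' not on the donor split.
#'
#' @param P_U1,P_U2 Probabilities of uniparental inheritance from each
#'   parent in U1 x U2 matings.
#' @param P_b Probability of biparental inheritance in U1 x U2 matings.
#' @param P_r Recombination probability between the loci.
#' @return A scenario object.
#' @export
scenario_didymium <- function(P_U1, P_U2, P_b, P_r = 0.5) {
  if (abs(P_U1 + P_U2 + P_b - 1) > 1e-12)
    stop("'P_U1', 'P_U2' and 'P_b' must sum to 1", call. = FALSE)
  if (min(P_U1, P_U2, P_b) < 0)
    stop("probabilities must be nonnegative", call. = FALSE)
  sc <- scenario_recombination(P_r = P_r, uu_regime = "biparental")
  sc$name <- "didymium"
  comps <- list()
  if (P_U1 > 0) comps <- c(comps, list(uni("U1", P_U1)))
  if (P_U2 > 0) comps <- c(comps, list(uni("U2", P_U2)))
  if (P_b > 0) comps <- c(comps, list(bip(P_b)))
  sc$rules[[3]] <- new_rule(c("U1", "U2"), "U1U2", comps)
  sc$uni_prob["U1U2"] <- 1 - P_b
  sc$params <- list(P_U1 = P_U1, P_U2 = P_U2, P_b = P_b, P_r = P_r)
  sc
}
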