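---
title: "Selection against heteroplasmy and the evolution of uniparental inheritance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection against heteroplasmy and the evolution of uniparental inheritance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upievol)
```

## The question

Most isogamous eukaryotes inherit mitochondria (and chloroplasts) from only
one parent, even though their gametes are equal in size and both carry
organelles. `upievol` implements a deterministic population-genetic model
of one explanation: cells whose mitochondria are a mixture of two
haplotypes (heteroplasmic cells) are less fit than cells carrying a single
haplotype, and a nuclear allele that enforces uniparental transmission
keeps its lineage homoplasmic and therefore spreads.

## The model

The organism is a single-celled diploid with an idealised sexual life
cycle. Diploid cells carry `n` segregating mitochondrial units (mtDNA
molecules, nucleoids or whole organelles — whichever unit is sampled
independently at transmission); gametes carry `n/2`. A unit is either wild
type or mutant, so a diploid cell's mitochondrial state is its mutant
count `i` in `0..n`, and a gamete's is `p` in `0..n/2`. The population is
effectively infinite: the state of the system is the probability
distribution over (nuclear genotype, mutant count), and every generation
is an exact linear-algebraic update of that distribution — there is no
sampling noise anywhere in the main model.

One generation composes four stages:

1. **Random mating.** Gametes fuse with a compatible partner (opposite
   mating type, or anyone in the no-mating-types scenario). Unordered
   pairs receive multinomial mass (a factor 2 for unlike allele pairs);
   incompatible pairings are lethal and the pool is renormalised.
   Biparental transmission pools the two parents' mutant counts (a
   discrete convolution). Uniparental transmission discards the
   recipient's mitochondria and restores the donor's complement from
   `n/2` to `n` by sampling `n/2` units *with replacement* from the
   donor's own `n/2` — a binomial doubling kernel.
2. **Mutation.** Every unit mutates independently: wild type to mutant
   with probability `mu`, back with `mu_b`. The transition from count
   `i0` is `i0 + a - b` with `a ~ Binomial(n - i0, mu)` and
   `b ~ Binomial(i0, mu_b)`, so each kernel row is an exact convolution
   of two binomials.
3. **Selection.** A cell with `i` mutants has relative fitness `w(i)`;
   the population is reweighted and renormalised by its mean fitness.
4. **Meiosis.** The cell doubles its complement with replacement
   (`n` to `2n`, binomial) and then each gamete draws `n/2` units
   *without replacement* (hypergeometric). Nuclear alleles segregate
   independently of mitochondria, half-and-half for a heterozygote.

### Fitness

Selection against heteroplasmy is symmetric in the two haplotypes:
`w(0) = w(n) = 1` and the fully mixed cell has `w(n/2) = 1 - c_h`, where
`c_h` in `[0, 1]` is the *cost of heteroplasmy*. With `x = i/(n/2)` on
the lower arm (mirrored above `n/2`) the three implemented shapes are

* concave: `w = 1 - c_h * x^2` (weak selection at low heteroplasmy),
* linear: `w = 1 - c_h * x`,
* convex: `w = 1 - c_h * sqrt(x)` (steep loss at low heteroplasmy).

The convex form deserves a note: the source rendering of this function is
typographically ambiguous, and the square root is the minimal shape that
is steep at low heteroplasmy and clearly distinct from the linear form,
which is what the shape comparison requires. Changing the exponent does
not alter any qualitative result in the package's test suite.

When the mutant haplotype is itself non-neutral a second fitness component
applies: deleterious, decreasing from 1 at `i = 0` to `1 - s_d` at
`i = n`; advantageous, increasing from `1 - s_a` to 1 (each with a concave
or convex shape). The two components combine multiplicatively. The
composition rule is a design choice — the source material states only that
two fitness functions act together — and multiplication is the only simple
rule that preserves both anchor values (1 for a wild-type homoplasmic
cell, `1 - s_d` for a mutant homoplasmic cell). By convention `mu_b = mu`
when neutral, `mu/100` when deleterious and `100 mu` when advantageous.

### Scenarios

Scenario objects assemble the allele set, genotype set, mating rules and
meiotic allele maps:

* `scenario_linked()` — mating-type and inheritance loci fully linked:
  alleles U1, B1, B2; genotypes U1B2 (uniparental) and B1B2 (biparental).
  B2 mates with everyone of type 1; U1 x B1 is a same-type pairing and
  lethal. The B2 frequency is pinned at exactly 0.5 by this structure.
* `scenario_recombination(P_r, uu_regime, P_b)` — the inheritance locus
  recombines away from its mating type: four alleles, four genotypes,
  U1 x U2 matings possible and governed by `uu_regime` (uniparental
  50/50-donor, biparental, or a `P_b` mixture). Recombination acts at
  meiosis of the doubly heterozygous genotypes only, emitting recombinant
  alleles with total probability `P_r`; the inheritance-homozygous
  genotypes U1U2 and B1B2 are unaffected. This is the minimal mechanism
  consistent with the scenario's description, and it reproduces the
  published threshold behaviour (effectively linked below `P_r ~ 1e-5`).
* `scenario_no_mating_types(uu_regime, P_b)` — two alleles U and B, all
  pairings viable, multinomial pair mass without the factor 2 for like
  pairs. At its symmetric equilibrium this model coincides exactly with
  the recombination model under the aggregation U = U1 + U2, B = B1 + B2,
  which the package verifies.
* `scenario_mitosis(divisions, timing)` — vegetative segregation: each
  generation inserts `divisions` mitotic divisions (binomial doubling to
  `2n`, hypergeometric split back to `n`; both daughters are kept and
  share that marginal law). `timing = "before_selection"` applies all
  divisions before selection; `"midway"` applies half, selection, then
  half.
* `scenario_physarum(P_b)` — leaky uniparental inheritance on the linked
  background: U1 x B2 matings are biparental with probability `P_b`.
* `scenario_didymium(P_U1, P_U2, P_b)` — random-donor uniparental
  inheritance with recombining loci: U1 x U2 matings transmit from U1,
  from U2, or biparentally (`P_U1 + P_U2 + P_b = 1`). The equilibrium
  depends only on `P_b`, which the test suite verifies by comparing
  different donor splits.

### The experiment a run performs

`simulate_upi()` reproduces the standard experiment: initialise all
gametes homoplasmic wild type, evenly split between the resident
biparental mating types; iterate to mutation–selection equilibrium
(burn-in); convert a fraction `intro_freq = 0.01` of resident gametes to
the uniparental allele (optionally into the most heteroplasmic resident
state instead of the homoplasmic one); iterate to the final equilibrium.
Equilibrium is declared when no gamete-stage proportion changes by more
than `eq_tol = 1e-12` between consecutive generations (`1e-13` at
`mu = 1e-10`, where the dynamics are correspondingly slower). Generations
are counted from the introduction; the burn-in length is reported
separately. The *uniparental-inheritance frequency* is defined per
transmission event: post-mating genotype frequencies weighted by each
genotype's probability of having transmitted uniparentally (this
resolves an ambiguity between two published accountings, and matches the
tabulated formula `P(U1B2) + P(U2B1) + P(U1U2)(1 - P_b)`).

```{r example}
cfg <- run_config(n = 8, mu = 1e-3, fitness = fitness_spec(0.2, "concave"),
                  scenario = scenario_linked())
run <- simulate_upi(cfg, stop_when_fixed = TRUE)
run
```

## Numerical design choices

**Kernels are precomputed.** For a given `(n, mu, mu_b, scenario)` every
transition kernel — the uniparental doubling kernel, the mutation kernel,
the composed meiosis kernel (doubling times partition), and the
`divisions`-fold mitosis kernel — is built once in `build_model()`; a
generation is then a handful of dense matrix products on state vectors of
length `n + 1`. All probabilities are in double precision; convolutions
are accumulated directly (not via FFT) so that entries are exactly
nonnegative and kernel rows sum to 1 to within `1e-12` at any `n` up to
200 and any rates in `[0, 1]`.

**Stopping at fixation.** Once the uniparentally transmitting genotypes
exceed mass `1 - 1e-6`, allele and genotype frequencies are at their
equilibrium values; the only remaining motion is the *neutral*
equilibration of the haplotype frequency inside the fixed genotype, which
proceeds at rate `mu` and can dominate wall time by orders of magnitude
(about `1e8` generations at `mu = 1e-7`) without changing anything the
run reports. `simulate_upi(stop_when_fixed = TRUE)` therefore ends
fixation-type runs at that point; polymorphic equilibria are always run
to the full `1e-12` criterion. A related subtlety: when U x U matings are
themselves uniparental (dominant-U regimes), a rare B allele rides along
almost neutrally through uniparental U x B matings and its last trace
decays only algebraically, so "fixation of uniparental transmission" is
the meaningful endpoint there, not the disappearance of B.

**Mitosis and the stability of biparental inheritance.** The mitosis
kernel's heteroplasmy decay per division is governed by its subdominant
eigenvalue (0.80 at `n = 4`, larger for larger `n`); one division leaves
about half of fully heteroplasmic cells heteroplasmic, matching the
biology the scenario emulates, and 20 divisions leave about 1.5%.
Biparental inheritance is stable only when segregation is *complete to
within the equilibrium tolerance* before selection acts — any residual
heteroplasmy difference, however small, gives the uniparental allele a
compounding advantage in an infinite population. At `n = 4` completeness
requires roughly 90 divisions or more; the package's reference
configuration for the stable-biparental regime (`mitosis_stable_bpi`)
uses 100 divisions, under which the uniparental genotype stays exactly at
its post-introduction frequency of 0.02. With fewer divisions, or with
selection applied midway through them, the uniparental allele spreads,
only more slowly — both published behaviours.

**Ordering of mitosis.** The source life cycle states only that mitosis
precedes selection; this package applies it after mutation
(mating, mutation, mitosis, selection, meiosis), so that the divisions
segregate the generation's fresh mutations as well. The midway timing
splits the divisions around selection.

## Validation strategy

The test suite validates the recursion against machinery that shares no
code with it:

* *Exhaustive enumeration* at small `n`: mutation by enumerating all
  `2^n` per-unit flip patterns, doubling by enumerating all `m^m`
  with-replacement draws, partition by enumerating all subsets — compared
  to the kernels at `1e-12`.
* *A finite-population Monte-Carlo simulator* (`mc_generation()`) that
  realises the identical life cycle on `N = 1e5` discrete individuals:
  one-generation state distributions are compared cell-by-cell and
  50-generation allele trajectories are compared under CLT envelopes.
  Individuals within a generation are correlated (shared pairing pool,
  selection resampling), so the envelopes carry an overdispersion factor
  of 3 relative to naive multinomial sampling.
* *Structural invariants*: kernel row-stochasticity; mass conservation at
  every stage except mating and selection (which renormalise); exact
  invariance of the B2 frequency at 0.5 in linked scenarios; symmetry of
  every operation under relabelling the two haplotypes when `mu = mu_b`
  and fitness is neutral; mean-fraction preservation of the doubling and
  partition kernels; and the equilibrium identities of the scenario
  layer (no-mating-types equals recombination at matched parameters;
  didymium equilibria depend only on `P_b`; leaky-uniparental equilibria
  have biparental frequency exactly `P_b`).

The deterministic runs in the tests use moderate state spaces (`n` of
8–20) and mutation rates of `1e-3`–`1e-7`; these reproduce every
qualitative regime of the model. What the synthetic setting does not
emulate is real biology: finite population size (drift can easily lose a
rare uniparental mutation that deterministic dynamics would fix),
more than two mitochondrial haplotypes, paternal leakage varying between
matings, or any empirical map from heteroplasmy level to fitness beyond
the three stylised shapes. Passing tests show the recursion is computed
correctly and reproduces the model's published behaviour, not that the
model describes any particular organism.

## Known limitations

* Equilibria reached through nearly neutral tails (dominant-U regimes,
  post-fixation haplotype equilibration) are reported at well-defined
  stopping points rather than at unattainable exact stationarity; the
  convergence flags in `RunSummary` make the distinction explicit.
* One published interior equilibrium value (the no-mating-types
  polymorphic equilibrium under concave fitness) is reproduced to about
  6% relative accuracy but not exactly; the package's value is internally
  consistent across the two scenario constructions that must agree there,
  and the residual difference likely traces to an unpublished detail of
  that scenario's original implementation.
* Three-haplotype extensions, gamete-stage selection, overlapping
  generations and analytic maximisation of the uniparental equilibrium
  are out of scope; sweeps over `P_b` or allele frequencies can be done
  numerically with `simulate_upi()`.
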