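Package: upievol
Title: Deterministic Models for the Evolution of Uniparental Organelle
    Inheritance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact propagation of cell-type probability distributions
    through an isogamous life cycle (random mating, mitochondrial
    mutation, selection against heteroplasmy, meiosis) in an effectively
    infinite population. Tracks the spread of a nuclear allele that
    enforces uniparental inheritance of mitochondria against a resident
    biparental allele, using binomial and hypergeometric transition
    kernels over discrete mitochondrial states. Includes scenario
    variants (recombination between mating-type and inheritance loci,
    absence of mating types, non-neutral mitochondrial haplotypes,
    mitotic vegetative segregation, leaky and random-donor uniparental
    inheritance), a finite-population Monte-Carlo cross-check, and a
    command-line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
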