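Package: disswarm
Title: Divergence-Island SNP Classification and Swarm Association Analysis
    for Anopheles Hybrid Zones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing hybridization between the sibling malaria
    vectors Anopheles coluzzii and Anopheles gambiae s.s. using panels of
    divergence-island SNPs (DIS) fixed for alternative alleles in the
    pericentromeric islands of speciation on chromosomes X, 2L and 3L.
    Classifies individuals into non-hybrid, F1 and backcrossed (F1+n)
    categories with sex-aware hemizygosity rules, assigns species by an
    allele majority rule, types mating swarms as monospecific or mixed,
    measures the association between island genotypes and swarm type with
    likelihood-ratio G-tests, Fisher-Irwin exact tests, N-1 chi-square
    tests and logistic regressions with per-term likelihood-ratio tests,
    tracks kdr insecticide-resistance genotype frequencies and the
    recovery of species-specific 2L islands carrying the resistant
    allele, and provides a forward population simulator of the two-species
    system with island-specific recombination suppression, kdr selection
    and X-island-driven swarm assembly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
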