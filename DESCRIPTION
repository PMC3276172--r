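Package: pombepop
Title: Population Genetics and Growth Phenomics of Fission Yeast Natural Isolates
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale pipeline for multi-locus sequence and phenotype
    analysis of haploid yeast strain collections. Reads per-locus multiple
    sequence alignments, applies indel and repeat-region site filters,
    collapses strains into compound haplotypes, and computes per-locus
    nucleotide diversity (pi), Watterson's theta, Tajima's D and the derived
    effective population size. Estimates pairwise F_st between geographic
    populations from haplotype sequences, linkage-disequilibrium statistics
    (D, D', r, chi-squared) for parsimony-informative SNPs, and the
    four-gamete test with the minimum-recombination bound. Extracts lag,
    doubling time and proliferation efficiency from microcultivation growth
    curves, computes a log-scale relative-fitness score against a reference
    strain, and analyses strain-by-trait profiles by average-linkage
    hierarchical clustering, within- versus between-group similarity tests,
    atypicality ranking and FDR-controlled per-trait deviation calls.
    Includes a synthetic-data module (neutral and structured coalescent
    simulator under infinite sites, three-phase growth curves, planted-group
    trait matrices, and a synthetic reconstruction of the published 84-strain
    collection) so that every stage runs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
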