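Package: bombusgen
Title: Microsatellite Conservation Genetics of Bumble Bees Along Urban Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for microsatellite conservation genetics of
    haplodiploid social insects sampled along an environmental (urban-rural)
    gradient. Provides GenePop and tabular genotype input/output with
    per-individual metadata, genotyping quality control (missingness and
    null-allele filters, Monte-Carlo exact Hardy-Weinberg and linkage
    disequilibrium tests with deterministic pruning), full-sib colony
    reconstruction under haplodiploidy with genotyping error, effective
    colony number via the Crozier model, multilocus Weir-Cockerham F-statistics
    with bootstrap confidence intervals, rarefaction-standardized allelic
    richness, diploid-male detection from multilocus heterozygosity,
    drift-based power simulation for differentiation tests, and two-way
    fixed-effects body-size analysis with least-squares-means contrasts.
    Includes a haplodiploid colony genotype simulator with known truth
    (single-locus complementary sex determination, null alleles, mistyping,
    genotyping failure, colony-structured body size) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    car,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
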