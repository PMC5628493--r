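Package: autozyg
Title: Autozygosity Mapping and Candidate-Variant Prioritization for
    Recessive Traits in Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps recessive Mendelian trait loci from SNP-array genotypes of
    small pedigrees by sliding-window autozygosity scanning, and prioritizes
    candidate causal variants within mapped regions by private-allele
    filtering and built-in coding-consequence annotation. Includes a
    pedigree gene-dropping simulator (Haldane meiosis) that generates
    array-style genotype matrices and WGS-like variant tables with seeded
    recessive causal alleles, marker quality-control filters (call rate,
    Mendelian conflicts, map position), protein-alignment conservation
    scoring, and assay-level verification utilities (in-silico PCR-RFLP
    digestion, recessive genotype-phenotype concordance, composite
    linkage-disequilibrium r-squared, physical-to-genetic distance
    arithmetic), plus a single-command pipeline orchestrator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
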