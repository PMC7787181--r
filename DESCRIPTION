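Package: chromarch
Title: Chromosome Architecture Analyses for Avian-Style Sex Chromosomes
Version: 0.1.0
Authors@R: person("chromarch", "developers", role = c("aut", "cre"),
    email = "chromarch@example.org")
Description: A tested pipeline for coverage-based sex-chromosome
    classification, pseudoautosomal-region boundary detection,
    evolutionary-strata demarcation from windowed Z/W divergence, Hi-C
    matrix balancing, insulation-score TAD boundary calling and A/B
    compartment assignment, synteny-chain inversion detection with
    outgroup polarization and breakpoint-boundary enrichment statistics,
    and repeat/palindrome annotation (centromeric monomer arrays,
    terminal and interstitial telomeric repeats, inverted-repeat
    palindromes).  Every analysis stage is exercised on synthetic
    genomes with planted, recorded truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
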