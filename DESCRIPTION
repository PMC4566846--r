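Package: magicpop
Title: Simulation, Haplotype Reconstruction and QTL Mapping for Multi-Parent
    (MAGIC) Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for multi-parent advanced generation intercross (MAGIC)
    populations of inbred founders, modelled on an eight-founder maize design.
    Forward-simulates the funnel breeding scheme (half-diallel, pooled four-way
    crosses, eight-way hybrids, single seed descent) to produce recombinant
    inbred line genomes with known founder mosaics; reconstructs founder
    mosaics from SNP-array genotype calls with a hidden Markov model fitted by
    expectation-maximization; performs multi-founder linkage and association
    QTL mapping with a kinship-adjusted mixed model, leave-one-chromosome-out
    kinship, permutation significance thresholds and -2 LOD support intervals;
    runs a geometric-effect-series phenotype simulation for power and false
    discovery rate estimation; and computes population diagnostics
    (minor allele frequency, heterozygosity, linkage disequilibrium decay,
    local LD profiles and LD pruning) used to characterise such populations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools, jsonlite
Suggests: testthat (>= 3.0.0), vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
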