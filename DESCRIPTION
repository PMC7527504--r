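Package: slocuspop
Title: Molecular Evolution and Population Genetics of S-Locus Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Codon-aware diversity and divergence statistics
    (Nei-Gojobori synonymous/non-synonymous site counting with
    Jukes-Cantor correction), neutrality tests (Tajima's D, Fu and Li's
    D* and F*, the McDonald-Kreitman test), Poisson-corrected protein
    distances with UPGMA and bootstrap, minimum-spanning and
    median-joining haplotype networks with rho-based dating, and
    microsatellite diversity plus composite linkage-disequilibrium
    scanning for diploid unphased genotypes.  Includes a coalescent
    simulator with a tunable non-synonymous/synonymous rate ratio and an
    SSR genotype simulator for validating every statistic against its
    sampling null.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    igraph,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
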