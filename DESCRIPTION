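Package: ldphase
Title: Linkage Disequilibrium Decay and Persistence of Gametic Phase Across
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation of pairwise linkage disequilibrium (signed r and r
    squared) from phased haplotype panels, distance-binned LD decay curves,
    marker-panel thinning summaries, and persistence of gametic phase between
    populations measured as the within-distance-class correlation of signed r.
    Includes a quality-control cascade for sire/dam/offspring trio genotypes
    (Mendelian masking, missingness, call rate, minor allele frequency, exact
    Hardy-Weinberg test), estimation of time since population divergence from
    the decay of phase correlation with recombination distance, and a
    Wright-Fisher forward simulator that generates phased multi-population
    panels and trios with tunable ancestral LD so the whole pipeline is
    testable without external genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
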