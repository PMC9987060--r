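Package: sweepscan
Title: Selective-Sweep Scans, Diversity Statistics and LD Decay for
    Structured Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sliding-window selective-sweep detection for resequenced
    structured populations: Weir-Cockerham F_ST and nucleotide-diversity
    ln-ratio scans against a reference population with top-quantile
    intersection, region merging and gene mapping; per-population
    diversity reports (Ho, He, PIC); pairwise F_ST matrices; linkage
    disequilibrium decay from genotype correlations; one-way ANOVA and
    pairwise comparisons from printed summary statistics; and a
    Balding-Nichols synthetic-population generator with planted sweeps
    and known truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
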