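Package: phaxkit
Title: Non-Recombining Haplotype Blocks: Detection, Diversity and Dating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying and analysing historically non-recombining
    haplotype blocks (PHAXs) from phased haploid SNP data, as used for the
    male X chromosome. Detects blocks by linkage-disequilibrium (|D'|) and
    four-gamete criteria with ancestral-haplotype inclusion, applies genomic
    candidate filters (genes, recombination hotspots, segmental duplications,
    outgroup orthology), computes haploid diversity and neutrality statistics
    (haplotype and nucleotide diversity, Tajima's D, Fu's Fs, Fu and Li's D)
    with coalescent-simulation significance, AMOVA-based phi-st
    differentiation with permutation tests, builds Bandelt median-joining
    haplotype networks, and dates haplotype clusters with the rho statistic
    and its Saillard standard error. Includes a Kingman coalescent simulator
    (constant size, piecewise expansion, population splits) with
    infinite-sites mutation so every analysis can be exercised against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    GenomicRanges,
    igraph,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
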