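Package: relictpop
Title: Conservation Genomics of Relict Plant Populations: Diversity,
    Inbreeding, Genetic Load, and Climate-Driven Genetic Offsets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for desk-scale conservation-genomics
    analyses of small, fragmented plant populations. Provides a structured
    coalescent simulator for multi-lineage demographies with bottlenecks and
    migration; VCF hard/soft filtering cascades; windowed nucleotide
    diversity, Hudson's FST and Tajima's D; PLINK-style runs-of-homozygosity
    detection and F_ROH; derived-allele polarization, codon-level effect
    classification, Grantham scoring and genetic-load ratios; 0-fold/4-fold
    degeneracy and pi0/pi4; genotype-environment association via
    latent-factor regression and redundancy analysis; and generalized
    dissimilarity modelling with local, forward and reverse genetic offsets,
    migration distances and RGB vulnerability summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vegan,
    vcfR,
    Biostrings,
    IRanges,
    geosphere,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
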