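Package: popsaturate
Title: Population Diversity, Ploidy and Saturation Analysis for Resequencing Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream population-genomics analysis for large multi-sample
    resequencing panels of microbial eukaryotes such as Saccharomyces
    cerevisiae. Reads and filters multi-sample VCF data (depth, genotype
    quality, missingness and exact excess-heterozygosity tests), classifies
    sample zygosity and infers ploidy (1n-4n) from alternate-allele read
    fractions with fixed-mean Gaussian mixture criteria, summarises
    depth-based copy-number variation and whole-chromosome aneuploidy,
    computes pairwise SNP distances, heterozygosity and sliding-window
    nucleotide diversity, builds singleton-aware rarefaction curves with
    power-law and Michaelis-Menten saturation fits to estimate the fraction
    of species diversity captured, and assigns population structure through
    identity-by-state distances, neighbor-joining trees, an admixture EM
    estimator and ancestry-threshold clade assignment. A clade-structured
    synthetic-population generator with full truth tables makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    minpack.lm,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
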