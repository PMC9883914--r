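Package: heterokaryon
Title: Nucleotype Ratios, Inter-Nucleus Recombination and Allele-Specific
    Expression in Coenocytic Fungi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the nuclear organization of heterokaryotic
    (dikaryote-like) arbuscular mycorrhizal fungi from read-count data.
    Implements pooled-DNA SNP filtering, allele-frequency-spectrum karyotype
    inference with a two-nucleotype binomial mixture likelihood, mating-type
    (MAT) locus coverage ratios, principal component analysis over shared-SNP
    allele frequencies, single-nucleus genotype concordance with detection of
    consecutive-SNP recombination blocks, a Wright-Fisher style spore
    bottleneck drift simulator, and host-dependent allele-specific expression
    comparison. A synthetic-data generator produces VCF/BED/TSV/FASTA inputs
    with the statistical structure the pipeline assumes, so every step can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
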