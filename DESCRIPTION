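Package: asekit
Title: Allele-Specific Expression Counting, Imbalance Testing, and Visualization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for allele-specific expression analysis of aligned RNA-seq
    reads: strand-aware allele counting over heterozygous SNPs from indexed BAM
    files with quality and flag filtering, a subsettable sample-by-SNP count
    container with fraction, genotype and minor-allele-frequency derivations,
    exact binomial and chi-square tests for allelic imbalance against
    configurable expected allele ratios, N-masking of reference genomes to
    reduce reference-mapping bias, per-SNP and per-region allele-count
    visualizations, and a self-contained simulator that emits aligned reads
    with known per-SNP allele ratios for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    vcfR,
    stats,
    graphics,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
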