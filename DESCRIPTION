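Package: spvspectra
Title: Strain-Private Variant Discovery and Germline Mutation Spectra in
    Inbred Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies recent de novo germline mutations in panels of inbred
    strains as strain-private variants (SPVs) residing on long haplotypes
    shared identical-by-descent (IBD) between strains, and characterises
    per-strain mutation spectra. Provides pairwise IBD segment detection on
    a minor-allele-frequency filtered SNP panel, a stringent quality filter
    stack for private-variant calling with a per-rule audit, polarization
    and trinucleotide-context annotation, folded six-class (and CpG-split
    seven-class) mutation spectra standardized by the nucleotide composition
    of IBD territory, neutrality diagnostics (coding-consequence
    composition, G-tests, bootstrap confidence intervals,
    conservation-score CDF comparison), and among-strain spectrum
    comparison (pairwise G-tests, PCA, trait correlations). A mosaic-genome
    simulator generates laboratory-strain-like genomes from a small founder
    haplotype pool with planted private mutations and full ground truth, so
    the entire pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
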