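Package: tra2clip
Title: CLIP-Tag Motif Discovery and Splicing-Regulation Analysis for Tra2beta
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the computational analyses used to
    characterise the RNA binding landscape of the splicing activator Tra2beta
    from HITS-CLIP data: k-mer enrichment in CLIP tags with genome and
    transcriptome background correction, GAA-anchored consensus motif
    construction, genomic-feature annotation of tags, conservation-position
    enrichment testing (Fisher exact and chi-squared), exonic splicing
    enhancer z-score scanning with silencer-avoiding mutation design, and
    percent-spliced-in / qRT-PCR splice-isoform quantification. A synthetic
    data generator produces toy genomes, gene models, motif-planted CLIP tags,
    conservation masks and quantification readouts with the statistical
    structure the analyses assume, so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
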