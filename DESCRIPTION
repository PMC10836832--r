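Package: gshscreen
Title: Computational Screening for Genomic Safe Harbour Loci
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies putative genomic safe harbour (GSH) loci for targeted
    transgene integration. Safe intervals are computed as the genome-wide
    complement of buffered exclusion zones (ultra-conserved regions, DNase
    clusters, transcription units and their start sites, cancer genes, miRNAs,
    lncRNAs); ubiquitously expressed low-variance housekeeping genes are
    selected from a gene-by-tissue median-TPM matrix via a lowess
    mean-variance trend and a chi-squared screen; 1-Mb genome bins
    consistently in the active Hi-C A compartment across tissues and
    overlapping a housekeeping gene define active regions; candidates are the
    safe intervals inside active regions that survive a BLAT second-to-top
    hit-score uniqueness-ratio filter. A seeded synthetic-data generator with
    a planted-truth manifest makes every stage testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
biocViews: Software, GenomeAnnotation, Epigenetics, GeneExpression
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
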