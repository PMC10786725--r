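Package: polpause
Title: RNA Polymerase II Promoter-Proximal Pausing Analysis from ChIP-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies RNA polymerase II promoter-proximal pausing from
    ChIP-seq fragment data: gene-model construction with proximity and
    length filters, promoter and gene-body window counting, log2 pausing
    indices with paired Wilcoxon condition comparison, consensus-peak
    driven differential promoter enrichment (median-of-ratios
    normalization with a negative-binomial moment-dispersion test),
    hypergeometric gene-set over-representation, and drug-response
    quantification (constrained four-parameter logistic IC50, death
    ratios, exponential growth rates, 2^-ddCt relative expression).
    Includes a seeded synthetic-data generator with ground-truth tables
    so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    DESeq2,
    GenomicAlignments,
    Rsamtools,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
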