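Package: ploidyshift
Title: Ploidy and Karyotype Evolution Analysis for Experimentally Evolved Yeast
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing ploidy and karyotype evolution in
    experimentally evolved yeast populations selected for maltose
    metabolism. Infers relative chromosome copy number and aneuploidy
    calls from windowed sequencing depth, estimates haploid fraction
    from DNA-content flow cytometry via a constrained 1C/2C/4C Gaussian
    mixture, estimates per-generation selection coefficients from
    competition assays with factorial decomposition of fitness into
    ploidy, mating-type, and cell-type effects, evaluates gene-dosage
    null models for aneuploid gene expression, and scans promoters for
    IUPAC consensus transcription-factor motifs. A synthetic-data
    generator reproduces the statistical structure of every input so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    withr
Config/testthat/edition: 3
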