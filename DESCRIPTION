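Package: abequant
Title: Quantification of Adenine Base-Editing Outcomes from Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Analysis of adenine base-editing outcomes from amplicon deep
    sequencing. Provides paired-end read merging, quality filtering and
    primer anchoring, global affine-gap alignment to a wild-type amplicon,
    per-position and combination quantification of A-to-G edits, cytosine
    deamination and indel cataloguing, mono-/biallelic genotyping of clonal
    colonies from Sanger base-proportion traces, mismatch-scan enumeration
    and MIT specificity scoring of candidate off-target sites, and a
    background-error-model off-target caller for multiplexed amplicon
    panels with longitudinal samples. Includes a synthetic read, colony and
    panel simulator so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
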