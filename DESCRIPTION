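Package: qconbalance
Title: QconCAT Targeted Proteomics Quantification and Pathway Enzyme
    Balancing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for absolute protein quantification with concatamer
    (QconCAT) internal standards and for balancing heterologous pathway
    enzymes in whole-cell biocatalysis. Covers in-silico tryptic digestion
    and proteotypic peptide selection, concatamer standard design with
    junction auditing, peptide isotopologue distributions at arbitrary
    13C enrichment including labeling-deficit correction, conversion of
    multiple-reaction-monitoring (MRM) light/heavy peak areas into
    copies-per-cell protein abundances with calibration and digestion
    quality control, and a mass-action kinetic model of the limonene to
    carvone bioconversion pathway used to relate the P450/CDH abundance
    ratio to product titer. Includes a synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    deSolve,
    jsonlite,
    readr,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
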