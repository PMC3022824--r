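Package: sibsnp
Title: SNP Subset Selection and Case-Control Prediction with the
    Sequential Information Bottleneck
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage selection of single nucleotide polymorphism (SNP)
    subsets for case-control disease risk prediction, evaluated by the
    harmonic mean of sensitivity and specificity (HMSS). Stage one ranks
    SNPs by single-marker linear discriminant HMSS; stage two runs wrapper
    searches (forward selection, sequential forward floating selection,
    exhaustive one- and two-SNP search, and constrained group-accuracy
    search) around either a Fisher linear discriminant or a sequential
    information bottleneck (sIB) classifier, with stratified bootstrap
    confidence intervals and per-SNP chi-square association tests.
    Includes a synthetic two-cohort case-control genotype simulator with
    known causal architecture, plus PLINK text ped/map and TSV genotype
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
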