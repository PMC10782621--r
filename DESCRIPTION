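Package: ploidyscan
Title: Aneuploidy Detection from Read Coverage and Within-Sample Allele
    Frequencies
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.invalid")
Description: Detects whole-chromosome copy-number changes (aneuploidy) in
    short-read sequencing data from cultured cell lines. Windowed read
    counts are standardized by the median coverage of a set of baseline
    chromosomes, within-sample allele frequencies at heterozygous sites
    are summarized by kernel density estimation and mode detection, and
    each chromosome is classified against an enumerated space of
    single-clone and two-clone karyotype hypotheses, reporting the
    degeneracy class of hypotheses whose coverage-ratio and
    allele-frequency-mode signatures are indistinguishable. Includes
    GATK-style hard filtering of variant calls, genotype concordance
    crosstables, per-chromosome RNA-seq expression-dosage summaries, and
    a synthetic karyotype simulator emitting format-valid window counts,
    VCFs with allelic depths, and TPM tables for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
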