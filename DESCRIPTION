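Package: deamHRD
Title: CpG Deamination Fraction as a Biomarker for Homologous
    Recombination Deficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects homologous recombination deficiency (HRD) from
    somatic single base substitution (SBS) spectra. Classifies SBS calls
    into the 96 trinucleotide channels, computes the CpG C>T deamination
    fraction f_deam (a negative predictor of HRD) and the tumor
    mutational burden, derives genomic scar scores (LOH, LST, TAI and
    their sum HRDsum) from allele-specific copy-number segments, assigns
    cause-of-HRD classes from gene alteration and BRCA1 promoter
    methylation tables, and evaluates biomarkers by ROC/AUC, paired
    DeLong tests, balanced-accuracy cutpoint optimization, Cohen's kappa
    and channel-wise differential analysis with false discovery rate
    control. Includes a variant-level tumor-purity dilution simulator and
    a synthetic cohort generator so the full analysis runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    Biostrings
Config/testthat/edition: 3
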