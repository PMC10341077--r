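Package: hrdgis
Title: Genomic Instability Scoring for Homologous Repair Deficiency from
    Allele-Specific Copy Number Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes a genomic instability score (GIS) for homologous
    repair deficiency (HRD) detection from tumor-only allele-specific copy
    number segmentation. The score is the sum of three components measured
    on the observed (sequenceable) genome: percent loss of heterozygosity
    (PLOH), percent copy number alteration relative to each chromosome's
    expected allele-specific state (PCNA), and percent telomeric copy
    number alteration (PTCNA). Samples are classified GI-positive against
    a calibrated cutoff and combined with BRCA1/2 mutation status into an
    HRD call. Also provides the Cohen's-kappa cutoff-calibration scan
    against a reference assay, an exact-binomial depth-for-detection
    calculator, and a synthetic profile simulator for end-to-end testing
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
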