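# hrdgis

Genomic instability scoring for homologous repair deficiency (HRD)
detection from tumor-only allele-specific copy-number profiles.

## The problem

Tumors with a defective homologous recombination repair pathway (most
prominently through *BRCA1*/*BRCA2* inactivation) accumulate characteristic
genome-wide scars — long stretches of loss of heterozygosity (LOH),
allele-specific copy-number changes, and rearranged telomeres — and respond
to PARP inhibitors. Detecting that scarring from a single FFPE tumor sample,
without a matched normal, is the job of a genomic-instability (GI) assay.
`hrdgis` implements the scoring half of such an assay: it consumes the
allele-specific segmentation produced by a tumor-only purity/ploidy caller
(e.g. PureCN) and turns it into a single GI score (GIS) and an HRD call. It
does not align reads, call variants, or infer purity/ploidy.

## The score

All three components are measured on the **observed genome** — the arm
territory actually covered by segments — so scores adapt to the patchy
coverage of degraded FFPE DNA instead of dropping the sample:

* **PLOH** — percent of the observed genome in LOH (minor-allele copy
  number 0), counting only regions larger than 10 Mb and smaller than a
  whole chromosome arm.
* **PCNA** — percent of the observed genome whose allele-specific state
  `(total, minor)` deviates from the chromosome's *expected* state (the
  state covering the largest part of that chromosome), again counting only
  regions larger than 10 Mb that do not affect a whole arm. Because
  deviation is allele-specific, copy-neutral LOH counts.
* **PTCNA** — percent of evaluable telomeres whose terminal segment
  (larger than 1 Mb, within 5 Mb of the chromosome end, not a whole-arm
  event) deviates from the expected state. Telomeres that are poorly
  assembled in the reference (e.g. the acrocentric p arms in hg19) are
  excluded from the denominator.

```
GIS = PLOH + PCNA + PTCNA          GI-positive  iff  GIS >= 83
HRD-positive  iff  GI-positive  and/or  pathogenic BRCA1/2 mutation
```

The package also ships the calibration machinery that produced the cutoff —
a Cohen's-kappa-maximizing scan against a reference assay's labels — an
exact-binomial depth-for-detection calculator, and a synthetic profile
simulator so the whole pipeline is testable without patient data.

## Worked example

A two-chromosome toy genome (chrA 100 Mb, chrB 60 Mb, 1 Mb centromeres)
carrying a single 15 Mb copy-neutral LOH event at the chrA p terminus:

```r
library(hrdgis)

build <- load_arm_table(system.file("extdata", "toy_arms.tsv", package = "hrdgis"))
profiles <- read_segmentation(
  system.file("extdata", "example_segments.tsv", package = "hrdgis"), build)
res <- compute_gis(profiles$EX01, build)
res
#> <gis_result> EX01
#>   PLOH 9.4937 + PCNA 9.4937 + PTCNA 25.0000 = GIS 43.9873
#>   GI status: negative (cutoff 83)
#>   observed genome: 158,000,000 bp (100.0% of assembled territory)
call_hrd(res, brca = "pathogenic")$hrd_status
#> [1] "positive"
```

Reading the numbers: 158 Mb of the toy genome is observed (160 Mb minus the
two centromeres). The 15 Mb LOH region passes the size filter and is not a
whole arm, so PLOH = 100 × 15/158 = 9.4937; the same region deviates from
chrA's expected state (2,1), so PCNA = 9.4937; it also reaches the chrA p
telomere, so 1 of 4 evaluable telomeres is altered and PTCNA = 25. The sum,
43.99, is below the cutoff of 83, so the sample is GI-negative — but a
pathogenic BRCA1/2 mutation still makes it HRD-positive.

For real data, replace the toy arm table with the bundled hg19 frame
(`hg19_build()`, autosomes + X) and feed your caller's segmentation in the
same six-column dialect. Calibration against a reference assay:

```r
coh  <- simulate_cohort(28, 44, label_noise = 0.05, seed = 1)  # or your own table
scan <- scan_cutoffs(coh[, c("sample", "gis")], coh[, c("sample", "reference_status")])
scan
#> <cutoff_scan> 301 candidate cutoffs, n = 72
#>   max kappa 0.7222 on [84, 85]; selected cutoff 84
#>   at selection: sens 0.667 spec 0.983 ppv 0.889 npv 0.937 conc 0.931
```

A shell entry point with `score`, `calibrate` and `simulate` subcommands is
installed at `inst/cli/hrdgis`.

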