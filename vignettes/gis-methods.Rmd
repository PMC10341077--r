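---
title: "Scoring genomic instability from allele-specific copy-number profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring genomic instability from allele-specific copy-number profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdgis)
```

## Scope and input contract

`hrdgis` quantifies the genomic scarring left by homologous repair
deficiency (HRD) and classifies tumor samples as GI-positive/negative and
HRD-positive/negative. Its input is the *product* of a tumor-only
copy-number pipeline: a per-sample table of genomic intervals with integer
total (`C`) and minor-allele (`M`) copy numbers, as emitted by purity/ploidy
callers such as PureCN from SNP-backbone hybrid-capture sequencing.
Everything upstream — alignment, deduplication, variant calling, purity and
ploidy inference — is out of scope; purity and ploidy are carried as
metadata only, because the integer allele-specific states are already
resolved for them upstream.

Coordinates are 0-based half-open internally. Every on-disk dialect is
converted at the I/O boundary: the segmentation and arm-table TSVs are
1-based inclusive, while cytoband files follow the UCSC convention (0-based
half-open) because that is how UCSC distributes them.

## The observed genome

FFPE-derived DNA is often degraded, and parts of the genome cannot be
segmented reliably. Rather than dropping such samples, all percentages are
computed over the **observed genome**: the summed arm-overlapping territory
of the sample's segments, excluding centromere overlap and any coverage
gaps recorded by segment fusion. The companion *observed fraction* (observed
genome / assembled arm territory of the build) gates evaluability: below
`min_observed_fraction` (default 0.4) a sample is reported unevaluable
rather than scored from a handful of segments. The value is a floor we
chose — the method's definition names no threshold — set low enough to keep
degraded-but-informative samples and high enough that the three components
are estimated from most of the genome. Unevaluability is a reportable
outcome, not an error: a sample with a pathogenic *BRCA1/2* mutation is
HRD-positive even when its GI score is undefined.

Chromosome set: autosomes 1–22 plus X; Y is present in the bundled hg19
frame but excluded from scoring by default. The clinical context of the
assay (ovarian and breast carcinoma) makes Y uninformative, and SNP
backbones cover it poorly. The set is configurable via
`genome_build(included = ...)`.

## Segment fusion and coverage gaps

Fragmented coverage splits single biological events into several segments
of identical state. `merge_equal_state_runs()` fuses consecutive
equal-state segments separated by an unobserved gap of at most `max_gap_bp`
(default 1 Mb, chosen to bridge typical FFPE coverage holes without joining
independent events). The fused gap contributes to the event's *span* —
which the size filters judge — but never to the observed genome: event size
and coverage completeness are deliberately separated. The scorer applies
this fusion internally, so callers need not pre-merge.

## The three components

**PLOH.** A base is in LOH when its minor-allele copy number is 0. Maximal
LOH runs are built by fusing consecutive LOH segments across gaps of at
most `max_gap_bp`, *regardless of total copy number*: PLOH measures allele
loss, and a total-copy-number change inside one LOH tract should not split
the tract below the size filter. A run qualifies when its span is strictly
greater than 10 Mb and it does not affect a whole arm (below). Homozygous
deletions (`C = 0`) satisfy `M = 0` and are included, flagged in the
contributing-regions output, since they too represent loss of one (indeed
both) parental alleles. PLOH is 100 × (qualifying observed LOH bp) /
(observed genome bp).

**PCNA.** Each chromosome's *expected state* is the `(C, M)` pair covering
the largest part of its observed arm territory; ties break toward the
smaller total, then the smaller minor, copy number (the more parsimonious
state). Deviation is judged allele-specifically, so copy-neutral LOH —
the central lesion class of HRD genomes — counts as deviation even though
total copy number is unchanged. Deviant runs fuse across differing deviant
states by default (`fuse_mixed_states = TRUE`): the size filter tests
altered territory, not uniformity of the alteration; a state-uniform
variant is available via configuration. Qualification and the denominator
are as for PLOH. A chromosome with a single state defines its own
expectation and contributes nothing.

**PTCNA.** For each chromosome with an expected state, the p telomere is
evaluable when it is assembled in the reference and some segment starts
strictly within 5 Mb of position 0; the q telomere, when some segment ends
strictly within 5 Mb of the chromosome end. The anchoring segment is the
outermost such segment — after equal-state fusion, simply the chromosome's
first (last) segment. The telomere is altered when that segment spans more
than 1 Mb, deviates from the expected state, and the alteration run
containing it is not whole-arm. PTCNA is 100 × altered / evaluable
telomeres; with zero evaluable telomeres it is undefined and the sample
unevaluable. Unassembled reference telomeres (the acrocentric p arms
chr13/14/15/21/22 in hg19) never enter the denominator. We anchor the
verdict on the terminal segment itself, not on any deviation within the
5 Mb window: the window is a *distance* criterion for what counts as
telomeric, and the terminal segment is what the assay actually observes at
the chromosome end.

**Whole-arm rule.** Arm-level events are a feature of overall aneuploidy
rather than HRD scarring, so regions "affecting a whole chromosome arm" are
not counted in any component. Segmentation never lands exactly on arm
boundaries, so the rule is operationalized as: a region is whole-arm when
its observed overlap with an arm reaches `whole_arm_fraction` (default 0.9)
of that arm's observed territory. An arm the region does not touch never
disqualifies it. The centromere belongs to neither arm; hg19 centromeres
are assembly gaps, and segments overlapping them contribute only their
arm-overlapping portions.

**Strictness.** All printed thresholds are strict inequalities: span
> 10 Mb, telomeric span > 1 Mb, terminus distance < 5 Mb. The GI call uses
`GIS >= cutoff`, mirroring the convention of the commercial score it was
calibrated against (positive at score ≥ 42).

## Classification and calibration

`GIS = PLOH + PCNA + PTCNA` ranges over [0, 300]. The default cutoff 83 is
the assay's calibrated operating point. `scan_cutoffs()` reproduces the
calibration: over an integer grid (default 0–300, the score's range), each
cutoff's prediction (`gis >= c`) is compared with reference-assay labels by
Cohen's kappa, alongside sensitivity, specificity, PPV, NPV and
concordance. The selected cutoff is the *lower end* of the first maximal
contiguous run of cutoffs attaining the maximum kappa — among equally
concordant cutoffs, the lowest classifies the most patients positive and
therefore eligible for therapy. Samples with undefined GIS are excluded
and reported as dropout. For a 2×2 table the chance-agreement term can
only reach 1 under perfect agreement, so kappa is defined for every
two-class scan; single-class reference labels are rejected.

`min_depth_for_detection()` exposes the related assay-design question —
how many unique reads are needed to detect a variant at a given allele
frequency — as an exact binomial calculation: the smallest `N` with
`P(X >= k) >= s` for `X ~ Binomial(N, af)`. It is a parametric calculator,
not a reproduction of any particular pipeline's threshold, because the
detection model behind published depth figures (alt-read floor, error
model) is generally not stated.

## The simulator

`simulate_profile()` generates the scorer's input contract directly:
integer allele-specific segments on a build, with three planted event
classes matching the component definitions — interstitial LOH (copy-neutral
`(2,0)` or with loss `(1,0)`), interstitial CNA with the minor allele
retained (gains such as `(3,1)`, `(4,2)`), and telomere-anchored deviant
events. Event sizes are log-uniform (default 5–40 Mb, the scale of the
scars the size filters target); placement is uniform over arms with
rejection of overlaps, and interstitial events stay clear of the 5 Mb
telomeric windows so that planted event types map one-to-one onto
component rules. Coverage dropout removes log-uniform 0.5–5 Mb holes until
a target fraction of the genome is unobserved, emulating FFPE patchiness.
Everything is deterministic given a seed, and an event ledger records each
planted event with its size-filter status for cross-validation against the
scorer's contributing regions.

What the simulator does *not* emulate: read-level noise, SNP-level B-allele
frequencies, purity mixtures, segmentation error (breakpoint jitter, state
miscalls), and the correlated event structure of real HRD genomes. Passing
tests therefore demonstrate that the scoring rules are implemented exactly
and behave correctly on profiles with known truth — not that the assay
performs at any particular level on clinical specimens.

`simulate_cohort()` builds calibration fixtures: per-sample event counts
are drawn uniformly from per-group ranges (HRD-like: 20–34 LOH, 14–24 CNA,
16–28 telomeric events; HRP-like: 0–12 / 0–10 / 0–14; dropout 0–10%),
producing a continuum of instability with the HRD-like group centred above
the operating cutoff and the HRP-like group below it, with overlapping
tails — as in clinical cohorts, where scores spread across the cutoff
region rather than forming two point masses. Reference labels are the
samples' own scored status with a configurable fraction flipped, emulating
imperfect agreement between two assays.

## Numerical choices and degenerate inputs

* Percentages are computed in double precision; files report 4 decimals.
* Expected-state ties are resolved deterministically (smaller `C`, then
  smaller `M`); the per-base oracle in the test suite confirms tie cases.
* Kappa ties in the cutoff scan are compared with a 1e-12 tolerance before
  forming the maximizing run, so floating-point noise cannot split it.
* Empty segmentation yields an empty profile list; a profile with no
  observed arm territory, or no evaluable telomere, is unevaluable, never
  an error. Chromosomes absent from the active build reject the file
  (referential integrity); chromosomes excluded from scoring are dropped
  and counted in the load report.
* `arm_of` is additive under interval splitting, and the three overlap
  lengths always sum to the interval length; both are property-tested.

## Verification strategy and problem sizes

The test suite checks the interval implementation against an independent
per-base painter that colors every base of randomized toy genomes (2–5
chromosomes of 0.15–0.45 Mb, filters scaled accordingly) and applies the
rules positionally; 100 random genomes must agree to 1e-9 relative
tolerance. Structural properties — GIS 0 for single-state genomes,
invariance under whole-genome duplication `(C, M) → (2C, 2M)`, monotonicity
under insertion of a qualifying LOH region — are verified on simulated
hg19-scale profiles. Cutoff recovery is checked on 100 replicate cohorts
of 72 samples (28 HRD-like, 44 HRP-like) with 5% label noise; the selected
cutoff must fall within ±5 of the operating threshold in at least 95% of
replicates. These sizes keep the full suite at a few minutes on one core
while exercising every rule branch.

## Known limitations

* The scorer trusts its input segmentation; systematically wrong
  purity/ploidy fits upstream translate into wrong allele-specific states
  and are invisible here.
* The whole-arm fraction (0.9) and run-fusion gap (1 Mb) are pragmatic
  operationalizations of qualitative rules; both are exposed as parameters.
* Only one genome build per run; no liftover.
* The simulator's independence assumptions (uniform placement, independent
  events) understate the clustering of real rearrangements; calibration
  results on simulated cohorts demonstrate the machinery, not clinical
  performance.
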