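---
title: "Methods: rare germline variant analysis in cancer cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare germline variant analysis in cancer cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raregerm)
```

# The problem

Germline variants with population allele frequency below 0.5% sit between
two established study designs: too rare for array-based association
studies, yet too frequent collectively to ignore when sequencing cancer
cohorts. In B-cell lymphoid neoplasms — chronic lymphocytic leukemia and
the aggressive lymphomas — such variants in cancer-related genes may
predispose to disease (sometimes completed by a somatic "second hit"),
masquerade as clonal-hematopoiesis mosaics, or stratify survival.
`raregerm` implements the full analysis chain for this setting: consensus
germline calling from several variant callers, a rarity/impact
prioritization cascade, second-hit and CHIP structure detection, a
carrier-collapsing burden test against public controls, and per-gene
survival screening. This vignette documents the models, the parameters
that matter, the numerical choices, and what the synthetic-cohort tests do
and do not establish.

# Consensus calling

## Variant normalization

Callers represent the same indel differently (different anchor positions,
padded alleles). Cross-caller matching keys every record on its canonical
form: shared trailing bases are trimmed, extending leftwards through the
reference whenever an allele would become empty, then shared leading bases
are trimmed while both alleles retain at least one base. The result is the
unique left-most parsimonious representation; the test suite verifies by
enumeration that every representation of the same deletion in a
homopolymer context maps to one key, and that the operation is idempotent.
Records whose stated reference allele contradicts the reference sequence
are rejected with a warning rather than silently re-anchored. Multi-allelic
records are split into bi-allelic rows before normalization, apportioning
allele depths from the AD field; the source is silent on this, and
splitting-before-keying is the convention that makes caller comparisons
well defined.

## Merging rule

A variant enters the consensus when at least `min_callers = 2` callers
report a non-reference genotype at the same normalized site. Merged QC
values must pass `min_gq = 30` Phred, `min_dp = 10` reads and
`min_vaf = 0.30`; the VAF floor guards against contamination of the
germline compartment with tumor cells, which shifts mosaic or somatic
alleles well below the heterozygous expectation of 0.5. GQ and DP are
merged as medians across supporting callers, and VAF is recomputed from
allele depths summed across callers (falling back to the median of
per-caller fractions) — a deliberate robustness choice, since a single
outlier caller should not veto or rescue a call; the merge rule was an
open design point and the median/summed-depth combination is ours.
Zygosity is the majority genotype; a 1–1 tie resolves to heterozygous,
which is conservative for downstream homozygote detection, and the row is
flagged `genotype_conflict` for review. Thresholds are applied to the
merged values, i.e. after caller aggregation: whether the VAF filter
precedes or follows merging was unstated, and filtering the merged value
uses all available evidence. Excluded-region BEDs (low mappability,
homopolymers, abnormal coverage) are consumed as a single merged input
with BED 0-based half-open semantics at the interface; internally all
coordinates are 1-based inclusive.

# Prioritization cascade

Three commuting filters define a qualifying variant:

* **Rarity.** The population-maximum allele frequency must be strictly
  below `popmax_max = 0.005`. Two behaviors are exposed through
  `exclude_pops`: for cohort characterization no population is excluded
  (a variant common anywhere is discounted), while the burden stage
  excludes Finnish, Ashkenazi Jewish and residual "Other" panels —
  bottlenecked or heterogeneous groups whose frequency spikes would
  otherwise mask variants that are genuinely rare in the ancestry matched
  to the controls. A variant absent from the frequency table is treated as
  unobserved (popmax 0, passes), which is the only defensible reading for
  novel variants.
* **Impact.** Protein-truncating terms qualify regardless of score;
  missense variants need CADD-like Phred strictly above `cadd_min = 20`
  (the top 1% of predicted-deleterious substitutions); variants with extra
  high-impact structural/interaction annotations form a third category
  used only by the extended burden model. Missense records without a score
  are rejected with a warning rather than guessed. One consequence per
  variant is assumed, the most severe across transcripts
  (PTV > missense > inframe > other).
* **Panel.** Gene panels are provenance-tracked unions of curated source
  lists; off-panel and unannotated variants are routed to a background
  stream (used for rate comparisons), so the partition is exhaustive and
  disjoint.

The suite verifies order-independence of the cascade and monotonicity:
relaxing the CADD or popmax threshold can only grow the qualifying set.

# Second-hit structure and CHIP

A true germline variant is present in every cell; a clonal-hematopoiesis
mosaic is confined to the blood compartment. Variants in CHIP-associated
genes that pass germline QC in the control compartment but show
tumor-compartment VAF below `tumor_absent_threshold = 0.05` are flagged
`likely_chip` and removed before any downstream analysis; the threshold
number is ours ("very low VAF" was not quantified) and is configurable.
Variants without tumor data are kept as germline with a "not assessable"
flag — dropping them would silently bias carrier counts.

Double-hit detection emits one event per patient–gene: homozygotes (one
event per homozygous variant), germline double hits (two or more distinct
qualifying variants in the same gene; a heterozygote co-occurring with a
homozygote also counts and is cross-referenced with its homozygote event),
germline–somatic co-mutations (same patient, same gene in the somatic
table), and LOH second hits (a qualifying variant's normalized position
inside a loss-of-heterozygosity segment of the same patient, segments
1-based inclusive). Compound candidates whose phase table places both
variants on one haplotype are retained with `phase = "cis"` rather than
dropped, so stricter trans-only analyses remain possible downstream.

# The burden test

The collapsing unit is the carrier: a patient with at least one qualifying
allele in the gene, counted once (dominant model). Public controls publish
per-variant allele counts, not genotypes, so control carriers are
estimated as the sum of allele counts over the gene's qualifying variants,
capped at the control sample size — for variants this rare, each allele
almost surely sits in a distinct heterozygous control, which is the
standard approximation for public-control collapsing tests. The test is
the exact one-sided hypergeometric upper tail on the resulting 2×2 table,
in the enrichment direction only (depletion is not the scientific
question). Benjamini–Hochberg correction is applied within each model
(PTV-only and PTV-plus-high-impact are corrected separately and both
reported), and the genomic inflation factor
$\lambda = \mathrm{median}\,\chi^2_1(1-p)\,/\,0.4549$ accompanies every
result table.

Two numerical notes. Genes with zero case carriers are skipped, not
tested: their p-value is 1 by construction and including them would only
dilute the FDR. And the exact test is *conservative* at rare-variant
counts — attainable p-values are discrete, the null rejection fraction at
0.05 runs below 0.05, and λ computed over such p-values sits below 1
(typically 0.7–0.85 in the package's null calibration studies, which the
acceptance script recomputes). This is a property of exact conditional
tests, not a defect; analysts should read λ ≈ 0.8 on rare-variant burden
screens as healthy, and reserve concern for λ well above 1.

# Survival screening

Gene carrier status enters a Cox proportional-hazards model with Efron tie
handling (unstated in the source; Efron is the better approximation and
the survival-package convention is available either way). Covariate sets
follow the outcome: IGHV mutation status and tumor stage for time to first
treatment, IGHV status and age at diagnosis for overall survival, with the
alternative adjustment (age + CLL/MBL status) available by configuration.
The screen is restricted to genes carried by strictly more than
`min_carrier_freq = 0.01` of the analyzed patients — below that, a Cox
model on a handful of carriers is numerically fragile and scientifically
uninterpretable. Patients with missing covariates are dropped per model
with a message; non-converging or separated fits are flagged and excluded
from the BH correction (within outcome) rather than contributing
meaningless p-values. Confidence intervals are Wald (normal approximation
on the log hazard).

# The synthetic cohort generator

`generate_cohort()` writes a complete study bundle — four per-caller VCF
sets, reference FASTA, population AF/CADD/consequence/known-variant
tables, an excluded-region BED with decoy variants planted inside it,
somatic and LOH tables, tumor-compartment VAFs for CHIP genes, six
overlapping panel source lists, emulated control allele counts, a clinical
table, and a JSON ground truth — as a deterministic, byte-identical
function of its spec.

What it emulates, and the defaults (all chosen to mirror the cohort scale
the package targets):

* Background qualifying-variant rate 0.0025 per gene per patient — the
  order observed when ~1,700 qualifying variants spread over ~900 panel
  genes in ~700 patients; demos and tests often raise it to 0.01 so small
  cohorts have enough structure to exercise every stage (a sizing choice,
  not a claim about biology).
* A variant-type mix dominated by missense (93.5%), with stop-gain 2.4%,
  frameshift 2.4%, splice 1.2% and the remainder spread over inframe and
  start/stop-loss classes.
* Planted per-patient rates for second-hit structure near the observed
  scale: homozygotes 0.017, compound heterozygotes 0.021, CHIP mosaics
  0.014, germline–somatic hits 0.023, LOH hits 0.0014. Exact-recovery
  tests raise these (and set caller sensitivity 1, QC failure 0) so a
  40-patient cohort carries ~14 events — again sizing, with the rates
  printed in the test code.
* Germline heterozygous VAFs concentrate in [0.35, 0.65]; CHIP mosaics
  draw control VAF in [0.35, 0.45] with tumor VAF below 0.02, so both the
  30% germline VAF floor and the CHIP rule are exercised from both sides.
  A configurable 5% of background calls are drawn to fail exactly one QC
  threshold (GQ, DP or VAF).
* One pseudo-caller ("platypus") writes indels right-shifted inside a
  planted homopolymer run, exercising normalization; indel sites carry a
  7-base run so several representations exist.
* Per-population frequencies use a point-mass-at-zero (novel, probability
  0.45) plus log-uniform mixture, with occasional Finnish/Ashkenazi
  spikes above the rarity threshold to exercise the popmax exclusions; no
  claim of demographic realism is made.
* Survival times are exponential with log-linear covariate effects (IGHV
  0.4, age 0.3 per decade, stage 0.25 per step) and independent uniform
  censoring — the simplest generator compatible with proportional
  hazards, so Cox recovery is a well-posed test. Planted gene hazards
  apply to carriers on both outcomes.
* Control allele counts are binomial draws at the background allele
  frequency, so the no-enrichment null holds exactly.

Ground-truth events are derived from the full emitted genotype table under
the analysis eligibility rules, not merely from the planting labels:
incidental structure (a background heterozygote landing in a gene that
already carries a planted one) is genuine double-hit structure and belongs
to the truth. The truth file is therefore the expected detector output
under full sensitivity and passing QC.

What the generator does **not** emulate: read-level data (no FASTQ/BAM;
caller disagreement is reduced to independent Bernoulli detection),
linkage disequilibrium and population structure, pedigrees, sex
chromosomes, and gene length variation. Passing tests on this generator
establish that the pipeline's logic and statistics behave as specified —
not that any particular real cohort will show the same operating
characteristics.

# Calibration, power and recovery studies

The acceptance surface is parameter recovery, not reproduction of any
cohort-specific estimate (those require controlled-access data). Problem
sizes were fixed as follows:

* **Null burden calibration** runs on 2,000 genes at 500 cases against
  15,708 emulated controls, with per-gene carrier frequencies drawn
  log-uniformly on [0.002, 0.05] — the spread of a cancer panel whose
  genes range from near-singletons to a few percent of patients. These
  studies use `simulate_burden_counts()`, the count-level layer of the
  generator: per-gene carrier and allele counts are the sufficient
  statistics of the collapsing test, so simulating them directly is exact
  while keeping thousands of genes cheap. As discussed above, the exact
  test is conservative at these counts; the measured rejection fraction
  at 0.05 and λ land below their nominal values, and the package reports
  them as computed.
* **Power**: a gene with background carrier frequency 0.0025 and a
  tenfold case enrichment, screened among 200 genes over 50 replicates,
  is recovered at q < 0.1 in well over 80% of replicates.
* **Cox recovery**: a planted hazard ratio of 3 (500 patients, 40
  carriers) is covered by the fitted 95% CI in ≥ 90% of 20 replicates; a
  null gene inside a 50-gene screen stays at q ≥ 0.1.
* **Exact recovery**: on a noise-free 40-patient cohort the full pipeline
  recovers planted homozygotes, compound heterozygotes, CHIP mosaics and
  somatic/LOH second hits with precision and recall 1.0.

# Known limitations

* The control-carrier estimate ignores the (tiny) probability of one
  control carrying two qualifying alleles, and public-control designs
  cannot adjust for covariates or relatedness; significant burden hits on
  real data still require ancestry-matched follow-up.
* The one-consequence-per-variant rule discards transcript-level nuance.
* Phase assignment relies entirely on a supplied phase table; no
  read-backed phasing is attempted.
* λ over discrete exact-test p-values is a blunt diagnostic; the QQ
  autoplot is the more informative view.
* The generator's independence assumptions (sites, callers, patients)
  make consensus and burden behavior cleaner than real data, where caller
  errors correlate within loci.
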