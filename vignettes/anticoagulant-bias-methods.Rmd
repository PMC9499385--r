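---
title: "Methods: quantifying anticoagulant bias in circulating plasma miRNA profiles"
author: "plasmiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying anticoagulant bias in circulating plasma miRNA profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmiR)
```

## The problem

Circulating extracellular microRNAs (c-miRNAs) in plasma are candidate
biomarkers, but their measured profiles are highly sensitive to
pre-analytical conditions. One such condition is the anticoagulant in the
blood collection tube: K2 EDTA tubes promote low-level red-blood-cell (RBC)
hemolysis, which releases RBC-abundant miRNAs (miR-451a, miR-486-5p,
miR-92a-3p, miR-16-5p, ...) into the cell-free fraction, while citrate-based
anticoagulants (ACD, sodium citrate, CTAD) largely do not. Because a few
RBC species can come to dominate the read pool, this contamination
simultaneously inflates the RBC-derived share of the profile, depresses
apparent diversity, and dilutes platelet-derived species.

`plasmiR` implements the complete measurement and analysis chain needed to
detect and quantify this bias in a paired design (every subject sampled
into every anticoagulant group), together with a synthetic cohort generator
that makes each stage testable end-to-end with known ground truth.

## Pipeline stages and their models

### Read preprocessing

Small-RNA libraries carry a fixed 3' adapter
(`TGGAATTCTCGGGTGCCAAGG`) and 4 randomized bases ligated to both ends of
the insert. `preprocess_fastq()` applies, in protocol order:

1. **Adapter trimming** at the leftmost occurrence; partial matches are
   accepted only at the 3' terminus with at least 6 bases of overlap, and
   mismatches up to a 10% error rate (no indels). These parameters are the
   documented defaults of the standard trimming tool for this chemistry.
   Reads without adapter evidence are *discarded*, not kept untrimmed: an
   untrimmed read still carries its 3' randomized bases at unknown
   positions and cannot be assigned to a miRNA coordinate frame.
2. **Randomized-base removal**: the first and last 4 bases of the trimmed
   read are stripped positionally. These are randomized ligation adapters,
   not UMIs; no deduplication is performed.
3. **Length gate**: inserts of 16–28 nt inclusive are kept. The bounds are
   inclusive because the protocol removes reads *shorter than* 16 and
   *longer than* 28.

The stage emits conservation-checked statistics
(`input = passed + no_adapter + bad_length`) and passes quality strings
through untouched.

### Assignment and isomiR classification

Mature miRNAs are frequently observed as isomiRs: end-trimmed, end-extended
or internally substituted variants of the canonical sequence. To call these
classes, the reference anchors every mature sequence on its hairpin
precursor at recorded 0-based half-open coordinates, so extension bases can
be compared with the genomic (hairpin) context.

`assign_reads()` performs gapless placement of each read against each
mature sequence with 5'/3' end offsets up to `max_shift = 3` and at most
`max_mismatch = 2` internal mismatches, where *internal* means inside the
overlap with the canonical mature interval — extension bases are judged by
the classifier, not counted as mismatches. The best candidate minimizes
(mismatches, total |offset|), with ties broken by lexicographically
smallest miRNA name; all three keys are deterministic. The implementation
enumerates all mismatch-free placements exactly via a hashed dictionary of
pure-trim variants (any mismatch-free placement decomposes as extension
bases around such a core), falling back to a full placement scan only for
reads that need mismatches; a brute-force enumeration oracle in the test
suite verifies exact agreement.

`classify_isomir()` then labels each assigned read: `canonical` (exclusive),
`trim3`/`trim5`, `ext3_templated`/`ext3_nontemplated` (an extension is
templated iff every extended base equals the hairpin base at that position;
running off the hairpin is non-templated by definition), the corresponding
5' labels, and `polymorphic` for internal single-nucleotide differences.
Isoform identity for tallies is the exact read sequence.

This replaces the original study's genome-wide remapping step with a
self-contained hairpin-context aligner: genome-scale remapping is
unnecessary for a self-consistent reference and would add a heavyweight
external dependency; the cost is that counts on real data are not expected
to match that tool read-for-read.

### Filters and QC gates

All thresholds ship as defaults and are exposed as parameters:

| Filter | Rule | Default |
|---|---|---|
| noisy reads | drop miRNA iff mean count ≤ 2 **and** zero in ≥ 90% of samples | 2 / 90% |
| expression | keep miRNA iff CPM > 2 (strict) in ≥ 10 samples | 2 / 10 |
| isoforms | parent passes expression rule **and** isoform mean count > 10 | 10 |
| major isoforms | pooled isoform count > 10% of parent's pooled count | 10% |
| sample QC | exclude if miRNA reads < 15% of total; flag (strict: exclude) if unaligned > 50% | 15% / 50% |
| qPCR QC | exclude sample if mean Cq > 25 (strict) | 25 |

"Missing in ≥ 90% of samples" is implemented as *strictly zero* counts;
log2 CPM uses a 1-CPM pseudocount (`log2(CPM + 1)`), bounded below at 0.
The expression gate for DE selection uses the overall mean log2 CPM, not
per-group means (both readings are defensible; the overall mean is the one
implemented and tested).

### Diversity and global structure

Per-sample Shannon diversity (natural log, via `vegan::diversity`) is
computed on CPM values; a miRNA counts as detected within one sample at
CPM > 2, consistent with the global expression filter. Top-N concentration
ranks miRNAs by within-group mean CPM. Group overlap partitions per-group
detection sets, where a group detects a miRNA at CPM > 2 in ≥ 2 of its
samples (the 10-of-30 global rule scaled to group size). PCA runs on
per-miRNA centered, unit-variance log2 CPM profiles via singular value
decomposition; components are sign-fixed so the largest-magnitude loading
is positive, making scores reproducible across sample orderings.

### Hemolysis and origin statistics

* Spectrophotometric score: `HS = (A414 − A385) + 0.16·A385` from 1-mm-path
  absorbances; 414 nm is the free-hemoglobin peak and the A385 term makes
  the score lipemia-independent. The difference term is the plain
  `A414 − A385` difference. Absorbances are taken as given (blank handling
  happens upstream of this package).
* Sequencing ratio: `log2CPM(miR-451a) − log2CPM(miR-23a-3p)` —
  miR-451a is RBC-enriched, miR-23a-3p hemolysis-insensitive.
* qPCR ratio: `dCq = Cq(miR-23a-3p) − Cq(miR-451a)`; one cycle is one log2
  unit (100% efficiency assumed; the protocol applies no efficiency
  correction).
* RBC–Platelet ratio: |mean Cq of the RBC trio (miR-451a, miR-92a-3p,
  miR-16-5p) − mean Cq of the platelet quartet (miR-223-3p, miR-126-3p,
  miR-21-5p, miR-150-5p)|.
* Origin fractions: share of TMM-normalized CPM attributable to the
  RBC-derived, platelet-derived, hemolysis-susceptible and remaining
  panels, per group, plus within-panel composition vectors.

Panels are *study inputs*, shipped as editable defaults
(`default_origin_panels()`). miR-191-5p is abundant in both RBCs and
platelets; conflict resolution deterministically assigns shared members to
the RBC panel and logs the move.

### Differential expression

Counts are TMM-normalized (`edgeR::calcNormFactors`; the test suite
cross-checks the factors against a literal transcription of the published
trimmed-mean-of-M-values formula). Each miRNA is fit with a
negative-binomial GLM with additive subject and group effects — subject as
a blocking variable, since every subject appears in several groups — with
empirical-Bayes dispersion moderation, and each of the six pairwise group
contrasts is tested with the quasi-likelihood F-test. P-values are adjusted
by Benjamini–Hochberg *pooled across all contrasts as one family*;
`significant` means adjusted p < 0.05 strictly. A miRNA is called DE iff
its mean log2 CPM exceeds 5, it has at least one significant contrast, and
either some significant contrast has |log2FC| > 1 or it has ≥ 3
significant contrasts.

**Why blocking matters.** With strong subject effects and no group effect
the blocked analysis makes essentially zero calls. Omitting the blocking
term under this machinery does *not* inflate the false-positive rate — the
unmodeled subject variance flows into the genewise quasi-dispersion and the
unblocked test becomes conservative — but it is devastating for power: in
the packaged simulation (2-fold effects, subject SD of 1 log2 unit),
blocking recovers essentially all planted effects while the unblocked
analysis of the same data recovers none. The test suite demonstrates both
facts.

### qPCR validation

`relative_expression()` computes `EXP = Cq(miR-30e-5p) − Cq(target)`.
Reference-gene stability uses a NormFinder-style model-based variance
decomposition on sign-flipped Cq values: per-sample gene-centering removes
the sample level; per assay and group an intra-group variance is estimated
from the centered residuals and bias-corrected across assays
(`σ²ᵍᵢ = (k/(k−2))·(s²ᵍᵢ − Σs²/(k(k−1)))`, clamped at 0); the gene-centered
group-mean deviations are shrunk toward zero by their estimated
signal-to-noise ratio; and the stability value is the group average of
|shrunken inter-group effect| + √(intra-group variance / group size),
lower = more stable. With only two candidate assays the bias correction is
not identifiable (it divides by k − 2) and the raw residual variance is
used. Platform concordance is summarized by ordinary least-squares R² and
Spearman rank correlation over matched samples.

## The synthetic cohort generator

`generate_cohort()` emulates the study design — 10 subjects × 4
anticoagulant groups — with known ground truth at every level:

* **Repertoire**: ~350 miRNAs; log-normal population weights with a forced
  heavy tail (miR-451a + miR-486-5p ≈ 38% of baseline reads, mirroring the
  extreme concentration of real plasma profiles); panel members set to
  realistic mid-range weights; miR-30e-5p set low (~0.15%) but high enough
  to be reliably counted at the default depth — it is the qPCR
  normalization control, and a reference miRNA drowned in counting noise
  would make cross-platform comparisons meaningless at desk scale.
* **Subject baselines**: per-subject log-normal jitter (SD 0.15 log2)
  around the population profile, shared across that subject's four
  samples — this is what the DE blocking term absorbs.
* **Hemolysis**: per-sample fraction *h* ~ Gamma(shape 2) with group means
  ACD/Citrate/CTAD/EDTA = 0.030/0.030/0.025/0.150; EDTA must be strictly
  largest (an all-equal configuration, e.g. all zero, is allowed for null
  experiments). RBC-panel abundances are multiplied by `1 + 30·h`
  (hemolysis-susceptible members by half that coefficient) and
  renormalized. The transfer coefficient is a free parameter of the
  generator — the source study measures no such quantity — chosen once so
  that the miRNA-based hemolysis indicators are strongly informative of the
  planted contamination (rank correlation > 0.8), as they are in real
  cohorts.
* **Counts**: multinomial at a per-sample miRNA depth derived from a
  Poisson total (default mean 1e5 reads) and a Beta-distributed miRNA-read
  percentage (mean ≈ 75%).
* **Reads** (optional): each read is a canonical or isomiR insert — 3'
  trims (rate 0.30), 3' extensions (0.15, 70% templated off the hairpin),
  5' offsets (0.10), internal SNVs (0.05); variants that would leave the
  16–28 nt window are emitted canonical — wrapped in 4 randomized bases per
  end plus the adapter.
* **Absorbance**: `A414 = 0.05 + 2.5·h`, `A385 = 0.04 + 0.7·h`, each with
  Gaussian noise (SD 0.005).
* **Cq**: `Cq = 13.2 − log2(abundance proportion) + N(0, 0.15)`;
  degenerate samples are shifted +6 cycles (diluted miRNA input).
* **Degenerate samples** (rate 0.05): miRNA reads diluted with
  uniform-random sequences to a 5–12% miRNA fraction and a 55–75%
  unaligned fraction — enough to trip the 15% and 50% QC gates, without
  modeling real contaminant classes.

A single master seed drives reference, cohort and per-sample read
substreams, so any artifact is reproducible in isolation.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: extracellular-vesicle sorting, ligation sequence
bias (isomiR rates are uniform across miRNAs), qPCR efficiency curves
beyond the log-linear map, genome-wide multi-mapping ambiguity, and
between-run batch effects. Conclusions about the *pipeline's* correctness
transfer; conclusions about effect sizes in real plasma do not.

## Numerical choices and degenerate inputs

* Assignment tie-breaks are fully deterministic (mismatches, |offset|,
  name); the dictionary and scan paths provably agree and are tested
  against exhaustive enumeration.
* The Shannon index errors on all-zero vectors; CPM errors on zero library
  sizes, naming the sample.
* PCA drops constant rows with a warning before unit-variance scaling and
  truncates to matrix rank with a warning.
* NormFinder variance estimates are clamped at zero; the inter-group
  variance shrinkage handles the zero-signal case exactly.
* TMM factors inherit the canonical trimming constants (30% on M, 5% on
  A); factors multiply to 1 within 1e−9.
* Non-detect Cq values are rejected rather than imputed: in the emulated
  design every assay is detectable in every sample, so no imputation
  policy can be derived or validated.

## Problem sizes used by the packaged checks

The test suite and the acceptance script run entirely on synthetic data at
desk scale, chosen as the smallest sizes at which every targeted effect is
comfortably resolvable: cohorts of 350 miRNAs × 40 samples at 1e5
reads/sample for profile-level statistics (50 seeds for structure
recovery), 200k simulated reads for the rank-recovery check of the full
read path, 1,100+ randomized reads against 5-hairpin references for
aligner-oracle equivalence, and 250-gene × 16-sample negative-binomial
simulations (dispersion 0.1) for DE calibration.

## Known limitations

* The aligner is reference-bounded: reads from miRNAs absent from the
  reference are reported unaligned, never discovered de novo.
* Counts from real FASTQ will differ from pipelines that remap against a
  whole genome, particularly for miRNA families with near-identical
  members, where the name tie-break is a convention rather than a
  biological claim.
* NormFinder stability values for two-assay panels use the documented
  fallback and are not comparable with k ≥ 3 runs.
* The qPCR model assumes 100% amplification efficiency throughout.
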