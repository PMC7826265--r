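---
title: "Methods: consensus somatic calls in miRNA biogenesis genes and their miRNA-level consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus somatic calls in miRNA biogenesis genes and their miRNA-level consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutatlas)
```

`mutatlas` analyzes somatic mutations in miRNA biogenesis genes and their
consequences on miRNA expression, isomiR composition and clinical outcome.
This vignette documents the statistical procedures, the tunable parameters
and their defaults, the synthetic data model used for validation, and the
design choices made where several defensible options existed.

## Consensus calling model

Multi-caller somatic call sets disagree; the package treats a call as
credible when it carries a `PASS` filter status *and* satisfies four
reliability criteria on read support and quality:

1. **Alt-read support** — at least 2 alt-supporting tumor reads, enforced
   only when the matched normal shows no alt-supporting read. When the
   normal does carry alt reads, support is judged by criterion 2 instead.
   (The alternative — enforcing the 2-read minimum unconditionally — is a
   defensible reading; the conditional form follows the rule that a
   non-zero normal turns the problem into a contrast of frequencies.)
2. **Frequency contrast** — tumor alt-allele frequency at least 5× the
   normal's, enforced when the normal frequency is positive. The boundary
   is inclusive (exactly 5× passes) and a zero normal frequency satisfies
   the criterion vacuously (the ratio is infinite).
3. **Somatic score** — SSC > 30, strict, for the callers that report it
   (VarScan2, SomaticSniper).
4. **Base quality** — tumor alt BQ > 20, strict, for MuSE and MuTect2.

An absent SSC or BQ field is never grounds for rejection: the criteria are
caller-specific, not missing-data penalties. Filtering is a pure predicate
(`reliability_pass()`), so it is total and order-independent; the test suite
verifies exact agreement with an independently written one-record-at-a-time
evaluation of the conjunction on 10^4 randomized records.

Merging deduplicates on the key (sample, chrom, pos, ref, alt) after
left-normalizing indels (shared suffix then shared prefix trimmed, keeping
the VCF anchor base), so the same deletion padded differently by two callers
collapses to one record whose `callers` field is the union of supporters.
Merging is idempotent and monotone: adding one caller's list never removes
or alters existing keys.

The analyzed territory is each gene's coding exons extended by 2 nt on both
sides, which makes canonical splice-site disruptions part of the analyzed
region. Cross-gene overlapping regions are rejected at load time (the panel
genes do not overlap; supporting overlap would make gene assignment
ambiguous). Mutation "coding length" for density purposes is the summed
extended interval length.

Consequences are classified against simplified one-transcript CDS models:
codon translation for SNVs (with first/last-codon hits classed
`start_stop`), frame arithmetic for indels (`frameshift` iff the length
change is not a multiple of 3), positions in the 2-nt extensions as
`splice_site`. This is deliberately not a full VEP-style annotator: no
multi-transcript ranking, no HGVS engine beyond simplified `p.` labels. The
*deleterious* class is frameshift + nonsense + splice-site; start/stop and
complex events are tallied separately.

## Atlas statistics

*Hypermutation.* Samples with more than 10,000 exome-wide mutations
(strictly greater) are excluded together with their panel mutations before
any frequency or enrichment statistic, since their panel hits are dominated
by passengers.

*Overmutation.* For gene *g* and cancer *c* the 2×2 table counts mutations
(not mutated samples) in {*g*, other panel genes} × {*c*, pan-cancer
excluding *c*}; the test is one-sided (enrichment) Fisher. Both choices are
configurable (`count_unit`, `include_self`) because either convention is
defensible; the defaults avoid self-comparison of the tested cancer with a
background that contains it. Correction is Bonferroni over genes × cancers:
with a 29-gene, 33-cancer atlas, 0.05 / (29 × 33) ≈ 5 × 10⁻⁵, which is why
a nominal p < 0.00005 is the adjusted-significance landmark.

*Hotspots.* A hotspot is a (gene, residue) with ≥ `min_recurrence`
point-mutation recurrences; the default of 3 is the smallest recurrence the
atlas treats as non-accidental, and indels are keyed by identical
protein-level label because their exact nucleotide representation varies.
Synonymous recurrences are reported (with a per-consequence breakdown)
rather than silently dropped, since recurrent synonymous positions can be
real signals; downstream analyses that want missense-only hotspots filter on
the breakdown.

*Printed percentages* round half-up to the nearest integer
(`round_half_up()`), matching the convention of published summary tables
(base R's banker's rounding would print 44.5% as 44%).

## miRNA differential analysis

*Detectability.* A miRNA is kept when its level is exactly 0 in at most 30%
of samples (pan-cancer) or 10% (single-cancer); zero is "undetectable" by
definition of the input dialect.

*Per-cancer normalization.* To pool heterogeneous cancers, each miRNA is
transformed per cancer as x′ = (x − median) / max|x − median| (0/0 → 0).
This yields per-cancer median exactly 0 and range within [−1, 1] and is
idempotent. A min–max variant would also bound the range but not preserve
the median exactly; preserving the median was prioritized because group
effects are measured as differences of medians. Cancers with a single
sample are rejected (the transform is undefined).

*Test.* The group comparison is a two-sided Wilcoxon rank-sum test —
distribution-free, appropriate for the bounded normalized scale — with
exact enumeration when the smaller group has ≤ 8 observations (tie-broken
to the normal approximation) and the tie-corrected normal approximation
otherwise. Effects are differences of medians on normalized scales and
log2 fold changes of medians (pseudocount 1 RPM) on the raw scale. Volcano
style outputs use nominal p < 0.05; Benjamini–Hochberg values are emitted
as an additional column rather than replacing the nominal ones.

*Reference re-normalization.* Because standard RPM normalization divides by
total miRNA-mapped reads, a global 5p deficit mechanically inflates all
other miRNAs. Re-expressing each sample as log2((x + 1)/(x_ref + 1)) against
miR-451a — whose maturation is DICER1-independent, so its true level is
unaffected by DICER1 mutations — removes any per-sample global factor
exactly (the invariance is asserted algebraically in the tests at machine
precision with pseudocount 0). The log-ratio form is the default; a plain
ratio is available (`log = FALSE`).

*Arm asymmetry.* Arms are parsed from the canonical `-5p`/`-3p` identifier
suffix; miRNAs without a suffix are `unspecified` and excluded from the
arm × direction Fisher test.

## isomiR analysis

Only 3p-miRNAs with median total abundance ≥ 100 RPM enter the analysis
(low-expression isoform fractions are unstable). "Median across samples"
was chosen over mean or minimum as the robust reading of a cohort-level
expression cutoff; it is a parameter (`min_rpm`, `select_high_expression_3p`).
The main 5′ end is defined cohort-wide on the *reference* (unmutated)
samples as the offset with the largest summed per-sample read share — a
scale-free definition, so per-sample library-size factors cannot move it —
and group comparisons therefore address the same isoform in every sample.
Per sample, main + upstream + downstream fractions sum to 1 by construction
(asserted to 1e−9). Group comparisons are rank-sum tests per miRNA plus a
pooled test on per-sample median fractions; groups with fewer than 3
informative samples yield `NA` with a warning rather than a fragile p-value.

## Clinical association

Survival uses the Kaplan–Meier product-limit estimator, the two-group
log-rank test, and a Cox proportional-hazards fit on the group indicator
(Breslow tie handling) to orient the effect as a hazard ratio. Stage
associations dichotomize early (I–II) versus late (III–IV) — sub-stages
(IIIA…) are collapsed to their Roman numeral — and use the
Cochran–Mantel–Haenszel test stratified by cancer type, continuity
correction off; with a single stratum the statistic reduces to the
(n−1)/n-scaled Pearson chi-square, which is the CMH closed form. Deletion
on the thresholded copy-number scale is call ≤ −1 (shallow or deep),
amplification ≥ +1.

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` emits every input the pipeline consumes, with planted
ground truth. Default study conditions: 3 cancer types × 60 samples, a
4-gene panel (SMAD4-, SMAD2-, DICER1-, TNRC6A-like, with down-scaled CDS
lengths — planting and recovery are length-independent), an SMAD4-style
hotspot concentrated in gastrointestinal labels and a DICER1-style RNase
hotspot in the endometrial label, per-gene deleterious/missense/synonymous
rates of 3%/2%/2%, one expected noise call per sample per caller, 2%
hypermutated samples, an arm effect of (−0.5, +0.5) on the normalized scale
for DICER1-hotspot carriers sparing miR-451a, and a survival hazard ratio
of 2 for hotspot/deleterious carriers of the arm-effect gene.

Generative choices (the published analyses imply effect structure but no
generative model, so these are the package's own):

* **Expression.** Per-miRNA baselines are log-normal on the RPM scale;
  noise is additive Gaussian (SD 0.25) on the normalized scale and
  multiplicative log-normal (sdlog 0.5) on the RPM scale, so both level
  dialects are testable. Dropout zeros (2% per cell; two miRNAs at 35% to
  exercise the detectability filter) model undetectable signals. Arm shifts
  are additive on the normalized scale and act as 2^shift factors on RPM.
* **Survival.** Exponential event times (baseline median 1095 days ≈ 3
  years, a typical advanced-cancer median), proportional hazards, censoring
  uniform over a 10-year follow-up — at the default hazard this yields ≈30%
  censoring.
* **isomiRs.** 5′ offsets −1/0/+1 with a Beta-distributed main fraction
  (median ≈ 0.95, matching the observed concentration of 5′ ends); a
  configurable reduction of the main fraction in mutated samples supports
  power studies.
* **Noise calls** are constructed to violate *exactly one* named
  reliability criterion while satisfying the rest (`emit_noise_call()`), so
  filter behavior is testable per criterion. Non-`PASS` decoy records
  exercise the extraction step.
* **Determinism.** Each file family draws from its own stream seeded by a
  fixed offset from `config$seed`, samples in a fixed order, so the bundle
  is byte-identical under the same seed and earlier samples are unchanged
  when the cohort grows.

What the generator does *not* emulate: read-level data (no FASTQ/BAM),
trinucleotide mutational signatures, germline variants, batch effects,
correlated miRNA co-expression structure, or per-cancer differences in
miRNA baselines. Passing tests therefore demonstrate correctness of the
statistical machinery and bookkeeping under a clean generative model, not
robustness to the full messiness of real tumor data.

The caller VCF dialects are an emulation contract of the package (field
layouts documented in `?caller-dialects`), not a claim about any archive's
internal encodings.

## Problem sizes and numerical tolerances

The validation suite exercises: exact-agreement filter checks on 10^4
random records; consensus-vs-ground-truth conservation over 100 seeded
zero-noise cohorts; Fisher p-values against direct hypergeometric
enumeration on all 2×2 tables with total ≤ 30 plus 5,000 random tables with
margins ≤ 60 (|Δp| ≤ 1e−12); type-I calibration of the differential test on
10^4 null miRNAs (observed rate ≤ 0.06 at nominal 0.05); arm-shift recovery
at n = 200/200 over 100 replicates, before and after reference
re-normalization; and Cox hazard-ratio recovery at n = 500/500 with 30%
censoring over 200 replicates. At those survival conditions the sampling SD
of the HR estimate is ≈ 0.16, so a ±0.3 recovery band around the true
hazard is a ≈1.9σ interval — the estimator is unbiased, and individual
replicates land outside such a band ≈6% of the time by construction.

Floating-point tolerances: normalization invariants at 1e−12, isomiR
fraction conservation at 1e−9, oracle agreements at 1e−9–1e−12; printed
percentages are compared after half-up integer rounding.

## Known limitations

* One transcript model per gene; consequence ranking across isoforms is out
  of scope.
* The consequence classifier handles SNVs and simple anchored indels;
  complex substitutions fall into the `other` class.
* Pan-cancer group comparisons pool normalized values across cancers rather
  than stratifying by cancer; with very unbalanced carrier distributions a
  stratified test would be more conservative.
* The CLI is a thin wrapper; scripted use of the exported functions is the
  primary interface.
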