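# mutatlas

Somatic mutations in the genes that make and operate microRNAs — *DROSHA*,
*DGCR8*, *DICER1*, the Argonautes, *SMAD2/4* and the other ~25 members of the
miRNA biogenesis machinery — are individually rare but collectively common in
tumors, and specific mutation types leave characteristic fingerprints on the
miRNA transcriptome (e.g. RNase-domain hotspot mutations in DICER1 suppress
5p-arm miRNAs). `mutatlas` is an R toolkit for building such a pan-cancer
mutation atlas and tracing its downstream consequences. It is aimed at cancer
genomics analysts working with multi-caller somatic call sets, small-RNA
expression matrices and clinical tables.

The package implements the full chain:

1. **Consensus somatic calls.** Per-sample VCFs from four caller dialects
   (MuSE, MuTect2, VarScan2, SomaticSniper) are read, restricted to
   `PASS` records, and filtered by four reliability criteria: (i) ≥ 2
   alt-supporting tumor reads when the matched normal has none; (ii) tumor
   alt-allele frequency ≥ 5× the normal frequency when the normal frequency
   is positive; (iii) somatic score SSC > 30 (VarScan2/SomaticSniper);
   (iv) alt base quality BQ > 20 (MuSE/MuTect2). Calls are merged across
   callers without duplication (indels are left-normalized to a canonical
   key) and restricted to the analyzed gene territory: coding exons extended
   by 2 nt so that definitive splice-site mutations are captured.
2. **Atlas statistics.** Hypermutated samples (> 10,000 exome-wide
   mutations) are excluded; consequences are classified against simplified
   transcript models (deleterious := frameshift + nonsense + splice-site);
   mutation density is mutations per kbp of analyzed sequence. Per-gene,
   per-cancer *overmutation* is tested with a one-sided Fisher's exact test
   of the 2×2 table {gene, other panel genes} × {cancer, pan-cancer
   background}, Bonferroni-corrected over genes × cancers (with 29 genes and
   33 cancers, adjusted significance at 0.05 corresponds to nominal
   p < 0.00005). Recurrently mutated amino-acid residues (*hotspots*,
   ≥ 3 recurrences by default) are detected per (gene, residue), indels by
   identical protein-level label.
3. **Mutation-group miRNA analysis.** miRNAs undetectable (level = 0) in
   > 30% of pan-cancer samples (> 10% within one cancer) are dropped; levels
   are made comparable across cancers by the per-cancer transform
   x′ = (x − median) / max|x − median| (median 0, range within [−1, 1]).
   Carriers of a mutation class are compared to samples free of any mutation
   in the gene by a two-sided Wilcoxon rank-sum test per miRNA; effects are
   differences of medians (normalized scale) or log2 fold changes of medians
   (RPM scale). To rule out total-count normalization artifacts, RPM levels
   can be re-expressed as per-sample log2 ratios to miR-451a — a miRNA whose
   maturation bypasses DICER1 — which is invariant to per-sample global
   scaling. 5p/3p arm asymmetry among significant miRNAs is tested with a
   Fisher's exact test on the arm × direction table.
4. **isomiR 5′-heterogeneity.** For highly expressed 3p-miRNAs
   (median ≥ 100 RPM), the main 5′-isoform fraction is computed per sample
   and compared between mutation groups.
5. **Clinical association.** Kaplan–Meier curves with log-rank tests and a
   Cox proportional-hazards fit (Breslow ties) for survival; the
   Cochran–Mantel–Haenszel test (stratified by cancer type) for stage;
   Fisher tests of co-occurrence with thresholded copy-number deletions.
6. **Synthetic cohort generator.** `generate_cohort()` emits the complete
   input bundle — caller VCFs, gene regions + transcript models, expression
   matrices (both dialects), isomiR, clinical and copy-number tables — with
   *planted* hotspots, deleterious mutations, filter-failing noise calls,
   arm-asymmetric expression shifts sparing miR-451a, and a survival hazard,
   plus a ground-truth JSON, so every stage can be validated against a known
   answer.

## Worked example

A complete run on a synthetic cohort (90 samples across PAAD/COAD/UCEC, a
planted SMAD4-like hotspot, a DICER1-like RNase hotspot driving a
5p-down/3p-up arm shift, and a survival hazard for carriers):

```r
library(mutatlas)

cfg <- cohort_config(n_samples_per_cancer = 30, seed = 42)
bundle <- generate_cohort(cfg, "cohort")

clinical <- read.delim(file.path("cohort", "clinical.tsv"))
calls <- do.call(rbind, lapply(bundle$vcf_files, function(f) {
  caller <- sub("^.*_([A-Za-z0-9]+)\\.vcf$", "\\1", basename(f))
  apply_reliability_filters(read_caller_file(f, caller))
}))
muts <- merge_callers(calls, clinical)
muts <- restrict_to_regions(muts, read_gene_regions(bundle$files["regions"]))
muts <- classify_consequence(muts, read_cds_models(bundle$files["cds_models"],
                                                   bundle$files["genome"]))

ex <- exclude_hypermutated(muts, flag_hypermutated(clinical))
summ <- classification_summary(ex$muts)
hs <- detect_hotspots(ex$muts)
```

which recovers exactly the planted structure:

```
retained 33 mutations in 88 samples; 5 deleterious
    gene protein_pos   label count
1  SMAD4          50  p.P50A    10
2 DICER1         250 p.F250C     8
```

Continuing with the differential arm analysis and survival for DICER1
hotspot carriers:

```r
groups <- define_groups(ex$muts, ex$samples, "DICER1",
                        class_hotspot(hs$protein_pos[hs$gene == "DICER1"]))
res <- diff_test(norm, groups$mutated, groups$reference)  # norm: see vignette
arm_asymmetry(res)$counts
km_logrank(clinical, groups$mutated, groups$reference)
```

```
    direction
arm  down up
  5p   29  0
  3p    0 29
arm x direction Fisher p = 6.7e-17
log-rank p = 0.0224, Cox HR = 2.50
```

Every significant downregulated miRNA is a 5p-arm and every upregulated one
a 3p-arm — the planted DICER1-hotspot fingerprint — and the carriers' planted
survival disadvantage (true HR 2) is detected.

The same chain is available as one orchestrated run
(`run_pipeline(run_config(...))`, YAML-configured, with a hashed manifest and
a markdown report via `render_report()`), or from a shell through the thin
CLI in `inst/scripts/mutatlas`.

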