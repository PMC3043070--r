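# mirpivot

Integrated analysis of paired miRNA–mRNA expression cohorts: exact
combinatorial differential expression, exact ranked-list gene-set
enrichment, and a pivot-miRNA framework linking miRNA expression to
biological processes.  Written for transcriptomics analysts working with
tumor cohorts profiled on both a miRNA and an mRNA platform, with sample
annotations (intrinsic subtype, receptor status, proliferation markers)
driving two-class contrasts.

## The statistics

**TNoM (threshold number of misclassifications).**  For a feature measured
in two classes of sizes n₁ and n₀, TNoM is the minimum number of samples
misclassified by any single expression threshold under either label
orientation.  Its null distribution over all C(n₁+n₀, n₁) equiprobable
label arrangements is exact and distribution-free; `mirpivot` computes it
by a lattice-path dynamic program (the label sequence maps to a ±1 walk,
and TNoM ≤ k iff the walk leaves the band (k, N−k)), accumulating the
band-exit probability mass directly so that p-values far below machine
epsilon are exact.  Tables report k, the exact p, a Welch t-test p, log2
fold change, and Benjamini–Hochberg q-values.

**mHG (minimum hypergeometric).**  For a gene set H of size B marked along
a ranked universe of N genes by the label vector λ (prefix sums b_n), the
statistic is

    s = min over n of HGT(b_n; N, B, n),   HGT(b; N, B, n) = P(X ≥ b),
    X ~ Hypergeometric(N, B, n)

and its exact p-value P(mHG ≤ s) — which needs no correction for the
optimized cut — is computed by a second lattice DP that absorbs label
arrangements the first time they attain a tail ≤ s.  Scores are carried in
log space, so enrichments at the 10⁻³⁰⁰ scale are handled.

**Pivot integration.**  mRNAs are ranked by Spearman correlation to a pivot
miRNA (scheme B), by signed differential expression (scheme A), or by
TargetScan-style context scores (scheme C), and any GMT gene-set collection
is tested against those rankings.  The miRNA × gene-set association matrix
stores signed scores (±log₁₀ p, positive when the set is enriched among the
pivot's positive correlatees), and the concordance of those signs with a
phenotype contrast is summarized by a Pearson correlation across miRNAs.
Predicted-target anti-correlation is tested by taking a pivot's top 2000
predicted targets as the set and its anti-correlation ranking as the list.

Preprocessing utilities (replicate averaging with an either-array detection
rule, 75th-percentile scaling, log2 transform, <10%-detection filtering,
top-variance selection), proliferation phenotype rules (Ki67 × mitotic
index → HP/LP), lysate-microarray z-score hit calling, and a synthetic
paired-cohort generator with a ground-truth manifest complete the pipeline.

## Worked example

Simulate a 60-sample cohort (two subtypes, duplicate hybridizations,
detection dropout) with 5 planted differential miRNAs at 3 SD and a 60-gene
co-expression module coupled to two pivot miRNAs; preprocess; test.

```r
library(mirpivot)

cfg <- cohort_config(
  n_samples = 60, n_mirna = 150, n_mrna = 1000,
  subtype_props = c("basal-like" = 0.5, "luminal-A" = 0.5),
  de = list(n_features = 5, effect_sd = 3, direction = "both",
            on = "subtype", group_a = "basal-like", group_b = "luminal-A"),
  modules = list(list(name = "cellcycle", n_genes = 60, loading = 0.7,
                      pivots = 1:2, signs = c(1, 1), class_effect = 2)),
  seed = 42)
cohort <- generate_cohort(cfg)
cohort$mirna
#> ExpressionMatrix: 150 features x 120 samples (linear scale), with detection calls

groups <- setNames(cohort$annotations$replicate_group,
                   cohort$annotations$sample_id)
mirna <- detection_filter(log2_transform(
  percentile_normalize(average_replicates(cohort$mirna, groups))$matrix))

ann <- cohort$annotations[!duplicated(cohort$annotations$replicate_group), ]
de <- differential_expression_table(
  mirna,
  ann$replicate_group[ann$subtype == "basal-like"],
  ann$replicate_group[ann$subtype == "luminal-A"])
head(as.data.frame(de), 6)
#>   feature_id  k       tnom_p          t_p    log2_fc direction            q
#> 1    miR-114  1 1.014674e-15 1.763446e-19  3.0738249        up 7.610055e-14
#> 2    miR-124  1 1.014674e-15 1.121075e-17  3.0070331        up 7.610055e-14
#> 3    miR-143  2 2.993288e-14 1.526533e-19 -3.0709573      down 1.496644e-12
#> 4    miR-012  3 5.787024e-13 1.347342e-16  2.9852328        up 2.170134e-11
#> 5    miR-127  5 9.236091e-11 2.366837e-15 -2.6618353      down 2.770827e-09
#> 6    miR-100 16 2.530062e-03 2.099671e-02  0.7429679        up 6.325156e-02
```

The five planted miRNAs (miR-114, miR-124, miR-143, miR-012, miR-127) fill
the top five rows with the planted directions: `k` is the number of samples
the best expression threshold misclassifies, `tnom_p` its exact
combinatorial p-value, and `q` the BH-adjusted value across the 150
features.  The sixth row shows the null background (k = 16 of a possible
30, q > 0.05).

The association matrix then recovers the module coupling — pivots miR-001
and miR-002 carry signed scores of 97.3 and 90.3 (i.e. mHG p ≈ 10⁻⁹⁷ among
their positive correlatees) against decoy-set background scores of |score|
≈ 0–3:

```r
sets <- generate_gene_sets(cohort$truth, n_decoys = 20)
am <- association_matrix(mirna[1:5, ], cohort$mrna, sets)
round(am$score[, 1:4], 2)
#>         cellcycle decoy001 decoy002 decoy003
#> miR-001     97.30    -1.43    -1.14    -1.35
#> miR-002     90.28    -0.94    -1.72    -1.47
#> miR-003      8.50    -0.79     0.22     0.72
#> miR-004    -20.17    -2.60     2.81     0.81
#> miR-005     3.96    -0.80     0.94     0.43
```

(Unplanted miRNAs can pick up moderate scores by chance correlation with
the module's shared latent factor — a real property of factor-structured
data, which is why the recovery tests compare against the planted cells'
much larger magnitudes.)

A thin command-line front end over the same functions lives at
`inst/cli/mirpivot.R` (subcommands `simulate`, `preprocess`, `de`,
`enrich`, `target-enrich`, `pivot-matrix`, `classify`, `lma`).

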