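test_that("generated cohorts have the configured shape and are seed-stable", {
  cfg <- cohort_config(n_samples = 30, n_mirna = 40, n_mrna = 120,
                       replicates = 2, seed = 3)
  ch <- generate_cohort(cfg)
  expect_identical(dim(ch$mirna), c(40L, 60L))  # 2 arrays per sample
  expect_identical(dim(ch$mrna), c(120L, 30L))
  expect_identical(nrow(ch$annotations), 60L)
  expect_identical(ch$mirna$scale, "linear")
  expect_identical(ch$mrna$scale, "log2")
  expect_false(is.null(ch$mirna$detection))
  ch2 <- generate_cohort(cfg)
  expect_identical(ch$mirna$values, ch2$mirna$values)
  expect_identical(ch$mrna$values, ch2$mrna$values)
  expect_identical(ch$annotations, ch2$annotations)
})

test_that("invalid configs fail validation with a list of violations", {
  expect_error(cohort_config(subtype_props = c("basal-like" = 0.5)),
               "sum to 1")
  expect_error(cohort_config(n_samples = 1), "n_samples")
  expect_error(cohort_config(de = list(n_features = 1000, effect_sd = 2,
                                       on = "subtype", group_a = "basal-like",
                                       group_b = "luminal-A")),
               "n_features")
})

test_that("planted differential miRNAs are recovered by the pipeline", {
  cfg <- cohort_config(
    n_samples = 60, n_mirna = 150, n_mrna = 50,
    subtype_props = c("basal-like" = 0.5, "luminal-A" = 0.5),
    de = list(n_features = 10, effect_sd = 4, direction = "both",
              on = "subtype", group_a = "basal-like", group_b = "luminal-A"),
    seed = 1)
  ch <- generate_cohort(cfg)
  mf <- preprocess_mirna(ch)
  ann <- sample_level_annotations(ch)
  de <- differential_expression_table(
    mf, ann$sample_id[ann$subtype == "basal-like"],
    ann$sample_id[ann$subtype == "luminal-A"])
  top15 <- de$feature_id[1:15]
  expect_true(all(ch$truth$de$feature_id %in% top15))
  # planted direction is recovered too
  hit <- merge(as.data.frame(de), ch$truth$de, by = "feature_id")
  expect_identical(hit$direction.x, hit$direction.y)
})

test_that("detection dropout decreases with intensity", {
  cfg <- cohort_config(n_samples = 40, n_mirna = 200, n_mrna = 50,
                       baseline_log2_sd = 2.5, seed = 6)
  ch <- generate_cohort(cfg)
  mean_log2 <- rowMeans(log2(ch$mirna$values))
  det_rate <- rowMeans(ch$mirna$detection)
  expect_gt(cor(mean_log2, det_rate, method = "spearman"), 0.3)
})

test_that("recovery count is monotone in planted effect size", {
  recovered <- function(effect, seed) {
    cfg <- cohort_config(
      n_samples = 40, n_mirna = 100, n_mrna = 50,
      subtype_props = c("basal-like" = 0.5, "luminal-A" = 0.5),
      de = list(n_features = 8, effect_sd = effect, direction = "both",
                on = "subtype", group_a = "basal-like",
                group_b = "luminal-A"),
      seed = seed)
    ch <- generate_cohort(cfg)
    mf <- preprocess_mirna(ch)
    ann <- sample_level_annotations(ch)
    de <- differential_expression_table(
      mf, ann$sample_id[ann$subtype == "basal-like"],
      ann$sample_id[ann$subtype == "luminal-A"])
    sum(de$feature_id[de$q < 0.05] %in% ch$truth$de$feature_id)
  }
  for (seed in 1:5) {
    counts <- vapply(c(0.5, 1, 2, 4), recovered, numeric(1), seed = seed)
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("gene-set generation yields modules plus disjoint decoys", {
  cfg <- cohort_config(n_samples = 30, n_mirna = 20, n_mrna = 400,
                       modules = list(
                         list(name = "m1", n_genes = 30, loading = 0.7,
                              pivots = 1:2, signs = c(1, -1)),
                         list(name = "m2", n_genes = 20, loading = 0.5,
                              pivots = 3)),
                       seed = 2)
  ch <- generate_cohort(cfg)
  sets <- generate_gene_sets(ch$truth, n_decoys = 50,
                             decoy_size_range = c(10, 30))
  expect_length(sets, 52L)
  core <- unlist(ch$truth$modules)
  for (nm in grep("decoy", names(sets), value = TRUE)) {
    expect_length(intersect(sets[[nm]], core), 0L)
  }
  sets2 <- generate_gene_sets(ch$truth, n_decoys = 50,
                              decoy_size_range = c(10, 30))
  expect_identical(unclass(sets)[], unclass(sets2)[])  # seed-stable
  expect_error(generate_gene_sets(ch$truth, 1, c(10, 4000)), "exceeds")
})

test_that("target tables put planted pairs at the most negative scores", {
  cfg <- cohort_config(n_samples = 30, n_mirna = 20, n_mrna = 3000,
                       targets = list(pivot = 1, n_targets = 50, rho = 0.5),
                       seed = 1)
  ch <- generate_cohort(cfg)
  tab <- generate_target_table(ch$truth, n_background_pairs = 5000)
  expect_identical(nrow(tab), 5050L)  # 50 planted + 5000 distinct background
  planted_key <- paste(ch$truth$targets$pivot_id, ch$truth$targets$gene_id)
  is_planted <- paste(tab$mirna, tab$gene) %in% planted_key
  expect_lt(mean(tab$score[is_planted]), mean(tab$score[!is_planted]))
  top50 <- order(tab$score)[1:50]
  expect_gte(mean(is_planted[top50]), 0.8)
})

test_that("truth manifests round-trip through the TSV report", {
  cfg <- cohort_config(
    n_samples = 20, n_mirna = 15, n_mrna = 60,
    de = list(n_features = 3, effect_sd = 2, direction = "both",
              on = "subtype", group_a = "basal-like", group_b = "luminal-A"),
    modules = list(list(name = "m1", n_genes = 10, loading = 0.7,
                        pivots = 1:2, signs = c(1, -1), class_effect = 2)),
    targets = list(pivot = 3, n_targets = 5, rho = 0.4),
    seed = 4)
  ch <- generate_cohort(cfg)
  f <- tempfile(fileext = ".tsv")
  truth_report(ch$truth, f)
  back <- read_truth_report(f)
  expect_equal(back, ch$truth)
  # empty truth gives a header-only file
  truth_report(synthetic_truth(), f)
  expect_length(readLines(f), 1L)
})
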