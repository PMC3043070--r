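test_that("spearman ranking orders genes by correlation to the pivot", {
  vals <- rbind(c(1, 2, 3), c(3, 2, 1), c(5, 5, 5), c(1, 3, 2))
  m <- toy_matrix(vals, features = c("up", "down", "flat", "mid"))
  pivot <- stats::setNames(c(1, 2, 3), sample_ids(m))
  cor_rank <- spearman_rank_genes(pivot, m, "descending_correlation")
  expect_identical(cor_rank$gene[1], "up")
  expect_equal(cor_rank$score[1], 1)
  expect_identical(cor_rank$gene[4], "down")
  anti_rank <- spearman_rank_genes(pivot, m, "ascending_correlation")
  expect_identical(anti_rank$gene[1], "down")
  expect_equal(anti_rank$score[1], -1)
  # constant gene sits at rho = 0, between the signed correlations
  expect_equal(cor_rank$score[cor_rank$gene == "flat"], 0)
  expect_error(spearman_rank_genes(unname(pivot), m), "sample ids")
})

test_that("correlated and anti-correlated rankings are exact reverses", {
  set.seed(31)
  vals <- matrix(rnorm(50 * 12), 50, 12)
  vals[c(4, 9), ] <- 1  # constant rows produce rho ties at 0
  m <- toy_matrix(vals)
  pivot <- stats::setNames(rnorm(12), sample_ids(m))
  a <- spearman_rank_genes(pivot, m, "descending_correlation")
  b <- spearman_rank_genes(pivot, m, "ascending_correlation")
  expect_identical(b$gene, rev(a$gene))
})

test_that("differential ranking puts up-regulated significant features first", {
  de <- data.frame(feature_id = c("up1", "dn1", "mid"),
                   tnom_p = c(0.001, 0.001, 1),
                   direction = c("up", "down", "up"),
                   stringsAsFactors = FALSE)
  rk <- rank_by_differential(de)
  expect_identical(rk$gene, c("up1", "mid", "dn1"))
  expect_equal(rk$score, c(3, 0, -3))
  # all-ties order is lexicographic
  de2 <- data.frame(feature_id = c("b", "a", "c"), tnom_p = rep(1, 3),
                    direction = rep("up", 3), stringsAsFactors = FALSE)
  expect_identical(rank_by_differential(de2)$gene, c("a", "b", "c"))
})

test_that("target-score ranking is ascending with exclusions and tie-break", {
  tab <- target_score_table(rep("miR-1", 4), c("g1", "g2", "g4", "g3"),
                            c(-0.10, -0.40, -0.25, -0.25))
  rk <- rank_by_target_score("miR-1", tab, c("g1", "g2", "g3", "g4", "g9"))
  expect_identical(rk$gene, c("g2", "g3", "g4", "g1"))
  expect_false("g9" %in% rk$gene)   # not in the table
  expect_error(rank_by_target_score("miR-9", tab, "g1"), "miR-9")
})

test_that("signed association scores pick the better-supported direction", {
  expect_equal(signed_association_score(0.01, 0.5), 2)
  expect_equal(signed_association_score(0.5, 0.001), -3)
  expect_equal(signed_association_score(1, 1), 0)
})

test_that("association matrix has input shape and deterministic rows", {
  set.seed(41)
  S <- 20
  mrna <- toy_matrix(matrix(rnorm(100 * S), 100, S),
                     features = sprintf("g%03d", 1:100))
  pv <- matrix(rnorm(2 * S), 2, S)
  pv <- rbind(pv, pv[1, ])  # third pivot duplicates the first
  piv <- toy_matrix(pv, features = c("p1", "p2", "p1dup"),
                    samples = sample_ids(mrna))
  sets <- gene_set_collection(list(s1 = sprintf("g%03d", 1:10),
                                   s2 = sprintf("g%03d", 40:60),
                                   s3 = sprintf("g%03d", 90:100)))
  am <- association_matrix(piv, mrna, sets)
  expect_identical(dim(am$score), c(3L, 3L))
  expect_identical(rownames(am$score), c("p1", "p2", "p1dup"))
  expect_equal(am$score["p1", ], am$score["p1dup", ])
  # joint sample permutation leaves the matrix unchanged
  perm <- sample(S)
  am2 <- association_matrix(piv[, perm], mrna[, perm], sets)
  expect_equal(am$score, am2$score)
  # sign convention: positive iff best direction is the correlated one
  pos_better <- am$p_pos <= am$p_neg
  expect_identical(unname(am$score >= 0), unname(pos_better))
})

test_that("concordance computes Pearson r over shared miRNAs", {
  score <- matrix(c(1, 2, 3, 0, 0, 0), 3, 2,
                  dimnames = list(c("m1", "m2", "m3"), c("cc", "x")))
  de <- c(m1 = 1, m2 = 2, m3 = 3)
  res <- de_enrichment_concordance(de, score, "cc")
  expect_equal(res$r, 1)
  expect_identical(res$n_mirnas, 3L)
  expect_equal(de_enrichment_concordance(-de, score, "cc")$r, -1)
  expect_error(de_enrichment_concordance(de[1:2], score, "cc"), "fewer than 3")
  expect_error(de_enrichment_concordance(de, score, "nope"), "unknown set")
})

test_that("planted anti-correlated targets are detected, null targets are not", {
  cfg <- cohort_config(n_samples = 100, n_mirna = 10, n_mrna = 800,
                       targets = list(pivot = 1, n_targets = 40, rho = 0.5),
                       seed = 5)
  ch <- generate_cohort(cfg)
  mf <- preprocess_mirna(ch)
  tab <- generate_target_table(ch$truth, n_background_pairs = 1500)
  pid <- ch$truth$targets$pivot_id[1]
  res <- suppressMessages(target_anticorrelation_enrichment(
    pid, mf$values[pid, ], ch$mrna, tab))
  expect_lt(res$q, 0.05)
  expect_identical(res$direction, "anti-correlated")
  # same design with rho = 0: targets are independent of the pivot
  cfg0 <- cohort_config(n_samples = 100, n_mirna = 10, n_mrna = 800,
                        targets = list(pivot = 1, n_targets = 40, rho = 0),
                        seed = 5)
  ch0 <- generate_cohort(cfg0)
  mf0 <- preprocess_mirna(ch0)
  tab0 <- generate_target_table(ch0$truth, n_background_pairs = 1500)
  res0 <- suppressMessages(target_anticorrelation_enrichment(
    ch0$truth$targets$pivot_id[1], mf0$values[pid, ], ch0$mrna, tab0))
  expect_gt(res0$p_exact, 0.001)
})
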