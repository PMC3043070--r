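test_that("expression TSV round-trips and preserves order", {
  vals <- matrix(c(1.5, 2.25, 3, 40.125, 5, 6), 3, 2,
                 dimnames = list(c("miR-b", "miR-a", "miR-c"), c("s2", "s1")))
  m <- expression_matrix(vals, scale = "linear")
  f <- tempfile(fileext = ".tsv")
  write_expression_tsv(m, f)
  m2 <- read_expression_tsv(f, scale = "linear")
  expect_identical(feature_ids(m2), c("miR-b", "miR-a", "miR-c"))
  expect_identical(sample_ids(m2), c("s2", "s1"))
  expect_equal(m2$values, m$values, tolerance = 1e-5)
})

test_that("expression TSV errors name the offending id or cell", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "miR-1\t1\t2", "miR-1\t3\t4"), f)
  expect_error(read_expression_tsv(f, "linear"), "miR-1")
  writeLines(c("id\ts1\ts2", "miR-1\t1\t2", "miR-2\tNA\t4"), f)
  expect_error(read_expression_tsv(f, "linear"), "miR-2.*s1")
})

test_that("detection calls round-trip alongside values", {
  vals <- matrix(as.numeric(1:4), 2, 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  det <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2, dimnames = dimnames(vals))
  m <- expression_matrix(vals, "linear", det)
  fv <- tempfile(); fd <- tempfile()
  write_expression_tsv(m, fv, detection_path = fd)
  m2 <- read_expression_tsv(fv, "linear", detection_path = fd)
  expect_identical(m2$detection, det)
})

test_that("GMT parsing dedups genes and reports malformed lines", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("CC\tdesc\tA\tB\tC", "dup\td\tA\tA\tB"), f)
  sets <- read_gmt(f)
  expect_length(sets, 2L)
  expect_length(sets[["CC"]], 3L)
  expect_length(sets[["dup"]], 2L)  # "A" counted once
  writeLines(c("ok\td\tA", "bad\tonlydesc"), f)
  expect_error(read_gmt(f), "line 2")
  writeLines(character(0), f)
  expect_length(read_gmt(f), 0L)
})

test_that("GMT round-trips through write_gmt", {
  sets <- gene_set_collection(list(one = c("A", "B"), two = c("C")),
                              descriptions = c(one = "d1", two = "d2"))
  f <- tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  sets2 <- read_gmt(f)
  expect_identical(unclass(sets2)[], unclass(sets)[])
})

test_that("target-score tables collapse duplicates to the strongest score", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("mirna\tgene\tscore",
               "miR-1\tG1\t-0.1", "miR-1\tG1\t-0.4", "miR-1\tG2\t-0.2"), f)
  tab <- read_target_scores(f)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$score[tab$gene == "G1"], -0.4)
  writeLines(c("mirna\tgene", "miR-1\tG1"), f)
  expect_error(read_target_scores(f), "score")
})

test_that("sample annotations map raw measurements to categories", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "sample_id\tsubtype\tki67_percent\tmitoses",
    "S1\tbasal-like\t0.5\t7",
    "S2\tClaudin-low\t1\t0",
    "S3\tluminal-A\t5;12;8\t12",
    "S4\tluminal-B\t10\t5"), f)
  ann <- read_sample_annotations(f)
  expect_identical(ann$ki67_category, c("negative", "negative", "high",
                                        "moderate"))
  expect_identical(ann$mitotic_category, c("moderate", "low", "high", "low"))
  expect_identical(ann$subtype[2], "unclassified")
  writeLines(c("sample_id", "S1", "S1"), f)
  expect_error(read_sample_annotations(f), "duplicate sample_id")
})

test_that("write_table serializes at 6 significant digits and keeps headers", {
  df <- data.frame(feature_id = c("a", "b"), p = c(0.000123456789, 1))
  f <- tempfile(fileext = ".tsv")
  write_table(df, f)
  lines <- readLines(f)
  expect_identical(lines[1], "feature_id\tp")
  expect_match(lines[2], "0.000123457")
  write_table(df[0, ], f)
  expect_length(readLines(f), 1L)  # header only
})

test_that("expression matrix construction enforces its invariants", {
  vals <- matrix(1, 2, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(expression_matrix(vals, "linear"), "duplicate feature")
  vals2 <- matrix(c(1, NA, 3, 4), 2, 2,
                  dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(expression_matrix(vals2, "linear"), "non-finite")
  vals3 <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(expression_matrix(vals3, "linear",
                                 detection = matrix(TRUE, 1, 2)),
               "detection")
})
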