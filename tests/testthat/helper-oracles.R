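# Independent brute-force oracles: exhaustive enumeration over all C(N, B)
# label arrangements.  Used to validate the dynamic programs; they never
# share code with the DP path.

# all binary arrangements of B ones among N positions, one per column
all_arrangements <- function(N, B) {
  if (B == 0) return(matrix(0L, N, 1))
  idx <- utils::combn(N, B)
  apply(idx, 2, function(ii) { v <- integer(N); v[ii] <- 1L; v })
}

# cumulative TNoM null P(k <= K) by enumeration
enum_tnom_null <- function(n1, n0) {
  N <- n1 + n0
  arr <- all_arrangements(N, n1)
  ks <- apply(arr, 2, function(lab) tnom_statistic(seq_len(N), lab))
  vapply(0:min(n1, n0), function(k) mean(ks <= k), numeric(1))
}

# mHG scores of every arrangement
enum_mhg_scores <- function(N, B) {
  arr <- all_arrangements(N, B)
  apply(arr, 2, function(lam) mhg_statistic(lam)$s)
}

# standard preprocessing chain used by pipeline-level tests
preprocess_mirna <- function(cohort, min_fraction = 0.10) {
  groups <- stats::setNames(cohort$annotations$replicate_group,
                            cohort$annotations$sample_id)
  m <- average_replicates(cohort$mirna, groups)
  m <- percentile_normalize(m)$matrix
  m <- log2_transform(m)
  detection_filter(m, min_fraction)
}

# one annotation row per biological sample
sample_level_annotations <- function(cohort) {
  ann <- cohort$annotations[!duplicated(cohort$annotations$replicate_group), ]
  ann$sample_id <- ann$replicate_group
  ann
}

# small deterministic expression matrix for unit tests
toy_matrix <- function(values, scale = "log2", detection = NULL,
                       features = sprintf("f%02d", seq_len(nrow(values))),
                       samples = sprintf("s%02d", seq_len(ncol(values)))) {
  dimnames(values) <- list(features, samples)
  if (!is.null(detection)) dimnames(detection) <- dimnames(values)
  expression_matrix(values, scale = scale, detection = detection)
}
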