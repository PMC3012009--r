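# Shared fixtures built in code.

# the canonical small cohort, generated once per test run
small_cohort <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- fixture_small()
    cached
  }
})

# normalized tumor-only ratio matrix + group split for a cohort
cohort_ratio <- function(cohort) {
  m <- average_replicates(cohort$expression, cohort$sheet)
  sheet <- cohort$sheet[cohort$sheet$sample_id %in% sample_ids(m), ]
  ratio <- normalize_to_reference(m, sheet, keep_normals = TRUE)
  tumors <- sheet$sample_id[!sheet$is_normal]
  groups <- split(tumors, sheet$group[match(tumors, sheet$sample_id)])
  list(ratio = ratio, ratio_tumor = ratio[["values"]][, tumors, drop = FALSE],
       sheet = sheet, tumors = tumors, groups = groups)
}

# plain random expression matrix helper
rand_em <- function(n_genes, n_samples, space = "ratio", sd = 1, seed = 1) {
  withr::with_seed(seed, {
    v <- matrix(rnorm(n_genes * n_samples, sd = sd), n_genes, n_samples,
                dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_samples))))
    expression_matrix(v, space)
  })
}

# null two-group matrix with heterogeneous gene variances
null_matrix <- function(n_genes, na, nb, d0 = 4, s0sq = 0.09, seed = 1) {
  withr::with_seed(seed, {
    sigma2 <- s0sq * d0 / rchisq(n_genes, d0)
    n <- na + nb
    v <- matrix(rnorm(n_genes * n, sd = rep(sqrt(sigma2), n)), n_genes, n,
                dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n))))
    v
  })
}

group_names <- function(v, na) {
  list(a = colnames(v)[seq_len(na)], b = colnames(v)[-seq_len(na)])
}
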