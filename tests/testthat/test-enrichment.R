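ratio_em <- function(v) expression_matrix(v, "ratio")

test_that("all-zero member ratios give a zero score", {
  v <- matrix(0, 10, 3, dimnames = list(sprintf("g%02d", 1:10),
                                        paste0("s", 1:3)))
  v[6:10, ] <- rnorm(15)
  sets <- gene_set_collection(list(zero = sprintf("g%02d", 1:5)))
  e <- pgsea_scores(ratio_em(v), sets, min_size = 5)
  expect_equal(unname(e$scores["zero", ]), rep(0, 3))
  expect_true(all(is.na(e$p["zero", ])))
})

test_that("the score is the one-sample t of member ratios", {
  withr::with_seed(500, {
    v <- matrix(rnorm(200 * 4), 200, 4,
                dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:4)))
  })
  sets <- gene_set_collection(list(S = sprintf("g%03d", 1:60)))
  e <- pgsea_scores(ratio_em(v), sets, min_size = 5)
  for (s in paste0("s", 1:4)) {
    tt <- t.test(v[1:60, s])
    expect_equal(unname(e$scores["S", s]), unname(tt$statistic),
                 tolerance = 1e-12)
    expect_equal(unname(e$p["S", s]), tt$p.value, tolerance = 1e-12)
  }
})

test_that("score concentrates near delta / (sigma / sqrt(n)) for shifted sets", {
  delta <- 0.4; sigma <- 0.5; n <- 100
  withr::with_seed(501, {
    scores <- vapply(1:50, function(i) {
      v <- matrix(delta + rnorm(n, 0, sigma), n, 1,
                  dimnames = list(sprintf("g%03d", 1:n), "s1"))
      e <- pgsea_scores(ratio_em(v),
                        gene_set_collection(list(S = sprintf("g%03d", 1:n))))
      e$scores["S", "s1"]
    }, 0)
  })
  expected <- delta / (sigma / sqrt(n))  # = 8
  se <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores) - expected), 3 * se + 0.5)
})

test_that("undersized sets are absent rather than zero-filled", {
  v <- matrix(rnorm(30), 10, 3,
              dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:3)))
  sets <- gene_set_collection(list(big = sprintf("g%02d", 1:8),
                                   tiny = c("g01", "g02"),
                                   ghost = c("nope1", "nope2", "nope3",
                                             "nope4", "nope5")))
  e <- pgsea_scores(ratio_em(v), sets, min_size = 5)
  expect_identical(rownames(e$scores), "big")
  expect_identical(unname(e$n_genes["big"]), 8L)
})

test_that("null enrichment p-values are uniform", {
  withr::with_seed(502, {
    v <- matrix(rnorm(2000 * 20), 2000, 20,
                dimnames = list(sprintf("g%04d", 1:2000), sprintf("s%02d", 1:20)))
    sets <- lapply(1:200, function(i) sample(rownames(v), 30))
    names(sets) <- sprintf("S%03d", 1:200)
  })
  e <- pgsea_scores(ratio_em(v), gene_set_collection(sets))
  ks <- suppressWarnings(stats::ks.test(as.vector(e$p), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted activation makes its subtype's scores the most positive", {
  co <- small_cohort()
  cr <- cohort_ratio(co)
  e <- pgsea_scores(expression_matrix(cr$ratio_tumor, "ratio"), co$sets)
  sc <- e$scores["PATHWAY_A", ]
  a_samples <- cr$groups$A
  expect_true(min(sc[a_samples]) > max(sc[setdiff(names(sc), a_samples)]))
})

test_that("arm calls recover a planted loss with the right sign", {
  d <- cohort_design(
    n_genes = 1500,
    subtypes = list(
      list(label = "L", n_samples = 20,
           arm_events = list(list(chromosome = "chr1", arm = "p",
                                  shift = -0.5, penetrance = 1.0)),
           set_events = list()),
      list(label = "G", n_samples = 10,
           arm_events = list(list(chromosome = "chr2", arm = "q",
                                  shift = 0.3, penetrance = 1.0)),
           set_events = list())),
    n_normals = 6, n_marker_genes = 0, planted_sets = list(),
    n_random_sets = 0, coupling = "none",
    d0_true = Inf, s0sq_true = 0.09, seed = 510)
  co <- simulate_cohort(d)
  cr <- cohort_ratio(co)
  calls <- arm_bias_calls(expression_matrix(cr$ratio_tumor, "ratio"),
                          co$annotation, p_threshold = 0.001, min_genes = 20)
  loss <- subset(calls, arm == "chr1p" & sample_id %in% cr$groups$L)
  expect_gte(mean(loss$call == "loss"), 0.95)
  gain <- subset(calls, arm == "chr2q" & sample_id %in% cr$groups$G)
  expect_gte(mean(gain$call == "gain"), 0.9)
  expect_true(all(gain$mean_shift[gain$call == "gain"] > 0))
})

test_that("arm call sensitivity grows with shift size and arm gene count", {
  sens <- function(shift, n_genes_arm) {
    withr::with_seed(511, {
      v <- matrix(rnorm(10 * n_genes_arm * 12, sd = 0.3),
                  10 * n_genes_arm, 12)
      dimnames(v) <- list(sprintf("g%05d", seq_len(nrow(v))),
                          sprintf("s%02d", 1:12))
      v[seq_len(n_genes_arm), ] <- v[seq_len(n_genes_arm), ] + shift
    })
    ann <- gene_annotation(data.frame(
      gene_id = rownames(v),
      chromosome = rep(sprintf("c%d", 1:10), each = n_genes_arm),
      start = seq(0, by = 100, length.out = nrow(v)),
      end = seq(50, by = 100, length.out = nrow(v)),
      strand = "+",
      arm = "p", stringsAsFactors = FALSE))
    calls <- arm_bias_calls(ratio_em(v), ann, min_genes = 10)
    mean(subset(calls, arm == "c1p")$call != "none")
  }
  grid_shift <- vapply(c(0.1, 0.2, 0.5), sens, 0, n_genes_arm = 40)
  expect_true(all(diff(grid_shift) >= 0))
  grid_size <- vapply(c(15, 40, 120), function(n) sens(0.15, n), 0)
  expect_true(all(diff(grid_size) >= 0))
})

test_that("a null cohort's arm call rate is at chance level", {
  d <- cohort_design(
    n_genes = 2000,
    chromosomes = data.frame(chromosome = sprintf("chr%d", 1:20),
                             p_length = 5e7, q_length = 5e7,
                             stringsAsFactors = FALSE),
    subtypes = list(list(label = "T1", n_samples = 50,
                         arm_events = list(), set_events = list())),
    n_normals = 12, n_marker_genes = 0, planted_sets = list(),
    n_random_sets = 0, coupling = "none", seed = 512)
  co <- simulate_cohort(d)
  cr <- cohort_ratio(co)
  calls <- arm_bias_calls(expression_matrix(cr$ratio_tumor, "ratio"),
                          co$annotation, p_threshold = 0.001, min_genes = 20)
  expect_lte(mean(calls$call != "none"), 0.005)
})

test_that("discriminant sets rank a planted activation first", {
  co <- small_cohort()
  cr <- cohort_ratio(co)
  e <- pgsea_scores(expression_matrix(cr$ratio_tumor, "ratio"), co$sets)
  disc <- discriminant_sets(e, cr$groups$A, c(cr$groups$B, cr$groups$C))
  expect_identical(disc$set[1], "PATHWAY_A")
  # exact consistency with the moderated t on the score matrix
  res <- moderated_t(e$scores, cr$groups$A, c(cr$groups$B, cr$groups$C),
                     prior = list(d0 = 0, s0sq = 0))
  expect_equal(disc$t[match(res$gene, disc$set)], res$t)
})

test_that("identical groups yield no discriminant sets", {
  withr::with_seed(513, {
    v <- matrix(rnorm(500 * 12), 500, 12,
                dimnames = list(sprintf("g%03d", 1:500), sprintf("s%02d", 1:12)))
    sets <- lapply(1:30, function(i) sample(rownames(v), 25))
    names(sets) <- sprintf("S%02d", 1:30)
  })
  e <- pgsea_scores(ratio_em(v), gene_set_collection(sets))
  disc <- discriminant_sets(e, sprintf("s%02d", 1:6), sprintf("s%02d", 7:12))
  expect_identical(sum(disc$fdr < 0.01), 0L)
})
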