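test_that("the same seed reproduces the cohort bit for bit", {
  d <- cohort_design(n_genes = 300, seed = 17,
                     n_marker_genes = 10, n_random_sets = 3)
  a <- simulate_cohort(d)
  b <- simulate_cohort(d)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$sets$sets, b$sets$sets)
  expect_identical(a$truth, b$truth)
  # and the written files are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(a, d1); write_cohort(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("with all effects off the per-gene sample mean tracks mu", {
  d <- cohort_design(
    n_genes = 400,
    subtypes = list(list(label = "T1", n_samples = 50,
                         arm_events = list(), set_events = list())),
    n_normals = 2, n_marker_genes = 0, planted_sets = list(),
    n_random_sets = 0, coupling = "none", seed = 23)
  co <- simulate_cohort(d)
  tumors <- co$sheet$sample_id[!co$sheet$is_normal]
  v <- co$expression$values[, tumors]
  se <- sqrt(co$truth$sigma2 / length(tumors))
  z <- abs(rowMeans(v) - co$truth$mu) / se
  expect_gte(mean(z < 4), 0.99)
})

test_that("a fully penetrant arm loss shifts arm genes by its effect size", {
  d <- cohort_design(
    n_genes = 600,
    chromosomes = data.frame(chromosome = c("chr1", "chr2"),
                             p_length = 5e7, q_length = 5e7,
                             stringsAsFactors = FALSE),
    subtypes = list(
      list(label = "L", n_samples = 12,
           arm_events = list(list(chromosome = "chr1", arm = "p",
                                  shift = -0.5, penetrance = 1.0)),
           set_events = list()),
      list(label = "U", n_samples = 12, arm_events = list(),
           set_events = list())),
    n_normals = 4, n_marker_genes = 0, planted_sets = list(),
    n_random_sets = 0, coupling = "none", seed = 31)
  co <- simulate_cohort(d)
  arm_genes <- co$annotation$gene_id[co$annotation$chromosome == "chr1" &
                                     co$annotation$arm == "p"]
  aff <- co$sheet$sample_id[co$sheet$group == "L"]
  una <- co$sheet$sample_id[co$sheet$group == "U"]
  delta <- mean(co$expression$values[arm_genes, aff]) -
           mean(co$expression$values[arm_genes, una])
  expect_equal(delta, -0.5, tolerance = 0.1)
  expect_true(all(co$truth$arm_events$drawn))
})

test_that("gene variances follow the scaled inverse chi-square prior", {
  d <- cohort_design(
    n_genes = 2500,
    subtypes = list(list(label = "T1", n_samples = 4,
                         arm_events = list(), set_events = list())),
    n_normals = 2, n_marker_genes = 0, planted_sets = list(),
    n_random_sets = 0, coupling = "none",
    d0_true = 4, s0sq_true = 0.09, seed = 41)
  co <- simulate_cohort(d)
  # sigma2 * d0 / s0sq should be inverse chi-square with d0 df
  u <- d$d0_true * d$s0sq_true / co$truth$sigma2
  ks <- stats::ks.test(u, stats::pchisq, df = d$d0_true)
  expect_gt(ks$p.value, 0.01)
})

test_that("the driver's realized coupling approximates rho_target", {
  rhos <- vapply(1:3, function(i) {
    d <- cohort_design(
      n_genes = 500,
      subtypes = list(
        list(label = "A", n_samples = 60, arm_events = list(),
             set_events = list(list(set = "OXPHOS_LIKE", shift = 0.8))),
        list(label = "B", n_samples = 60, arm_events = list(),
             set_events = list())),
      n_normals = 6, n_marker_genes = 0,
      planted_sets = list(list(name = "OXPHOS_LIKE", size = 60)),
      n_random_sets = 0, seed = 100 + i)
    co <- simulate_cohort(d)
    members <- co$sets$sets$OXPHOS_LIKE
    driver <- co$truth$coupling$driver_gene
    set_mean <- colMeans(co$expression$values[members, ])
    cor(co$expression$values[driver, ], set_mean, method = "spearman")
  }, 0)
  expect_true(all(abs(rhos - (-0.6)) < 0.15))
})

test_that("set events must name planted sets", {
  expect_error(cohort_design(
    n_genes = 100,
    subtypes = list(list(label = "A", n_samples = 3, arm_events = list(),
                         set_events = list(list(set = "NOPE", shift = 1)))),
    planted_sets = list(list(name = "YES", size = 10)),
    coupling = "none", seed = 1), "NOPE")
  expect_error(cohort_design(n_genes = 100, seed = 1,
                             subtypes = list(list(label = "A", n_samples = 2,
                                                  arm_events = list(list(
                                                    chromosome = "chr1",
                                                    arm = "p", shift = 1,
                                                    penetrance = 1.5)),
                                                  set_events = list()))),
               "penetrance")
})

test_that("the small fixture is stable and internally consistent", {
  a <- fixture_small()
  b <- fixture_small()
  expect_identical(a$expression$values, b$expression$values)
  expect_lte(nrow(a$expression$values), 200L)
  expect_lte(ncol(a$expression$values), 20L)
  # loader invariants hold on the emitted files
  dir <- withr::local_tempdir()
  write_cohort(a, dir)
  m <- load_expression(file.path(dir, "expression.tsv"), space = "absolute")
  expect_identical(m$values, a$expression$values)
  sheet <- load_sample_sheet(file.path(dir, "samples.tsv"))
  expect_identical(sheet$sample_id, a$sheet$sample_id)
  ann <- load_gene_annotation(file.path(dir, "annotation.tsv"))
  out <- assign_arms(ann, file.path(dir, "cytoband.txt"))
  expect_identical(out$arm, a$annotation$arm)
  sets <- load_gmt(file.path(dir, "sets.gmt"))
  expect_identical(names(sets$sets), names(a$sets$sets))
})
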