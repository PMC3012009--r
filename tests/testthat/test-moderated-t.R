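test_that("identical variances give an infinite-df prior at the common value", {
  prior <- fit_prior(rep(0.25, 50), df = 4)
  expect_identical(prior$d0, Inf)
  expect_equal(prior$s0sq, 0.25)
})

test_that("the prior fit recovers planted hyperparameters within 20%", {
  errs <- t(vapply(1:10, function(i) {
    withr::with_seed(1000 + i, {
      sigma2 <- 0.25 * 4 / rchisq(5000, 4)
      s2 <- sigma2 * rchisq(5000, 10) / 10
    })
    prior <- fit_prior(s2, df = 10)
    c(d0 = abs(prior$d0 - 4) / 4, s0sq = abs(prior$s0sq - 0.25) / 0.25)
  }, c(d0 = 0, s0sq = 0)))
  expect_true(all(errs[, "d0"] < 0.2))
  expect_true(all(errs[, "s0sq"] < 0.2))
})

test_that("degenerate prior inputs are rejected", {
  expect_error(fit_prior(c(0.1, 0.2), df = 4), "at least 10")
  expect_error(fit_prior(rep(0, 20), df = 4), "zero")
})

test_that("the finite-df branch agrees with the reference empirical-Bayes fit", {
  skip_if_not_installed("limma")
  withr::with_seed(55, {
    sigma2 <- 0.09 * 4 / rchisq(2000, 4)
    s2 <- sigma2 * rchisq(2000, 6) / 6
  })
  prior <- fit_prior(s2, df = 6)
  ref <- limma::fitFDist(s2, df1 = 6)
  expect_equal(prior$d0, ref$df2, tolerance = 1e-6)
  expect_equal(prior$s0sq, ref$scale, tolerance = 1e-6)
})

test_that("equal group means give t = 0 and p = 1", {
  v <- matrix(c(1, 2, 1, 2, 5, 5, 5, 5), 1, 8,
              dimnames = list("g", paste0("s", 1:8)))
  v <- rbind(v, matrix(rnorm(8 * 20), 20, 8,
                       dimnames = list(sprintf("x%02d", 1:20), colnames(v))))
  res <- moderated_t(v, paste0("s", 1:2), paste0("s", 3:4))
  expect_equal(res$t[1], 0)
  expect_equal(res$p[1], 1)
})

test_that("with d0 = 0 the statistic is the classical pooled t", {
  v <- null_matrix(100, 4, 5, seed = 60)
  g <- group_names(v, 4)
  res <- moderated_t(v, g$a, g$b, prior = list(d0 = 0, s0sq = 0))
  classical <- apply(v, 1, function(row) {
    tt <- t.test(row[g$a], row[g$b], var.equal = TRUE)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  expect_equal(res$t, unname(classical["t", ]), tolerance = 1e-10)
  expect_equal(res$p, unname(classical["p", ]), tolerance = 1e-10)
})

test_that("the full statistic matches a step-by-step formula oracle", {
  v <- null_matrix(100, 5, 6, seed = 61)
  g <- group_names(v, 5)
  res <- moderated_t(v, g$a, g$b)
  prior <- attr(res, "prior")
  oracle <- oracle_moderated_t(v, g$a, g$b, prior$d0, prior$s0sq)
  expect_equal(res$logFC, oracle$logFC, tolerance = 1e-12)
  expect_equal(res$t, oracle$t, tolerance = 1e-10)
  expect_equal(res$p, oracle$p, tolerance = 1e-10)
})

test_that("the statistic agrees with the reference moderated-t implementation", {
  skip_if_not_installed("limma")
  v <- null_matrix(500, 6, 11, seed = 62)
  g <- group_names(v, 6)
  res <- moderated_t(v, g$a, g$b)
  design <- cbind(1, c(rep(1, 6), rep(0, 11)))
  fit <- limma::eBayes(limma::lmFit(v, design))
  expect_equal(res$t, fit$t[, 2], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(res$p, fit$p.value[, 2], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("groups must be disjoint and large enough", {
  v <- null_matrix(20, 3, 3, seed = 63)
  expect_error(moderated_t(v, colnames(v)[1:3], colnames(v)[3:5]), "overlap")
  expect_error(moderated_t(v, colnames(v)[1], colnames(v)[2:4]), ">= 2")
})

test_that("shrinkage pulls every posterior variance monotonically toward s0sq", {
  v <- null_matrix(200, 4, 4, seed = 64)
  g <- group_names(v, 4)
  s0sq <- 0.1
  prev <- NULL
  for (d0 in c(0, 1, 4, 16, 64)) {
    res <- moderated_t(v, g$a, g$b, prior = list(d0 = d0, s0sq = s0sq))
    gap <- abs(res$s2_post - s0sq)
    expect_true(all(res$s2_post >= pmin(res$s2, s0sq) - 1e-12))
    expect_true(all(res$s2_post <= pmax(res$s2, s0sq) + 1e-12))
    if (!is.null(prev)) expect_true(all(gap <= prev + 1e-12))
    prev <- gap
  }
})

test_that("BH adjustment: hand cases and exact equality with the oracle", {
  expect_equal(benjamini_hochberg(0.3), 0.3)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(70, {
    for (i in 1:25) {
      p <- runif(sample(3:80, 1))^sample(1:3, 1)
      expect_identical(benjamini_hochberg(p), oracle_bh(p))
    }
  })
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(benjamini_hochberg(c(0.5, NA)), "missing")
})

test_that("BH output is equivariant under permutation of the input", {
  withr::with_seed(71, {
    p <- runif(40)
    perm <- sample(40)
  })
  expect_equal(benjamini_hochberg(p)[perm], benjamini_hochberg(p[perm]))
})

test_that("null data yield near-zero significant counts", {
  counts <- vapply(1:10, function(i) {
    v <- null_matrix(2000, 6, 6, seed = 200 + i)
    g <- group_names(v, 6)
    count_significant(moderated_t(v, g$a, g$b), fdr_max = 0.01)
  }, 0L)
  expect_gte(mean(counts <= 5), 0.9)
})

test_that("planted effects are counted within 10%", {
  withr::with_seed(80, {
    v <- matrix(rnorm(2000 * 12, sd = 0.3), 2000, 12,
                dimnames = list(sprintf("g%04d", 1:2000),
                                sprintf("s%02d", 1:12)))
    v[1:200, 1:6] <- v[1:200, 1:6] + 2
  })
  g <- group_names(v, 6)
  n <- count_significant(moderated_t(v, g$a, g$b), fdr_max = 0.01)
  expect_gte(n, 180)
  expect_lte(n, 220)
})

test_that("rank_top orders by t with ties broken by gene id", {
  v <- null_matrix(50, 3, 3, seed = 90)
  g <- group_names(v, 3)
  res <- moderated_t(v, g$a, g$b)
  up <- rank_top(res, "up", 10)
  ord <- order(-res$t, res$gene)
  expect_identical(up, res$gene[ord][1:10])
  all_of_them <- rank_top(res, "down", 50)
  expect_setequal(all_of_them, res$gene)
  expect_error(rank_top(res, "up", 51), "exceeds")
  # a single strongly planted gene tops the list
  v["g0001", g$a] <- v["g0001", g$a] + 50
  expect_identical(rank_top(moderated_t(v, g$a, g$b), "up", 1), "g0001")
})

test_that("signature derivation is null-safe and thresholds correctly", {
  v <- null_matrix(1000, 3, 3, seed = 91)
  g <- group_names(v, 3)
  sig <- derive_signature(v, g$a, g$b, fdr_max = 1e-5, min_fold = 2)
  expect_identical(length(sig$up) + length(sig$down), 0L)
  # planted up-regulation at 2.5-fold passes the 2-fold/FDR gate
  withr::with_seed(92, {
    v2 <- matrix(rnorm(1000 * 6, sd = 0.25), 1000, 6,
                 dimnames = dimnames(v)[c(1, 2)])
    colnames(v2) <- colnames(v)
    v2[1:50, g$a] <- v2[1:50, g$a] + log2(2.5)
  })
  sig2 <- derive_signature(v2, g$a, g$b, fdr_max = 1e-5, min_fold = 2)
  expect_gte(mean(sprintf("g%04d", 1:50) %in% sig2$up), 0.9)
  expect_length(intersect(sig2$up, sprintf("g%04d", 51:1000)), 0)
  expect_length(sig2$down, 0)
})
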