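#' Permutation test for subtype distinctness under unbalanced sizes
#'
#' Asks whether a small focal group's apparent distinctness from a larger
#' pool could be a sample-size artifact.  Each iteration draws a subset
#' `S` of size `k` from the pool without replacement and counts
#' significantly differentially expressed genes (moderated t,
#' `fdr < fdr_max`) in two comparisons sharing that draw:
#' `count_between` (focal vs `S`) and `count_within` (`S` vs the rest of
#' the pool).  If the focal group is genuinely distinct the between count
#' exceeds the within count in (nearly) every iteration.
#'
#' `exceed_fraction` is the fraction of iterations with
#' `count_between > count_within`, counting ties as 1/2 (under an
#' exchangeable null both counts are typically zero, and tie-splitting
#' makes the null expectation 1/2 rather than 0).  `p_bound` is the
#' add-one permutation bound
#' `(#\{count_within >= count_between\} + 1) / (B + 1)`, which can never
#' be exactly zero.
#'
#' @param m An `ExpressionMatrix` or matrix.
#' @param focal Sample ids of the focal group (>= 2).
#' @param pool Sample ids of the comparison pool, disjoint from `focal`.
#' @param k Subset size drawn from the pool; needs `2 <= k` and
#'   `length(pool) - k >= 2`.
#' @param B Number of iterations (the reference analysis uses 1000).
#' @param seed Integer seed.
#' @param fdr_max Per-gene significance rule within each iteration.
#' @return A list of class `DistinctnessTest` with the iteration `trace`
#'   (data frame: `iteration`, `count_between`, `count_within`),
#'   `exceed_fraction`, `p_bound` and the parameters.
#' @export
distinctness_permutation <- function(m, focal, pool, k, B = 1000, seed,
                                     fdr_max = 0.01) {
  if (missing(seed)) abort("distinctness_permutation() requires a 'seed'")
  vals <- if (inherits(m, "ExpressionMatrix")) m$values else m
  overlap <- intersect(focal, pool)
  if (length(overlap)) abort("focal and pool overlap: %s", quote_ids(overlap))
  n <- length(pool)
  if (length(focal) < 2L) abort("focal group needs >= 2 samples")
  if (k >= n) abort("k = %d must be < pool size %d", k, n)
  if (k < 2L || n - k < 2L)
    abort("need k >= 2 and pool size - k >= 2 (got k = %d, pool = %d)", k, n)
  if (B < 1L) abort("B must be >= 1")
  bt <- integer(B); wt <- integer(B)
  withr::with_seed(derive_seed(seed, "distinctness"), {
    for (b in seq_len(B)) {
      s <- sample(pool, k)
      bt[b] <- count_significant(moderated_t(vals, focal, s), fdr_max)
      wt[b] <- count_significant(moderated_t(vals, s, setdiff(pool, s)), fdr_max)
    }
  })
  structure(list(trace = data.frame(iteration = seq_len(B),
                                    count_between = bt, count_within = wt),
                 exceed_fraction = (sum(bt > wt) + 0.5 * sum(bt == wt)) / B,
                 p_bound = (sum(wt >= bt) + 1) / (B + 1),
                 B = B, k = k, fdr_max = fdr_max, seed = seed),
            class = "DistinctnessTest")
}

#' @export
print.DistinctnessTest <- function(x, ...) {
  cat(sprintf(paste0("DistinctnessTest: B = %d, k = %d\n",
                     "  between > within in %.1f%% of iterations (ties as 1/2)\n",
                     "  p_bound = %.4g\n"),
              x$B, x$k, 100 * x$exceed_fraction, x$p_bound))
  invisible(x)
}

#' Write the permutation trace as TSV
#' @param x A `DistinctnessTest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_permutation_trace <- function(x, path) {
  stopifnot(inherits(x, "DistinctnessTest"))
  utils::write.table(x$trace, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
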