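# Empirical-Bayes moderated t: variance prior fitting, the statistic,
# multiplicity correction, and result utilities.

# invert the trigamma function by Newton iteration (monotone decreasing)
trigamma_inverse <- function(x) {
  stopifnot(is.finite(x), x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-10) break
  }
  y
}

#' Fit the variance prior for the moderated t-statistic
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0sq`
#' of a scaled inverse chi-square distribution over true gene variances,
#' by the method of moments on log variances: under the hierarchical model
#' the sample variances follow `s0sq * F(d_g, d0)`, whose log has mean and
#' variance expressible through digamma/trigamma functions.  The excess of
#' the observed log-variance dispersion over the sampling minimum
#' `trigamma(d_g / 2)` determines `d0` by monotone root finding
#' (trigamma inversion).
#'
#' When the observed dispersion does not exceed the sampling minimum the
#' prior is degenerate: `d0 = Inf` with `s0sq` equal to the geometric mean
#' of the observed variances (so that identical variances are returned
#' unchanged).
#'
#' @param s2 Per-feature sample variances (non-negative; at least 10
#'   positive values required for a stable fit).
#' @param df Residual degrees of freedom, a scalar or per-feature vector.
#' @return A list of class `EBayesPrior` with elements `d0` and `s0sq`.
#' @export
fit_prior <- function(s2, df) {
  if (length(df) == 1L) df <- rep(df, length(s2))
  if (length(df) != length(s2)) abort("'df' must be scalar or match 's2'")
  if (all(s2 == 0)) abort("all variances are zero; prior is undefined")
  ok <- is.finite(s2) & s2 > 0 & df >= 1
  if (sum(ok) < 10L)
    abort("fit_prior() needs at least 10 features with positive variance and df >= 1 (got %d)",
          sum(ok))
  z <- log(s2[ok])
  dfo <- df[ok]
  e <- z - digamma(dfo / 2) + log(dfo / 2)
  emean <- mean(e)
  excess <- stats::var(e) - mean(trigamma(dfo / 2))
  prior <- if (!is.finite(excess) || excess <= 0) {
    list(d0 = Inf, s0sq = exp(mean(z)))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    list(d0 = d0, s0sq = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
  }
  structure(prior, class = "EBayesPrior")
}

#' @export
print.EBayesPrior <- function(x, ...) {
  cat(sprintf("EBayesPrior: d0 = %s, s0sq = %g\n", format(x$d0), x$s0sq))
  invisible(x)
}

#' Moderated two-group t-test per gene
#'
#' For each gene the pooled two-group variance `s2_g` (with
#' `d_g = |A| + |B| - 2` residual df) is shrunk toward the prior:
#' `s2_post = (d0 * s0sq + d_g * s2_g) / (d0 + d_g)`, and the moderated
#' statistic is `t = (meanA - meanB) / sqrt(s2_post * (1/|A| + 1/|B|))`
#' with `d0 + d_g` degrees of freedom.  With `d0 = 0` this is the
#' classical pooled-variance t-test; with `d0 = Inf` all genes share the
#' prior variance.
#'
#' @param m An `ExpressionMatrix` or plain matrix (features x samples).
#' @param group_a,group_b Disjoint character vectors of sample ids, each of
#'   size >= 2.
#' @param prior Optional `EBayesPrior` (or `list(d0, s0sq)`) to use instead
#'   of fitting one from the pooled variances.
#' @return A data frame of class `ModeratedTest` with per-feature columns
#'   `gene`, `logFC` (meanA - meanB), `s2`, `df`, `s2_post`, `t`, `p`,
#'   `fdr`, carrying the prior and group sizes as attributes.
#' @export
moderated_t <- function(m, group_a, group_b, prior = NULL) {
  vals <- if (inherits(m, "ExpressionMatrix")) m$values else m
  if (!is.matrix(vals)) abort("'m' must be a matrix or ExpressionMatrix")
  overlap <- intersect(group_a, group_b)
  if (length(overlap)) abort("groups overlap: %s", quote_ids(overlap))
  missing <- setdiff(c(group_a, group_b), colnames(vals))
  if (length(missing)) abort("unknown sample ids: %s", quote_ids(missing))
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L)
    abort("each group needs >= 2 samples for a within-group variance (got %d and %d)",
          na, nb)
  xa <- vals[, group_a, drop = FALSE]
  xb <- vals[, group_b, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  dg <- na + nb - 2L
  s2 <- (rowSums((xa - ma)^2) + rowSums((xb - mb)^2)) / dg
  if (is.null(prior)) prior <- fit_prior(s2, dg)
  d0 <- prior$d0; s0sq <- prior$s0sq
  s2_post <- if (is.infinite(d0)) rep(s0sq, length(s2))
             else (d0 * s0sq + dg * s2) / (d0 + dg)
  logfc <- ma - mb
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  tstat <- ifelse(se > 0, logfc / se,
                  ifelse(logfc == 0, 0, sign(logfc) * Inf))
  p <- 2 * stats::pt(abs(tstat), df = d0 + dg, lower.tail = FALSE)
  res <- data.frame(gene = rownames(vals) %||% as.character(seq_along(logfc)),
                    logFC = logfc, s2 = s2, df = dg, s2_post = s2_post,
                    t = tstat, p = p, fdr = benjamini_hochberg(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "prior") <- prior
  attr(res, "groups") <- list(a = group_a, b = group_b)
  class(res) <- c("ModeratedTest", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up false discovery rate adjustment: with p-values sorted
#' ascending, `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and mapped
#' back to input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p)) abort("'p' must be numeric")
  if (anyNA(p) || any(p < 0) || any(p > 1))
    abort("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Count significant features
#' @param result A `ModeratedTest`.
#' @param fdr_max Significance rule: `fdr < fdr_max` (default 0.01, the
#'   reference analysis' global rule).
#' @return Integer count.
#' @export
count_significant <- function(result, fdr_max = 0.01) {
  stopifnot(inherits(result, "ModeratedTest"))
  sum(result$fdr < fdr_max)
}

#' Top-ranked genes by moderated t
#'
#' @param result A `ModeratedTest`.
#' @param direction `"up"` (largest t first) or `"down"` (smallest first).
#' @param n Number of genes; must not exceed the feature count.
#' @return Character vector of gene ids; ties in t break by gene id.
#' @export
rank_top <- function(result, direction = c("up", "down"), n) {
  stopifnot(inherits(result, "ModeratedTest"))
  direction <- match.arg(direction)
  if (n > nrow(result)) abort("n = %d exceeds feature count %d", n, nrow(result))
  ord <- if (direction == "up") order(-result$t, result$gene)
         else order(result$t, result$gene)
  result$gene[ord][seq_len(n)]
}

#' Write a moderated test result as TSV
#' @param result A `ModeratedTest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_moderated_test <- function(result, path) {
  utils::write.table(as.data.frame(result)[, c("gene", "logFC", "t", "p", "fdr")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
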