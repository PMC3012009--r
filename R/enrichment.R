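#' Per-sample parametric gene set enrichment
#'
#' For each sample and each gene set, summarizes the member genes'
#' reference-normalized log-ratios as a one-sample t statistic against
#' zero: `score = mean(z) / (sd(z) / sqrt(n))` over the set members
#' measured in the matrix, with a two-sided p-value on `n - 1` degrees of
#' freedom.  Because the ratios are taken against tissue-matched normal
#' tissue, a positive score means the set's genes are coordinately
#' up-regulated in that sample relative to normal.
#'
#' Sets with fewer than `min_size` measured members are omitted entirely
#' (not zero-filled).  A set whose member ratios have zero spread within a
#' sample gets `p = NA` for that sample (score 0 when the mean is also 0);
#' such rows are excluded from [discriminant_sets()].
#'
#' @param m An `ExpressionMatrix` in ratio space (see
#'   [normalize_to_reference()]).
#' @param sets A `GeneSetCollection`.
#' @param min_size Minimum measured members per set (default 5; use ~20
#'   for chromosome-arm sets).
#' @return An object of class `EnrichmentMatrix`: list with `scores` and
#'   `p` (sets x samples matrices), `n_genes` (members used per set) and
#'   `min_size`.
#' @export
pgsea_scores <- function(m, sets, min_size = 5) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(sets, "GeneSetCollection"))
  if (m$space != "ratio")
    abort("pgsea_scores() expects a ratio-space matrix (normalize to reference first)")
  vals <- m$values
  members <- lapply(sets$sets, function(g) intersect(g, rownames(vals)))
  keep <- names(members)[lengths(members) >= min_size]
  if (!length(keep))
    abort("no gene set has >= %d measured members", min_size)
  scores <- matrix(NA_real_, length(keep), ncol(vals),
                   dimnames = list(keep, colnames(vals)))
  pmat <- scores
  for (nm in keep) {
    sub <- vals[members[[nm]], , drop = FALSE]
    n <- nrow(sub)
    mu <- colMeans(sub)
    sdv <- sqrt(pmax(colSums(sub^2) - n * mu^2, 0) / (n - 1L))
    sc <- ifelse(sdv > 0, mu / (sdv / sqrt(n)),
                 ifelse(mu == 0, 0, sign(mu) * Inf))
    pv <- ifelse(sdv > 0,
                 2 * stats::pt(abs(sc), df = n - 1L, lower.tail = FALSE),
                 NA_real_)
    scores[nm, ] <- sc
    pmat[nm, ] <- pv
  }
  structure(list(scores = scores, p = pmat,
                 n_genes = stats::setNames(lengths(members)[keep], keep),
                 min_size = min_size),
            class = "EnrichmentMatrix")
}

#' @export
print.EnrichmentMatrix <- function(x, ...) {
  cat(sprintf("EnrichmentMatrix: %d sets x %d samples (min_size %d)\n",
              nrow(x$scores), ncol(x$scores), x$min_size))
  invisible(x)
}

#' Write enrichment scores as TSV
#' @param e An `EnrichmentMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(e, path) {
  stopifnot(inherits(e, "EnrichmentMatrix"))
  out <- data.frame(set = rownames(e$scores), n_genes = e$n_genes[rownames(e$scores)],
                    e$scores, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expression-inferred chromosome arm gain/loss calls
#'
#' Treats each chromosome arm as a gene set and scores per-sample regional
#' expression bias with [pgsea_scores()]; an arm whose enrichment p-value
#' falls below `p_threshold` in a sample is called a gain or loss
#' according to the sign of the members' mean log-ratio.  This recovers
#' large copy-number events from expression data alone (the comparative
#' genomic meta-analysis idea).
#'
#' @param m An `ExpressionMatrix` in ratio space.
#' @param ann A `GeneAnnotation` with arms assigned (see [assign_arms()]).
#' @param p_threshold Call threshold (reference analysis: 0.001).
#' @param min_genes Minimum measured genes per arm (default 20).
#' @return A data frame of class `RegionalBiasCalls` with columns
#'   `sample_id`, `arm`, `n_genes`, `mean_shift`, `score`, `p`, `call`
#'   (`"gain"`, `"loss"` or `"none"`).
#' @export
arm_bias_calls <- function(m, ann, p_threshold = 0.001, min_genes = 20) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  ann <- gene_annotation(as.data.frame(ann))
  ann <- ann[ann$arm %in% c("p", "q") & ann$gene_id %in% gene_ids(m), , drop = FALSE]
  if (nrow(ann) == 0L) abort("no annotated genes overlap the matrix")
  arm_label <- paste0(ann$chromosome, ann$arm)
  arm_sets <- split(ann$gene_id, arm_label)
  arm_sets <- arm_sets[lengths(arm_sets) >= min_genes]
  if (!length(arm_sets))
    abort("no chromosome arm has >= %d measured genes", min_genes)
  e <- pgsea_scores(m, gene_set_collection(arm_sets), min_size = min_genes)
  shifts <- t(vapply(rownames(e$scores), function(a)
    colMeans(m$values[arm_sets[[a]], , drop = FALSE]),
    numeric(ncol(m$values))))
  long <- expand.grid(arm = rownames(e$scores), sample_id = colnames(e$scores),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- cbind(match(long$arm, rownames(e$scores)),
               match(long$sample_id, colnames(e$scores)))
  long$n_genes <- e$n_genes[long$arm]
  long$mean_shift <- shifts[idx]
  long$score <- e$scores[idx]
  long$p <- e$p[idx]
  long$call <- ifelse(!is.na(long$p) & long$p < p_threshold,
                      ifelse(long$mean_shift > 0, "gain", "loss"), "none")
  long <- long[, c("sample_id", "arm", "n_genes", "mean_shift", "score", "p", "call")]
  attr(long, "p_threshold") <- p_threshold
  class(long) <- c("RegionalBiasCalls", "data.frame")
  long
}

#' Gene sets discriminating two sample groups
#'
#' Applies the moderated t-statistic to the enrichment score matrix (sets
#' as features) and ranks sets by p-value.  Sets with any non-finite or
#' undefined score are excluded (with a message) before testing.
#'
#' @param e An `EnrichmentMatrix`.
#' @param group_a,group_b Disjoint sample id vectors (>= 2 each).
#' @param top_n Optionally truncate the ranked table.
#' @return A data frame of class `DiscriminantSets` with columns `set`,
#'   `logFC` (score difference), `t`, `p`, `fdr`, ranked by ascending p.
#' @export
discriminant_sets <- function(e, group_a, group_b, top_n = NULL) {
  stopifnot(inherits(e, "EnrichmentMatrix"))
  sc <- e$scores
  usable <- apply(is.finite(sc), 1L, all) & apply(!is.na(e$p), 1L, all)
  if (!all(usable)) {
    message(sprintf("excluding %d set(s) with undefined scores: %s",
                    sum(!usable), quote_ids(rownames(sc)[!usable])))
    sc <- sc[usable, , drop = FALSE]
  }
  if (nrow(sc) == 0L) abort("no usable sets after exclusion")
  # a stable prior fit needs >= 10 features; with fewer sets fall back to
  # the ordinary pooled t (d0 = 0, no shrinkage)
  prior <- if (nrow(sc) < 10L) list(d0 = 0, s0sq = 0) else NULL
  res <- moderated_t(sc, group_a, group_b, prior = prior)
  ord <- order(res$p, -abs(res$t), res$gene)
  out <- data.frame(set = res$gene[ord], logFC = res$logFC[ord],
                    t = res$t[ord], p = res$p[ord], fdr = res$fdr[ord],
                    stringsAsFactors = FALSE)
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  attr(out, "prior") <- attr(res, "prior")
  class(out) <- c("DiscriminantSets", "data.frame")
  out
}
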