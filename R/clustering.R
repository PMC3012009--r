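#' Filter genes by interquartile range
#'
#' Retains the most variable genes of a log-ratio matrix, either all genes
#' whose IQR across samples exceeds a threshold, or the `value` genes with
#' the largest IQR.  Quartiles use linear interpolation between order
#' statistics (`stats::quantile()` type 7); the threshold/top-n
#' correspondence depends on this rule, so it is fixed.  Ties in top-n mode
#' break by gene id; row order is preserved.
#'
#' @param m An `ExpressionMatrix` in ratio space.
#' @param mode `"threshold"` (keep IQR > `value`) or `"top_n"` (keep the
#'   `value` largest-IQR genes).
#' @param value Threshold (log2 units) or gene count.
#' @return The filtered `ExpressionMatrix`.
#' @export
iqr_filter <- function(m, mode = c("threshold", "top_n"), value) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  mode <- match.arg(mode)
  if (m$space != "ratio")
    abort("iqr_filter() expects a ratio-space matrix")
  iqr <- apply(m$values, 1L, stats::IQR, type = 7)
  keep <- if (mode == "threshold") {
    which(iqr > value)
  } else {
    value <- as.integer(value)
    if (value > nrow(m$values))
      abort("top_n = %d exceeds gene count %d", value, nrow(m$values))
    ord <- order(-iqr, rownames(m$values))
    sort(ord[seq_len(value)])
  }
  expression_matrix(m$values[keep, , drop = FALSE], m$space)
}

#' Hierarchical clustering of samples (or other column entities)
#'
#' Agglomerative clustering of the matrix columns under Euclidean distance
#' with complete or average linkage.  Deterministic given the column order
#' of the input (equal-distance merges follow `stats::hclust()`'s
#' order-based rule).
#'
#' @param m An `ExpressionMatrix` or plain numeric matrix; columns are the
#'   entities clustered.
#' @param linkage `"complete"` or `"average"`.
#' @return An object of class `ExprDendrogram` wrapping the `hclust` tree
#'   with its linkage and metric labels.
#' @export
hcluster <- function(m, linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  vals <- if (inherits(m, "ExpressionMatrix")) m$values else m
  if (!is.matrix(vals) || ncol(vals) < 2L)
    abort("hcluster() needs a matrix with at least 2 columns")
  if (any(!is.finite(vals))) abort("hcluster() input contains non-finite values")
  if (is.null(colnames(vals))) colnames(vals) <- paste0("c", seq_len(ncol(vals)))
  hc <- stats::hclust(stats::dist(t(vals), method = "euclidean"),
                      method = linkage)
  structure(list(hclust = hc, linkage = linkage, metric = "euclidean",
                 labels = hc$labels),
            class = "ExprDendrogram")
}

#' @export
print.ExprDendrogram <- function(x, ...) {
  cat(sprintf("ExprDendrogram: %d leaves, %s linkage, %s distance\n",
              length(x$labels), x$linkage, x$metric))
  invisible(x)
}

#' Merge heights of a dendrogram
#' @param x An `ExprDendrogram`.
#' @return Numeric vector of merge heights, one per internal node in merge
#'   order.
#' @export
merge_heights <- function(x) {
  stopifnot(inherits(x, "ExprDendrogram"))
  x$hclust$height
}

# leaf sets under each internal node, as canonical signature strings
node_bipartitions <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    pick <- function(j) if (j < 0L) hc$labels[-j] else members[[j]]
    members[[i]] <- c(pick(hc$merge[i, 1L]), pick(hc$merge[i, 2L]))
  }
  vapply(members, function(x) paste(sort(x), collapse = "\t"), "")
}

# canonical signature for an arbitrary leaf set
bipartition_signature <- function(leaves) paste(sort(leaves), collapse = "\t")

#' Bootstrap probabilities for dendrogram nodes
#'
#' Quantifies node support by resampling genes (rows) with replacement:
#' `B` replicate matrices of `round(r * n_genes)` rows are clustered with
#' the same linkage, and each original internal node receives
#' `BP = 100 * (number of replicates whose tree contains the node's leaf
#' set) / B`.  A degenerate replicate in which all pairwise column
#' distances are zero carries no nonsingleton node and contributes nothing.
#'
#' @param m An `ExpressionMatrix` (or matrix) of genes x samples.
#' @param linkage `"complete"` or `"average"`.
#' @param B Number of bootstrap replications (the reference analysis uses
#'   10,000).
#' @param r Relative resample size (1 resamples at the original gene count).
#' @param seed Integer seed; results are reproducible.
#' @return An object of class `BootstrapSupport`: the original
#'   `ExprDendrogram` plus a `support` data frame with columns `node`
#'   (merge index), `n_leaves` and `bp`.
#' @export
bootstrap_support <- function(m, linkage = c("complete", "average"),
                              B = 10000, r = 1, seed) {
  linkage <- match.arg(linkage)
  if (missing(seed)) abort("bootstrap_support() requires a 'seed'")
  if (r <= 0) abort("relative sample size r must be > 0")
  if (B < 1L) abort("B must be >= 1")
  dend <- hcluster(m, linkage)
  sigs <- node_bipartitions(dend$hclust)
  vals <- if (inherits(m, "ExpressionMatrix")) m$values else m
  G <- nrow(vals)
  size <- max(1L, as.integer(round(r * G)))
  counts <- numeric(length(sigs))
  tvals <- t(vals)
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(G, size, replace = TRUE)
      d <- stats::dist(tvals[, idx, drop = FALSE], method = "euclidean")
      if (all(d == 0)) next
      hb <- stats::hclust(d, method = linkage)
      counts <- counts + (sigs %in% node_bipartitions(hb))
    }
  })
  sizes <- vapply(strsplit(sigs, "\t", fixed = TRUE), length, 0L)
  support <- data.frame(node = seq_along(sigs), n_leaves = sizes,
                        bp = 100 * counts / B, stringsAsFactors = FALSE)
  structure(list(dendrogram = dend, support = support,
                 signatures = sigs, B = B, r = r, seed = seed),
            class = "BootstrapSupport")
}

#' @export
print.BootstrapSupport <- function(x, ...) {
  cat(sprintf("BootstrapSupport: %d nodes, B = %d, r = %g\n",
              nrow(x$support), x$B, x$r))
  invisible(x)
}

#' Bootstrap probability of a given leaf set
#'
#' @param bs A [bootstrap_support()] result.
#' @param leaves Character vector of leaf labels.
#' @return The node's BP in `[0, 100]`, or `NA` if no internal node of the
#'   original tree has exactly this leaf set.
#' @export
node_bp <- function(bs, leaves) {
  stopifnot(inherits(bs, "BootstrapSupport"))
  hit <- match(bipartition_signature(leaves), bs$signatures)
  if (is.na(hit)) NA_real_ else bs$support$bp[hit]
}

#' Export a dendrogram as Newick text
#'
#' Branch lengths are derived from merge heights; when bootstrap support is
#' supplied its BP values become internal node labels.
#'
#' @param x An `ExprDendrogram` or `BootstrapSupport`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(x, path) {
  bp <- NULL
  if (inherits(x, "BootstrapSupport")) {
    bp <- x$support$bp
    x <- x$dendrogram
  }
  stopifnot(inherits(x, "ExprDendrogram"))
  hc <- x$hclust
  build <- function(i, parent_h) {
    if (i < 0L)
      return(sprintf("%s:%s", hc$labels[-i], format(parent_h, digits = 10)))
    h <- hc$height[i]
    lab <- if (is.null(bp)) "" else format(bp[i], digits = 6)
    sprintf("(%s,%s)%s:%s",
            build(hc$merge[i, 1L], h), build(hc$merge[i, 2L], h),
            lab, format(parent_h - h, digits = 10))
  }
  root <- nrow(hc$merge)
  h <- hc$height[root]
  lab <- if (is.null(bp)) "" else format(bp[root], digits = 6)
  txt <- sprintf("(%s,%s)%s;",
                 build(hc$merge[root, 1L], h), build(hc$merge[root, 2L], h),
                 lab)
  writeLines(txt, path)
  invisible(path)
}
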