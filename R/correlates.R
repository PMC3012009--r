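#' Correlate a driver gene's expression with per-sample set enrichment
#'
#' Computes the Spearman rank correlation (average ranks on ties) between
#' one gene's expression across samples and every gene set's enrichment
#' score vector, with the large-sample t approximation for p-values
#' (`t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df).  Used to ask
#' which transcriptional programs track a putative regulator, e.g. a tumor
#' suppressor whose loss de-represses a pathway (expected: strong negative
#' rho).
#'
#' @param m An `ExpressionMatrix` containing the driver gene; its samples
#'   must cover the enrichment matrix's samples.
#' @param driver Gene id with non-constant expression.
#' @param e An `EnrichmentMatrix`.
#' @param rank_by `"rho"` (ascending, most negative first; default) or
#'   `"abs_rho"` (descending magnitude).
#' @return A data frame of class `CorrelationScreen` with columns `set`,
#'   `rho`, `p`, `rank`, ordered by rank; the driver id is attached as an
#'   attribute.  Sets with undefined correlations (constant score vector)
#'   are dropped with a message.
#' @export
correlate_gene_to_sets <- function(m, driver, e, rank_by = c("rho", "abs_rho")) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(e, "EnrichmentMatrix"))
  rank_by <- match.arg(rank_by)
  samples <- colnames(e$scores)
  missing <- setdiff(samples, sample_ids(m))
  if (length(missing))
    abort("enrichment samples absent from matrix: %s", quote_ids(missing))
  if (!driver %in% gene_ids(m)) abort("driver gene '%s' not in matrix", driver)
  x <- m$values[driver, samples]
  if (stats::sd(x) == 0) abort("driver gene '%s' has constant expression", driver)
  n <- length(samples)
  if (n < 4L) abort("need at least 4 samples for a correlation screen")
  rows <- lapply(rownames(e$scores), function(nm) {
    y <- e$scores[nm, ]
    if (any(!is.finite(y)) || stats::sd(y) == 0) return(NULL)
    rho <- stats::cor(x, y, method = "spearman")
    p <- if (abs(rho) >= 1) 0
         else 2 * stats::pt(abs(rho) * sqrt((n - 2) / (1 - rho^2)),
                            df = n - 2, lower.tail = FALSE)
    data.frame(set = nm, rho = rho, p = p, stringsAsFactors = FALSE)
  })
  dropped <- rownames(e$scores)[vapply(rows, is.null, TRUE)]
  if (length(dropped))
    message(sprintf("dropping %d set(s) with undefined correlation: %s",
                    length(dropped), quote_ids(dropped)))
  out <- do.call(rbind, rows)
  if (is.null(out)) abort("no set has a defined correlation with '%s'", driver)
  ord <- if (rank_by == "rho") order(out$rho, out$set)
         else order(-abs(out$rho), out$set)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "driver") <- driver
  attr(out, "rank_by") <- rank_by
  class(out) <- c("CorrelationScreen", "data.frame")
  out
}

#' Pearson correlation of two per-sample signature score vectors
#'
#' Compares two enrichment signatures by correlating their per-sample
#' scores across a common sample panel (e.g. two independently derived
#' signatures of the same transcriptional program should correlate
#' strongly even with modest member overlap).
#'
#' @param scores_a,scores_b Numeric vectors of per-sample scores.  If both
#'   are named they are aligned by name; otherwise they must have equal
#'   length and order.
#' @return Pearson correlation coefficient.
#' @export
signature_score_correlation <- function(scores_a, scores_b) {
  if (!is.null(names(scores_a)) && !is.null(names(scores_b))) {
    common <- intersect(names(scores_a), names(scores_b))
    if (length(common) < 3L) abort("fewer than 3 shared samples")
    scores_a <- scores_a[common]; scores_b <- scores_b[common]
  }
  if (length(scores_a) != length(scores_b))
    abort("score vectors differ in length (%d vs %d)",
          length(scores_a), length(scores_b))
  if (stats::sd(scores_a) == 0 || stats::sd(scores_b) == 0)
    abort("constant score vector; correlation undefined")
  stats::cor(scores_a, scores_b, method = "pearson")
}

#' Write a correlation screen as TSV
#' @param x A `CorrelationScreen`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlation_screen <- function(x, path) {
  stopifnot(inherits(x, "CorrelationScreen"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
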