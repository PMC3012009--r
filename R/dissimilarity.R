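#' Pairwise gene-set overlap dissimilarity
#'
#' Quantifies how much two gene sets share members:
#' `D(A, B) = 1 - (N_AB / 2) * (1 / N_A + 1 / N_B)`, one minus the mean
#' of the two overlap fractions.  Identical sets score 0, disjoint sets 1.
#' Sets are intersected with the measured-gene `universe` before counting;
#' sets empty after intersection are dropped with a message.  `D` is
#' bounded and symmetric with zero diagonal but is not a metric (no
#' triangle inequality).
#'
#' @param sets A `GeneSetCollection`.
#' @param universe Optional character vector of measured gene ids.
#' @param variant `"corrected"` (default, as above) or `"literal"`, the
#'   sign-flipped rendering `-1 + (N_AB / 2)(1/N_A + 1/N_B)` kept for
#'   comparison (it maps identical sets to 0 and disjoint sets to -1).
#' @return An object of class `SetDissimilarity`: list with the `D`
#'   matrix, per-set sizes `n`, the pairwise overlap matrix `n_overlap`
#'   and the `variant` used.
#' @export
set_dissimilarity <- function(sets, universe = NULL,
                              variant = c("corrected", "literal")) {
  stopifnot(inherits(sets, "GeneSetCollection"))
  variant <- match.arg(variant)
  members <- sets$sets
  if (!is.null(universe))
    members <- lapply(members, intersect, y = unique(as.character(universe)))
  empty <- names(members)[lengths(members) == 0L]
  if (length(empty)) {
    message(sprintf("dropping %d set(s) empty after universe intersection: %s",
                    length(empty), quote_ids(empty)))
    members <- members[lengths(members) > 0L]
  }
  if (length(members) < 2L) abort("need at least 2 non-empty sets")
  genes <- unique(unlist(members))
  inc <- vapply(members, function(g) genes %in% g, logical(length(genes)))
  inc <- t(inc) * 1  # sets x genes incidence
  n_overlap <- tcrossprod(inc)
  n <- diag(n_overlap)
  half_sum <- (n_overlap / 2) * outer(1 / n, 1 / n, "+")
  d <- if (variant == "corrected") 1 - half_sum else -1 + half_sum
  structure(list(D = d, n = n, n_overlap = n_overlap, variant = variant),
            class = "SetDissimilarity")
}

#' @export
print.SetDissimilarity <- function(x, ...) {
  cat(sprintf("SetDissimilarity: %d sets (%s variant)\n",
              nrow(x$D), x$variant))
  invisible(x)
}

#' Cluster gene sets by overlap dissimilarity
#'
#' Treats each set's row of the dissimilarity matrix as a feature vector
#' and agglomerates under Euclidean distance with average linkage, so that
#' highly redundant sets (sharing most of their members) fall in the same
#' branch.
#'
#' @param d A `SetDissimilarity`.
#' @return An `ExprDendrogram` over set names.
#' @export
cluster_sets <- function(d) {
  stopifnot(inherits(d, "SetDissimilarity"))
  if (nrow(d$D) < 2L) abort("need at least 2 sets to cluster")
  hcluster(d$D, linkage = "average")  # symmetric: columns are the sets
}

#' Percent similarity between two gene sets
#'
#' Reports two common renderings side by side: the Jaccard percent
#' `100 * |A n B| / |A u B|` and the overlap-dissimilarity complement
#' `100 * (1 - D(A, B))` (the mean of the two overlap fractions, as a
#' percent).
#'
#' @param a,b Character vectors of gene ids, non-empty after universe
#'   intersection.
#' @param universe Optional measured-gene universe.
#' @return A list with `jaccard` and `d_similarity`, both percentages.
#' @export
set_overlap_percent <- function(a, b, universe = NULL) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (!is.null(universe)) {
    universe <- unique(as.character(universe))
    a <- intersect(a, universe); b <- intersect(b, universe)
  }
  if (!length(a) || !length(b))
    abort("both sets must be non-empty after universe intersection")
  nab <- length(intersect(a, b))
  list(jaccard = 100 * nab / length(union(a, b)),
       d_similarity = 100 * (nab / 2) * (1 / length(a) + 1 / length(b)))
}

#' Write a dissimilarity matrix as TSV
#' @param d A `SetDissimilarity`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dissimilarity <- function(d, path) {
  stopifnot(inherits(d, "SetDissimilarity"))
  out <- data.frame(set = rownames(d$D), d$D, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
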