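#' Construct an expression matrix
#'
#' The central container of the package: a genes x samples matrix of log2
#' expression values together with a flag recording whether values are
#' absolute intensities (e.g. summarized microarray output) or log-ratios
#' relative to a normal-tissue reference (see [normalize_to_reference()]).
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique, non-empty row and column names.  All values must be finite:
#'   missing values are rejected so that every downstream statistic is
#'   defined for every gene.
#' @param space Either `"absolute"` (log2 intensities) or `"ratio"`
#'   (log2 ratios to a reference).
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `space`.
#' @seealso [load_expression()], [write_expression()]
#' @export
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' expression_matrix(m, "absolute")
expression_matrix <- function(values, space = c("absolute", "ratio")) {
  space <- match.arg(space)
  if (!is.matrix(values) || !is.numeric(values))
    abort("'values' must be a numeric matrix")
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid) || any(gid == "") || any(sid == ""))
    abort("'values' must have non-empty row names (gene ids) and column names (sample ids)")
  if (anyDuplicated(gid))
    abort("duplicated gene ids: %s", quote_ids(gid[duplicated(gid)]))
  if (anyDuplicated(sid))
    abort("duplicated sample ids: %s", quote_ids(sid[duplicated(sid)]))
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    abort("non-finite value at gene '%s', sample '%s'", gid[bad[1L]], sid[bad[2L]])
  }
  structure(list(values = values, space = space), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s space]\n",
              nrow(x$values), ncol(x$values), x$space))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of ids in matrix order.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

# internal: subset keeping class and space
em_subset <- function(x, genes = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing)) abort("unknown gene ids: %s", quote_ids(missing))
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing)) abort("unknown sample ids: %s", quote_ids(missing))
    v <- v[, samples, drop = FALSE]
  }
  expression_matrix(v, x$space)
}

#' Read an expression matrix from tab-separated text
#'
#' Expects a header row of sample ids and a first column of gene ids; every
#' other cell must be a finite number.  Ragged rows, non-numeric cells and
#' (by default) duplicated gene ids are rejected with an error naming the
#' offending row or column.
#'
#' @param path Path to a TSV file.
#' @param space Value space of the stored data, `"absolute"` or `"ratio"`.
#' @param duplicates What to do with duplicated gene ids: `"error"`
#'   (default) or `"mean"` to collapse duplicates to their per-sample mean.
#' @return An [expression_matrix()].
#' @export
load_expression <- function(path, space = c("absolute", "ratio"),
                            duplicates = c("error", "mean")) {
  space <- match.arg(space)
  duplicates <- match.arg(duplicates)
  if (!file.exists(path)) abort("file not found: '%s'", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) != 1L)
    abort("ragged TSV '%s': line %d has %d fields, expected %d",
          path, which(nf != nf[1L])[1L], nf[nf != nf[1L]][1L], nf[1L])
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  if (ncol(raw) < 2L) abort("'%s' has no sample columns", path)
  gid <- raw[[1L]]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                 dimnames = list(NULL, colnames(vals))))
  missing_cell <- is.na(vals) | vals %in% c("NA", "")
  bad <- which(is.na(num) & !missing_cell, arr.ind = TRUE)
  if (nrow(bad)) {
    abort("non-numeric cell '%s' at row '%s', column '%s' in '%s'",
          vals[bad[1L, 1L], bad[1L, 2L]], gid[bad[1L, 1L]],
          colnames(vals)[bad[1L, 2L]], path)
  }
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    abort("missing value at row '%s', column '%s' in '%s'",
          gid[bad[1L]], colnames(num)[bad[2L]], path)
  }
  if (anyDuplicated(gid)) {
    if (duplicates == "error")
      abort("duplicated gene ids in '%s': %s", path, quote_ids(unique(gid[duplicated(gid)])))
    num <- rowsum(num, group = gid, reorder = FALSE) /
      as.vector(table(factor(gid, levels = unique(gid))))
    gid <- unique(gid)
  }
  rownames(num) <- gid
  expression_matrix(num, space)
}

#' Write an expression matrix as tab-separated text
#'
#' Values are written with 17 significant digits so that
#' `load_expression(write_expression(x, p))` reproduces `x` exactly.
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  fmt <- matrix(format_full(x$values), nrow = nrow(x$values),
                dimnames = dimnames(x$values))
  out <- data.frame(gene_id = rownames(fmt), fmt, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
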