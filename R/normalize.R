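#' Average technical replicates
#'
#' Collapses each technical replicate group named in the sample sheet to a
#' single column equal to the arithmetic mean (in log2 space) of its member
#' columns.  The collapsed column keeps the id of the group's first member
#' (in matrix order) and its position; the other members are dropped.
#' Non-replicated samples pass through unchanged, so the operation is
#' idempotent.
#'
#' @param m An `ExpressionMatrix`.
#' @param sheet A `SampleSheet`; rows whose `replicate_group` is set define
#'   the groups.  Members of a group absent from the matrix are ignored.
#' @return An `ExpressionMatrix` with one column per replicate group plus
#'   one per singleton sample.
#' @details A replicate group must not span different `group` labels; that
#'   would silently average biologically distinct samples and is an error.
#' @export
average_replicates <- function(m, sheet) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  sheet <- sample_sheet(as.data.frame(sheet))
  ids <- sample_ids(m)
  rows <- sheet[sheet$sample_id %in% ids & !is.na(sheet$replicate_group), , drop = FALSE]
  if (nrow(rows) == 0L) return(m)
  keep <- ids
  vals <- m$values
  for (grp in unique(rows$replicate_group)) {
    members <- rows$sample_id[rows$replicate_group == grp]
    members <- ids[ids %in% members]          # matrix order
    if (length(members) < 2L) next
    glabels <- unique(rows$group[rows$replicate_group == grp])
    if (length(glabels) > 1L)
      abort("replicate group '%s' spans different group labels: %s",
            grp, quote_ids(glabels))
    vals[, members[1L]] <- rowMeans(vals[, members, drop = FALSE])
    keep <- setdiff(keep, members[-1L])
  }
  expression_matrix(vals[, keep, drop = FALSE], m$space)
}

#' Normalize expression to tissue-matched normal samples
#'
#' Converts absolute log2 intensities to log-ratios by subtracting, for each
#' gene, the centre (mean by default) of the normal samples of the same
#' tissue.  This removes tissue-level expression baselines so that
#' downstream statistics measure tumor-specific deviation.
#'
#' @param m An `ExpressionMatrix` in `"absolute"` space.
#' @param sheet A `SampleSheet` covering all samples of `m`.  Every
#'   non-normal sample's tissue must have at least one normal sample.
#' @param center Reference summary across the tissue's normal samples:
#'   `"mean"` (default) or `"median"`, computed per gene in log2 space.
#' @param keep_normals Keep the normal columns in the output (each expressed
#'   as a ratio to its own tissue reference)?  Default `TRUE`; set to
#'   `FALSE` to return tumor columns only.
#' @return An `ExpressionMatrix` in `"ratio"` space.
#' @export
normalize_to_reference <- function(m, sheet, center = c("mean", "median"),
                                   keep_normals = TRUE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  center <- match.arg(center)
  if (m$space != "absolute")
    abort("normalize_to_reference() expects an absolute-space matrix")
  rows <- match_sheet(m, sample_sheet(as.data.frame(sheet)))
  tissues <- unique(rows$tissue)
  no_normals <- tissues[!tissues %in% rows$tissue[rows$is_normal]]
  if (length(no_normals))
    abort("no normal samples for tissue(s): %s", quote_ids(no_normals))
  vals <- m$values
  out <- vals
  for (tis in tissues) {
    norm_ids <- rows$sample_id[rows$tissue == tis & rows$is_normal]
    ref_block <- vals[, norm_ids, drop = FALSE]
    ref <- if (center == "mean") rowMeans(ref_block)
           else apply(ref_block, 1L, stats::median)
    cols <- rows$sample_id[rows$tissue == tis]
    out[, cols] <- vals[, cols, drop = FALSE] - ref
  }
  if (!keep_normals) {
    tumor_ids <- rows$sample_id[!rows$is_normal]
    out <- out[, tumor_ids, drop = FALSE]
  }
  expression_matrix(out, "ratio")
}
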