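#' Derive an up/down expression signature
#'
#' Thresholds a moderated-t comparison into a two-sided signature: `up`
#' genes have `fdr < fdr_max` and fold change above `min_fold` (linear
#' scale, so `min_fold = 2` means `logFC > 1`), `down` genes symmetric.
#' An empty signature is a legitimate result, not an error.
#'
#' @param m An `ExpressionMatrix` or matrix.
#' @param group_a,group_b Disjoint sample id vectors (>= 2 each).
#' @param fdr_max FDR ceiling (the reference signature derivation uses
#'   1e-5).
#' @param min_fold Minimum linear fold change (reference: 2).
#' @param name Signature name.
#' @param prior Optional `EBayesPrior` passed to [moderated_t()].
#' @return A list of class `Signature` with `name`, `up`, `down`,
#'   `thresholds` and the underlying `ModeratedTest` as attribute `result`.
#' @export
derive_signature <- function(m, group_a, group_b, fdr_max = 1e-5,
                             min_fold = 2, name = "signature", prior = NULL) {
  if (min_fold <= 0) abort("min_fold must be positive")
  res <- moderated_t(m, group_a, group_b, prior = prior)
  lfc <- log2(min_fold)
  up <- res$gene[res$fdr < fdr_max & res$logFC > lfc]
  down <- res$gene[res$fdr < fdr_max & res$logFC < -lfc]
  sig <- structure(list(name = name, up = up, down = down,
                        thresholds = list(fdr_max = fdr_max, min_fold = min_fold)),
                   class = "Signature")
  attr(sig, "result") <- res
  sig
}

#' @export
print.Signature <- function(x, ...) {
  cat(sprintf("Signature '%s': %d up, %d down (FDR < %g, fold > %g)\n",
              x$name, length(x$up), length(x$down),
              x$thresholds$fdr_max, x$thresholds$min_fold))
  invisible(x)
}

#' Write a signature as a two-set GMT file
#' @param sig A `Signature`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @details Empty halves are written as a one-member placeholder-free line
#'   only when non-empty; a fully empty signature produces an empty file.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "Signature"))
  sets <- list()
  if (length(sig$up)) sets[[paste0(sig$name, "_UP")]] <- sig$up
  if (length(sig$down)) sets[[paste0(sig$name, "_DOWN")]] <- sig$down
  if (!length(sets)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  write_gmt(gene_set_collection(sets), path)
  invisible(path)
}
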