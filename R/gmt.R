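#' Construct a gene set collection
#'
#' @param sets Named list of character vectors of gene ids.  Names must be
#'   unique and every set non-empty; memberships are deduplicated.
#' @param descriptions Optional named character vector of per-set
#'   descriptions; missing entries default to the set name.
#' @param source Optional provenance string (e.g. the GMT path).
#' @return An object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, source = NA_character_) {
  if (!is.list(sets)) abort("'sets' must be a named list of gene id vectors")
  if (length(sets) == 0L)
    return(structure(list(sets = list(), descriptions = character(0),
                          source = source), class = "GeneSetCollection"))
  if (is.null(names(sets)) || any(names(sets) == ""))
    abort("'sets' must be a named list of gene id vectors")
  if (anyDuplicated(names(sets)))
    abort("duplicated set names: %s", quote_ids(names(sets)[duplicated(names(sets))]))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty)) abort("empty gene set(s): %s", quote_ids(empty))
  desc <- stats::setNames(names(sets), names(sets))
  if (!is.null(descriptions)) {
    hit <- intersect(names(descriptions), names(sets))
    desc[hit] <- descriptions[hit]
  }
  structure(list(sets = sets, descriptions = desc, source = source),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  if (length(x$sets) == 0L) {
    cat("GeneSetCollection: 0 sets\n")
  } else {
    cat(sprintf("GeneSetCollection: %d sets, %d-%d members\n",
                length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  }
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member ids, all tab-separated.
#' Lines with no members and duplicated set names are errors.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
load_gmt <- function(path) {
  if (!file.exists(path)) abort("file not found: '%s'", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    abort("GMT line %d in '%s' has no members (need name, description, >= 1 id)",
          short[1L], path)
  names_ <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names_))
    abort("duplicated set name(s) in '%s': %s", path,
          quote_ids(unique(names_[duplicated(names_)])))
  sets <- lapply(parts, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- names_
  desc <- stats::setNames(vapply(parts, `[[`, "", 2L), names_)
  gene_set_collection(sets, desc, source = path)
}

#' Write gene sets in GMT format
#' @param collection A `GeneSetCollection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  if (length(collection$sets) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
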