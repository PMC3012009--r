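#' Read a gene annotation table
#'
#' TSV with header and columns `gene_id`, `chromosome`, `start`, `end`,
#' `strand` (and optionally `arm`).  Coordinates are 0-based half-open
#' throughout the package: a gene occupies `[start, end)`.
#'
#' @param path Path to a TSV file.
#' @return A data frame of class `GeneAnnotation` with an `arm` column
#'   (`"p"`, `"q"` or `"unassigned"`).
#' @export
load_gene_annotation <- function(path) {
  if (!file.exists(path)) abort("file not found: '%s'", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, comment.char = "")
  gene_annotation(df)
}

#' Construct / validate a gene annotation table
#'
#' @param df Data frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand`; optional `arm`.
#' @return A data frame of class `GeneAnnotation`.
#' @export
gene_annotation <- function(df) {
  need <- c("gene_id", "chromosome", "start", "end", "strand")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) abort("annotation lacks columns: %s", quote_ids(missing))
  if (anyDuplicated(df$gene_id))
    abort("duplicated gene ids in annotation: %s",
          quote_ids(unique(df$gene_id[duplicated(df$gene_id)])))
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (anyNA(df$start) || anyNA(df$end))
    abort("non-numeric coordinates in annotation")
  bad <- which(df$start >= df$end)
  if (length(bad))
    abort("start >= end for gene(s): %s", quote_ids(df$gene_id[bad]))
  if (any(!df$strand %in% c("+", "-", ".")))
    abort("strand must be one of '+', '-', '.'")
  if (!"arm" %in% colnames(df)) df$arm <- "unassigned"
  if (any(!df$arm %in% c("p", "q", "unassigned")))
    abort("arm must be 'p', 'q' or 'unassigned'")
  df <- df[, c(need, "arm")]
  class(df) <- c("GeneAnnotation", "data.frame")
  df
}

#' Write a gene annotation table
#' @param ann A `GeneAnnotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a UCSC cytoBand file
#'
#' Plain-text cytoBand format: five tab-separated columns (chromosome,
#' start, end, band name, Giemsa stain), no header.  Malformed lines raise
#' an error naming the line number.
#'
#' @param path Path to a cytoBand text file.
#' @return A data frame with columns `chromosome`, `start`, `end`, `band`,
#'   `stain`.
#' @export
read_cytoband <- function(path) {
  if (!file.exists(path)) abort("file not found: '%s'", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 5L))
    abort("malformed cytoBand line %d in '%s': expected 5 tab-separated fields, found %d",
          which(nfield != 5L)[1L], path, nfield[nfield != 5L][1L])
  df <- data.frame(chromosome = vapply(parts, `[[`, "", 1L),
                   start = suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L))),
                   end = suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L))),
                   band = vapply(parts, `[[`, "", 4L),
                   stain = vapply(parts, `[[`, "", 5L),
                   stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end))
    abort("malformed cytoBand line %d in '%s': non-numeric coordinates",
          which(is.na(df$start) | is.na(df$end))[1L], path)
  df
}

#' Assign chromosome arms from cytoband data
#'
#' The p/q boundary of each chromosome is the start of its first
#' centromeric (`acen`) band.  A gene is assigned to the p arm when its
#' midpoint lies strictly below that boundary and to the q arm otherwise
#' (midpoints exactly on the boundary go to q).  Genes on chromosomes
#' absent from the cytoband table are `"unassigned"`.
#'
#' @param ann A `GeneAnnotation`.
#' @param cytoband A data frame from [read_cytoband()], or a path to a
#'   cytoBand file.
#' @return The annotation with its `arm` column filled in.
#' @export
assign_arms <- function(ann, cytoband) {
  ann <- gene_annotation(as.data.frame(ann))
  if (is.character(cytoband)) cytoband <- read_cytoband(cytoband)
  acen <- cytoband[cytoband$stain == "acen", , drop = FALSE]
  if (nrow(acen) == 0L)
    abort("cytoband table has no 'acen' bands; cannot locate centromeres")
  cen <- tapply(acen$start, acen$chromosome, min)
  mid <- (ann$start + ann$end) / 2
  hit <- match(ann$chromosome, names(cen))
  ann$arm <- ifelse(is.na(hit), "unassigned",
                    ifelse(mid < cen[hit], "p", "q"))
  ann
}

#' Genes overlapping a genomic region
#'
#' Returns the ids of genes whose `[start, end)` interval overlaps the
#' half-open query interval, ordered by gene start.  A gene that merely
#' abuts the query (gene start equal to query end, or gene end equal to
#' query start) does not overlap.
#'
#' @param ann A `GeneAnnotation`.
#' @param chromosome Chromosome label.
#' @param start,end Query interval, 0-based half-open; `start < end`.
#' @return Character vector of gene ids sorted by start coordinate.
#' @export
region_query <- function(ann, chromosome, start, end) {
  ann <- gene_annotation(as.data.frame(ann))
  if (!is.numeric(start) || !is.numeric(end) || start >= end)
    abort("invalid region: start (%s) must be < end (%s)",
          format(start), format(end))
  hit <- ann$chromosome == chromosome & ann$start < end & ann$end > start
  sel <- ann[hit, , drop = FALSE]
  sel$gene_id[order(sel$start, sel$gene_id)]
}
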