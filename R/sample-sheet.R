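#' Read a sample sheet
#'
#' A sample sheet maps sample ids to tissue of origin, subtype group,
#' normal/tumor status and, optionally, technical replicate groups and
#' patient labels.  Required columns: `sample_id`, `tissue`, `group`,
#' `is_normal`.  Optional: `replicate_group`, `patient` (empty cells mean
#' "not applicable").
#'
#' @param path Path to a TSV file with a header row.
#' @return A data frame of class `SampleSheet`.
#' @export
load_sample_sheet <- function(path) {
  if (!file.exists(path)) abort("file not found: '%s'", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  sample_sheet(df)
}

#' Construct / validate a sample sheet
#'
#' @param df Data frame with at least `sample_id`, `tissue`, `group`,
#'   `is_normal` columns.  `is_normal` may be logical or any of
#'   TRUE/FALSE/1/0/yes/no.
#' @return A validated data frame of class `SampleSheet`.
#' @export
sample_sheet <- function(df) {
  need <- c("sample_id", "tissue", "group", "is_normal")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) abort("sample sheet lacks columns: %s", quote_ids(missing))
  if (anyDuplicated(df$sample_id))
    abort("duplicated sample ids in sheet: %s",
          quote_ids(unique(df$sample_id[duplicated(df$sample_id)])))
  flag <- df$is_normal
  if (!is.logical(flag)) {
    flag <- tolower(as.character(flag))
    map <- c("true" = TRUE, "t" = TRUE, "1" = TRUE, "yes" = TRUE,
             "false" = FALSE, "f" = FALSE, "0" = FALSE, "no" = FALSE)
    if (any(!flag %in% names(map)))
      abort("unparseable is_normal value: %s", quote_ids(setdiff(flag, names(map))))
    flag <- unname(map[flag])
  }
  df$is_normal <- flag
  for (opt in c("replicate_group", "patient")) {
    if (!opt %in% colnames(df)) df[[opt]] <- NA_character_
    df[[opt]][!is.na(df[[opt]]) & df[[opt]] == ""] <- NA_character_
  }
  df <- df[, c(need, "replicate_group", "patient")]
  class(df) <- c("SampleSheet", "data.frame")
  df
}

#' Write a sample sheet as tab-separated text
#' @param sheet A `SampleSheet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  out <- as.data.frame(sheet)
  out$is_normal <- ifelse(out$is_normal, "TRUE", "FALSE")
  out$replicate_group[is.na(out$replicate_group)] <- ""
  out$patient[is.na(out$patient)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# internal: check that every matrix sample has exactly one sheet row
match_sheet <- function(m, sheet) {
  ids <- sample_ids(m)
  missing <- setdiff(ids, sheet$sample_id)
  if (length(missing))
    abort("samples absent from sheet: %s", quote_ids(missing))
  sheet[match(ids, sheet$sample_id), , drop = FALSE]
}
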