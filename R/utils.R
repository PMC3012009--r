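# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a master seed
#'
#' Deterministically maps a master seed and a stage label to a new seed so
#' that individual pipeline stages can be regenerated in isolation while the
#' whole run stays reproducible from a single integer.  The result always
#' fits in a signed 32-bit integer.
#'
#' @param seed Integer master seed.
#' @param label Character stage label.
#' @return An integer seed in `[0, 2^31 - 20)`.
#' @export
#' @examples
#' derive_seed(1L, "bootstrap")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  chars <- utf8ToInt(label)
  h <- sum(chars * ((seq_along(chars) %% 11L) + 1L))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

# stop() with sprintf-style formatting, no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# collapse a character vector for error messages
quote_ids <- function(x, max = 5L) {
  x <- as.character(x)
  shown <- utils::head(x, max)
  out <- paste0("'", shown, "'", collapse = ", ")
  if (length(x) > max) out <- paste0(out, ", ...")
  out
}

# row variances of a numeric matrix (denominator n - 1)
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) abort("row_vars() needs at least 2 columns")
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1L)
}

# format numerics so that a write -> read text round trip is lossless
format_full <- function(x) sprintf("%.17g", x)
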