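#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map_chr imap
#' @importFrom Matrix sparseMatrix Diagonal colSums rowSums t solve
NULL

# Derive a reproducible 32-bit sub-seed from a base seed and a stage label, so
# each generator stage owns an independent RNG stream and can be regenerated
# alone without disturbing the others.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

with_stage_seed <- function(seed, stage, code) {
  withr::with_seed(stage_seed(seed, stage), code)
}

assert_that <- function(ok, msg, class = "evnetprop_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}

`%||%` <- rlang::`%||%`

# Collapse a character vector into a single comma-separated field for TSV output.
collapse_ids <- function(x) vapply(x, function(v) paste(v, collapse = ","), character(1))

geometric_mean <- function(x) exp(mean(log(x)))

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE, check.names = FALSE))
}
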