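# Internal helpers shared across modules.

#' Pipeline logging
#'
#' One-line stage logging so summary counts are auditable. Silenced by setting
#' `options(regcascade.quiet = TRUE)`.
#' @param fmt `sprintf` format string.
#' @param ... values interpolated into `fmt`.
#' @return invisibly, the formatted line.
#' @export
rc_log <- function(fmt, ...) {
  line <- sprintf(fmt, ...)
  if (!isTRUE(getOption("regcascade.quiet", FALSE))) {
    message("[regcascade] ", line)
  }
  invisible(line)
}

# stop() with a consistent prefix; never truncates the offending value
rc_stop <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

rc_warn <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
}

# deterministic write.table wrapper: every pipeline TSV goes through here so
# outputs are byte-identical across runs
rc_write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}

rc_read_tsv <- function(path, ...) {
  if (!file.exists(path)) rc_stop("file not found: %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

DNA_BASES <- c("A", "C", "G", "T")

# reverse complement for plain character vectors of sequences
rc_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
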