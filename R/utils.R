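# internal utilities: small assertions and commented-TSV io used by every module

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

HYDROPHOBIC_D <- c("L", "I", "V", "F", "M")

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

#' Split a sequence string into single-letter vector
#' @noRd
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

#' Write a data frame as TSV with '#' provenance comments
#'
#' All tabular outputs of the package share this format: optional
#' '#'-prefixed comment lines (tool version, parameters), then a header row,
#' then tab-separated values.
#'
#' @param df data frame to write.
#' @param path output file path.
#' @param comments character vector of comment lines (without leading '#').
#' @return `path`, invisibly.
#' @export
write_tsv_commented <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- c(
    sprintf("# bzipscan %s", as.character(utils::packageVersion("bzipscan"))),
    if (length(comments)) paste0("# ", comments)
  )
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_commented()]
#' @param path file path.
#' @return data frame.
#' @export
read_tsv_commented <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Round a percentage the way family surveys report it
#'
#' `percentage(185, 197)` is 93.9: one decimal, halves rounded away from zero
#' (unlike base [round()], which rounds halves to even).
#'
#' @param k numerator count.
#' @param n denominator count (> 0).
#' @return percentage rounded to one decimal.
#' @examples
#' percentage(185, 197)
#' @export
percentage <- function(k, n) {
  abort_if(length(k) != 1L || length(n) != 1L || !is.numeric(k) || !is.numeric(n),
           "percentage() expects scalar counts")
  abort_if(n == 0, "percentage(): n must be > 0")
  abort_if(k < 0 || k > n, "percentage(): k must satisfy 0 <= k <= n")
  x <- 100 * k / n
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}
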