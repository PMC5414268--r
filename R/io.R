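#' Write a pipeline TSV with a self-describing header
#'
#' All tabular pipeline outputs share one layout: a single header line
#' starting with `#` carrying the tab-separated column names, then the rows.
#' Writing is atomic (temp file in the same directory, then rename) so a
#' crashed run never leaves a truncated table behind.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_neoscan_tsv <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(unlink(tmp), add = TRUE)
  con <- file(tmp, open = "wt")
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df)) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, na = "NA")
  }
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a pipeline TSV written by [write_neoscan_tsv()]
#'
#' @param path Input path.
#' @return A data.frame (zero rows if the table is empty).
#' @export
read_neoscan_tsv <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1L))
  cols <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  df <- utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                          col.names = cols, stringsAsFactors = FALSE,
                          comment.char = "", quote = "",
                          colClasses = NA, na.strings = "NA")
  if (nrow(df) == 0L) {
    df <- as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                        stringsAsFactors = FALSE)
  }
  df
}

# Deterministic 31-base modular string hash (documented constant modulus).
# Shared by the toy affinity backend and the run-log config hash; pure
# integer arithmetic on values < 2^31 so it is stable across platforms.
.neoscan_hash <- function(s, modulus = 1000003) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% modulus
  h
}
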