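#' Tabular output with metadata header
#'
#' All pipeline tables are plain CSV preceded by `#`-prefixed metadata
#' lines (seed, thresholds, package version), so every output records how
#' it was produced while staying trivially parseable.
#'
#' @param df data.frame to write.
#' @param path output file.
#' @param meta named list/vector written as `# name: value` lines.
#' @return `path`, invisibly.
#' @export
write_table_meta <- function(df, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, as.character(meta[[nm]])), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_meta
#' @export
read_table_meta <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Genotype matrix CSV round trip
#'
#' Lines as rows (first column `line`), markers as columns, calls in
#' `{-1, 0, 1, 2}`.
#'
#' @param geno integer call matrix with dimnames.
#' @param path file path.
#' @return For the reader, the integer matrix with dimnames restored.
#' @export
write_genotype_csv <- function(geno, path) {
  df <- data.frame(line = rownames(geno), geno, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_csv
#' @export
read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$line
  m
}
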