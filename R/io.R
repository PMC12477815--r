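#' Read a transcript count matrix from TSV
#'
#' Expects transcripts in rows (first column = transcript id) and samples in
#' columns.
#'
#' @param path TSV file.
#' @return integer matrix with transcript rownames.
#' @export
readCountMatrix <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  storage.mode(m) <- "integer"
  m
}

#' Write a tabular result as TSV
#'
#' Shared writer for pair tables, feature tables, variant tables and
#' estimate tables.
#'
#' @param x data.frame.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a study-tagged gene set file
#'
#' One gene id per line (optionally a second tab-separated study column; the
#' file is then split by study).
#'
#' @param path text file.
#' @return character vector, or named list of character vectors when a study
#'   column is present.
#' @export
readGeneSet <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (any(grepl("\t", lines, fixed = TRUE))) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    genes <- vapply(parts, `[`, character(1), 1L)
    study <- vapply(parts, `[`, character(1), 2L)
    split(genes, study)
  } else lines
}
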