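# Plain-text I/O: FASTA wrapped at 80 columns, tab-separated tables with a
# header row.

#' Write sequences as FASTA (80-column wrap)
#'
#' @param x An `XStringSet` (or named character; amino-acid assumed).
#' @param path Output file.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(x, filepath = path, width = 80L)
  invisible(path)
}

#' Read a protein FASTA
#' @param path Input file.
#' @return An [Biostrings::AAStringSet].
#' @export
read_protein_fasta <- function(path) Biostrings::readAAStringSet(path)

#' Read a nucleotide FASTA
#' @param path Input file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_nucleotide_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write a data.frame as TSV (header, no quotes, no row names)
#' @param x Data.frame.
#' @param path Output file.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with header
#' @param path Input file.
#' @return Data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write a counts matrix as TSV with a leading `sample_id` column
#' @param counts Matrix, samples x taxa.
#' @param path Output file.
#' @export
write_counts_table <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), as.data.frame(counts),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_table(df, path)
}

#' Read a counts matrix written by [write_counts_table()]
#' @param path Input file.
#' @return Integer matrix with sample-id row names.
#' @export
read_counts_table <- function(path) {
  df <- read_tsv_table(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}
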