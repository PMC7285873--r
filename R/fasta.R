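# FASTA/FASTQ input and output.

#' Read sequences from a FASTA or FASTQ file
#'
#' Auto-detects FASTA vs FASTQ from the first non-empty character
#' (\code{>} vs \code{@}); transparently reads gzip-compressed files.
#' Sequences are normalized to uppercase DNA: lowercase is raised and
#' \code{U} is mapped to \code{T}, so direct-RNA references in the RNA
#' alphabet are accepted.
#'
#' @param path path to a FASTA or FASTQ file, optionally gzipped.
#' @return named character vector of uppercase DNA sequences; names are the
#'   record ids (first whitespace-delimited token of the header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  con <- gzfile(path, "rt")
  first <- ""
  while (!length(first) || first == "") {
    first <- readLines(con, n = 1L)
    if (!length(first)) break
  }
  close(con)
  if (!length(first)) stopf("empty sequence file: %s", path)
  fmt <- substr(first, 1, 1)
  set <- if (fmt == ">") {
    Biostrings::readBStringSet(path, format = "fasta")
  } else if (fmt == "@") {
    Biostrings::readBStringSet(path, format = "fastq")
  } else {
    stopf("cannot detect FASTA/FASTQ format of %s (first character %s)",
          path, deparse(fmt))
  }
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stopf("empty sequence id in %s", path)
  if (anyDuplicated(ids)) {
    stopf("duplicate sequence id in %s: %s", path, ids[anyDuplicated(ids)])
  }
  if (any(nchar(seqs) < 1L)) stopf("zero-length sequence in %s", path)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stopf("sequence %s contains characters outside {A,C,G,T,N,U}",
          ids[which(bad)[1]])
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  if (anyDuplicated(names(seqs))) stopf("duplicate sequence ids")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
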