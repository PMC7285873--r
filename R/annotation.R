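# Transcript annotation: GTF/GFF parsing and the internal exon/intron model.
#
# Internal convention: all coordinates are 0-based half-open.  Conversion
# from the 1-based inclusive GTF/GFF convention happens here and only here.

#' Parse a GTF/GFF transcript annotation
#'
#' Reads exon features and assembles per-transcript exon and intron
#' structure.  Exons are stored sorted by genomic coordinate; the derived
#' intron list is ordered 5' to 3' in transcript orientation, so intron
#' index 1 is always the transcript's 5'-most intron (on the minus strand
#' this is the genomically last inter-exon gap).
#'
#' @param path GTF (2.2) or GFF3 file; exon features must carry a
#'   \code{transcript_id} attribute (GTF) or a \code{Parent} chain (GFF3).
#' @return object of class \code{tx_annotation}: a list of transcripts,
#'   each with \code{transcript_id}, \code{gene_id}, \code{chrom},
#'   \code{strand}, \code{exons} and \code{introns} (integer matrices with
#'   \code{start}/\code{end} columns, 0-based half-open genomic intervals).
#' @export
parse_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(ex) == 0L) stopf("no exon features in %s", path)
  mc <- S4Vectors::mcols(ex)
  tid <- if ("transcript_id" %in% names(mc)) {
    as.character(mc$transcript_id)
  } else if ("Parent" %in% names(mc)) {
    vapply(mc$Parent, function(p) sub("^transcript:", "", as.character(p)[1]),
           character(1))
  } else {
    stopf("exon features in %s carry neither transcript_id nor Parent", path)
  }
  gid <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id) else tid
  df <- data.frame(
    transcript_id = tid, gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(ex),
    stringsAsFactors = FALSE)
  build_annotation(df)
}

# Assemble a tx_annotation from a 0-based half-open exon table
# (columns transcript_id, gene_id, chrom, strand, start, end).
build_annotation <- function(df) {
  txs <- split(df, df$transcript_id)
  out <- lapply(txs, function(d) {
    if (nrow(d) == 0L) return(NULL)
    o <- order(d$start)
    if (any(o != seq_len(nrow(d)))) {
      warnf("unsorted exons for transcript %s; sorting", d$transcript_id[1])
      d <- d[o, , drop = FALSE]
    }
    ex <- cbind(start = d$start, end = d$end)
    if (nrow(ex) > 1L && any(ex[-1L, "start"] < ex[-nrow(ex), "end"])) {
      stopf("overlapping exons for transcript %s", d$transcript_id[1])
    }
    strand <- d$strand[1]
    introns <- if (nrow(ex) > 1L) {
      cbind(start = ex[-nrow(ex), "end"], end = ex[-1L, "start"])
    } else {
      matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
    }
    if (strand == "-" && nrow(introns) > 1L) {
      introns <- introns[rev(seq_len(nrow(introns))), , drop = FALSE]
    }
    list(transcript_id = d$transcript_id[1], gene_id = d$gene_id[1],
         chrom = d$chrom[1], strand = strand, exons = ex, introns = introns)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  structure(out, class = "tx_annotation")
}

#' @export
print.tx_annotation <- function(x, ...) {
  n_introns <- vapply(x, function(t) nrow(t$introns), integer(1))
  cat(sprintf("Transcript annotation: %d transcripts, %d with introns\n",
              length(x), sum(n_introns > 0)))
  invisible(x)
}

#' Write a tx_annotation as GTF
#'
#' Inverse of \code{\link{parse_annotation}} for exon features; converts the
#' internal 0-based half-open coordinates back to 1-based inclusive.
#'
#' @param annotation a \code{tx_annotation}.
#' @param path output GTF path.
#' @export
write_gtf <- function(annotation, path) {
  lines <- unlist(lapply(annotation, function(t) {
    attr <- sprintf('gene_id "%s"; transcript_id "%s";',
                    t$gene_id, t$transcript_id)
    sprintf("%s\tnanotxsim\texon\t%d\t%d\t.\t%s\t.\t%s",
            t$chrom, t$exons[, "start"] + 1L, t$exons[, "end"],
            t$strand, attr)
  }))
  writeLines(lines, path)
  invisible(path)
}

# Spliced transcript length (sum of exon widths).
transcript_length <- function(tx) sum(tx$exons[, "end"] - tx$exons[, "start"])

# Spliced transcript sequence from a genome (named character vector).
spliced_sequence <- function(tx, genome) {
  if (!tx$chrom %in% names(genome)) {
    stopf("chromosome %s missing from genome", tx$chrom)
  }
  chrseq <- genome[[tx$chrom]]
  parts <- substring(chrseq, tx$exons[, "start"] + 1L, tx$exons[, "end"])
  s <- paste(parts, collapse = "")
  if (tx$strand == "-") revcomp(s) else s
}
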