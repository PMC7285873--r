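# Alignment records and parsers (PAF with cs/cg tags, SAM/BAM).
#
# Every alignment is reduced to an "edit walk": an ordered run-length list
# of operations over {M (exact match), X (mismatch), I (insertion to the
# read), D (deletion from the read), N (skipped reference, i.e. splice)}.
# The match/mismatch distinction is load-bearing for the error model, so
# plain-M CIGARs are resolved to =/X using the MD tag or a provided
# reference, and parsing fails loudly when neither is available.

OP_M <- 1L; OP_X <- 2L; OP_I <- 3L; OP_D <- 4L; OP_N <- 5L
OP_CHARS <- c("M", "X", "I", "D", "N")

# Walk = integer matrix with columns op, len.
make_walk <- function(op, len) {
  w <- cbind(op = as.integer(op), len = as.integer(len))
  merge_walk(w[w[, "len"] > 0L, , drop = FALSE])
}

merge_walk <- function(w) {
  if (nrow(w) < 2L) return(w)
  new_run <- c(TRUE, w[-1L, "op"] != w[-nrow(w), "op"])
  grp <- cumsum(new_run)
  out <- cbind(w[new_run, "op"], as.integer(rowsum(w[, "len"], grp)[, 1]))
  dimnames(out) <- list(NULL, c("op", "len"))
  out
}

walk_query_len <- function(w) sum(w[w[, "op"] %in% c(OP_M, OP_X, OP_I), "len"])
walk_target_len <- function(w) sum(w[w[, "op"] %in% c(OP_M, OP_X, OP_D, OP_N), "len"])

new_alignment <- function(query_id, query_length, target_id, target_kind,
                          strand, query_start, query_end, target_start,
                          target_end, walk, is_primary = TRUE, score = NA_real_,
                          query_seq = NULL) {
  rec <- list(query_id = query_id, query_length = as.integer(query_length),
              target_id = target_id, target_kind = target_kind,
              strand = strand, query_start = as.integer(query_start),
              query_end = as.integer(query_end),
              target_start = as.integer(target_start),
              target_end = as.integer(target_end),
              walk = walk, is_primary = is_primary, score = score,
              query_seq = query_seq)
  class(rec) <- "alignment_record"
  rec
}

#' Validate an alignment record's edit-walk invariants
#'
#' Checks that query-consuming operation lengths sum to the query interval,
#' target-consuming lengths sum to the target interval, and adjacent
#' operations of identical type are merged.
#'
#' @param rec an alignment record.
#' @return \code{TRUE} invisibly, or an error.
#' @export
check_alignment <- function(rec) {
  w <- rec$walk
  if (walk_query_len(w) != rec$query_end - rec$query_start) {
    stopf("alignment %s: query-consuming ops (%d) != query interval (%d)",
          rec$query_id, walk_query_len(w), rec$query_end - rec$query_start)
  }
  if (walk_target_len(w) != rec$target_end - rec$target_start) {
    stopf("alignment %s: target-consuming ops (%d) != target interval (%d)",
          rec$query_id, walk_target_len(w), rec$target_end - rec$target_start)
  }
  if (nrow(w) > 1L && any(w[-1L, "op"] == w[-nrow(w), "op"])) {
    stopf("alignment %s: adjacent ops of identical type not merged",
          rec$query_id)
  }
  invisible(TRUE)
}

tokenize_cigar <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  tok <- regmatches(cigar, list(m))[[1]]
  if (!length(tok) || sum(attr(m, "match.length")) != nchar(cigar)) {
    stopf("malformed CIGAR: %s", cigar)
  }
  list(op = substr(tok, nchar(tok), nchar(tok)),
       len = as.integer(substr(tok, 1L, nchar(tok) - 1L)))
}

# Resolve plain-M CIGAR ops to =/X by comparing query and reference bases.
# `qseq` is the aligned-orientation query sequence, `tseq` the reference
# sequence of the target (full chromosome/transcript string).
resolve_m_by_reference <- function(op, len, qseq, tseq, qstart, tstart) {
  out_op <- integer(0); out_len <- integer(0)
  qi <- qstart; ti <- tstart
  for (k in seq_along(op)) {
    o <- op[k]; l <- len[k]
    if (o == "M") {
      q <- strsplit(substr(qseq, qi + 1L, qi + l), "")[[1]]
      t <- strsplit(substr(tseq, ti + 1L, ti + l), "")[[1]]
      eq <- q == t
      r <- rle(eq)
      out_op <- c(out_op, ifelse(r$values, OP_M, OP_X))
      out_len <- c(out_len, r$lengths)
      qi <- qi + l; ti <- ti + l
    } else {
      code <- switch(o, "=" = OP_M, "X" = OP_X, "I" = OP_I, "D" = OP_D,
                     "N" = OP_N, NULL)
      if (!is.null(code)) { out_op <- c(out_op, code); out_len <- c(out_len, l) }
      if (o %in% c("=", "X", "I")) qi <- qi + l
      if (o %in% c("=", "X", "D", "N")) ti <- ti + l
    }
  }
  make_walk(out_op, out_len)
}

# Resolve plain-M ops using the SAM MD tag (reference-free).
resolve_m_by_md <- function(op, len, md) {
  # Expand M runs into per-base match/mismatch using MD, then re-run-length.
  toks <- regmatches(md, gregexpr("\\d+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  # per-aligned-base stream over M/X columns only (MD skips insertions)
  md_stream <- integer(0)
  for (t in toks) {
    if (grepl("^\\d+$", t)) {
      md_stream <- c(md_stream, rep(OP_M, as.integer(t)))
    } else if (startsWith(t, "^")) {
      # deletion block; consumed by D ops, nothing added for M columns
    } else {
      md_stream <- c(md_stream, OP_X)
    }
  }
  out_op <- integer(0); out_len <- integer(0)
  pos <- 0L
  for (k in seq_along(op)) {
    o <- op[k]; l <- len[k]
    if (o == "M") {
      seg <- md_stream[(pos + 1L):(pos + l)]
      r <- rle(seg)
      out_op <- c(out_op, r$values); out_len <- c(out_len, r$lengths)
      pos <- pos + l
    } else {
      code <- switch(o, "=" = OP_M, "X" = OP_X, "I" = OP_I, "D" = OP_D,
                     "N" = OP_N, NULL)
      if (!is.null(code)) { out_op <- c(out_op, code); out_len <- c(out_len, l) }
      if (o %in% c("=", "X")) pos <- pos + l
    }
  }
  make_walk(out_op, out_len)
}

parse_cs_tag <- function(cs) {
  toks <- regmatches(cs, gregexpr(":[0-9]+|\\*[a-zA-Z][a-zA-Z]|\\+[a-zA-Z]+|-[a-zA-Z]+|~[a-zA-Z][a-zA-Z][0-9]+[a-zA-Z][a-zA-Z]", cs))[[1]]
  if (!length(toks)) stopf("malformed cs tag: %s", cs)
  op <- integer(length(toks)); len <- integer(length(toks))
  for (k in seq_along(toks)) {
    t <- toks[k]
    c1 <- substr(t, 1, 1)
    if (c1 == ":") { op[k] <- OP_M; len[k] <- as.integer(substr(t, 2, nchar(t))) }
    else if (c1 == "*") { op[k] <- OP_X; len[k] <- 1L }
    else if (c1 == "+") { op[k] <- OP_I; len[k] <- nchar(t) - 1L }
    else if (c1 == "-") { op[k] <- OP_D; len[k] <- nchar(t) - 1L }
    else { op[k] <- OP_N; len[k] <- as.integer(gsub("[a-zA-Z~]", "", t)) }
  }
  make_walk(op, len)
}

#' Parse alignments from PAF, SAM or BAM
#'
#' PAF requires a \code{cs} or \code{cg} tag; SAM/BAM requires a CIGAR.
#' CIGARs written with \code{=}/\code{X} are used directly; plain \code{M}
#' operations are resolved through the MD tag, or by base comparison against
#' \code{reference} when supplied.  Without either, parsing stops and asks
#' for re-alignment with \code{--eqx} or a reference.
#'
#' @param path PAF, SAM or BAM file (format chosen by extension:
#'   \code{.paf[.gz]}, \code{.sam}, \code{.bam}).
#' @param target_kind \code{"transcriptome"} or \code{"genome"}; recorded on
#'   every record.
#' @param reference optional named character vector of target sequences used
#'   to resolve plain-M CIGARs.
#' @return list of alignment records (each satisfying
#'   \code{\link{check_alignment}}).
#' @export
parse_alignments <- function(path, target_kind = c("transcriptome", "genome"),
                             reference = NULL) {
  target_kind <- match.arg(target_kind)
  ext <- tolower(sub("\\.gz$", "", path))
  if (grepl("\\.paf$", ext)) {
    parse_paf(path, target_kind)
  } else if (grepl("\\.sam$", ext)) {
    parse_sam_lines(readLines(path), target_kind, reference)
  } else if (grepl("\\.bam$", ext)) {
    parse_bam(path, target_kind, reference)
  } else {
    stopf("cannot determine alignment format of %s (expect .paf/.sam/.bam)", path)
  }
}

parse_paf <- function(path, target_kind) {
  lines <- readLines(gzfile(path))
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L) stopf("malformed PAF at line %d", i)
    tags <- f[-(1:12)]
    cs <- sub("^cs:Z:", "", grep("^cs:Z:", tags, value = TRUE))
    cg <- sub("^cg:Z:", "", grep("^cg:Z:", tags, value = TRUE))
    tp <- sub("^tp:A:", "", grep("^tp:A:", tags, value = TRUE))
    walk <- if (length(cs)) {
      parse_cs_tag(cs[1])
    } else if (length(cg)) {
      tk <- tokenize_cigar(cg[1])
      if (any(tk$op == "M")) {
        stopf("PAF line %d: cg tag contains plain M and no cs tag; re-align with --cs or --eqx", i)
      }
      code <- c("=" = OP_M, "X" = OP_X, "I" = OP_I, "D" = OP_D, "N" = OP_N)[tk$op]
      make_walk(code, tk$len)
    } else {
      stopf("PAF line %d has neither cs nor cg tag", i)
    }
    out[[i]] <- new_alignment(
      query_id = f[1], query_length = as.integer(f[2]),
      target_id = f[6], target_kind = target_kind, strand = f[5],
      query_start = as.integer(f[3]), query_end = as.integer(f[4]),
      target_start = as.integer(f[8]), target_end = as.integer(f[9]),
      walk = walk, is_primary = !length(tp) || tp[1] == "P",
      score = as.numeric(f[10]))  # matching bases
  }
  out
}

parse_sam_lines <- function(lines, target_kind, reference = NULL) {
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) stopf("malformed SAM at line %d", i)
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) next  # unmapped
    md <- sub("^MD:Z:", "", grep("^MD:Z:", f[-(1:11)], value = TRUE))
    out[[i]] <- sam_record(qname = f[1], flag = flag, rname = f[3],
                           pos0 = as.integer(f[4]) - 1L, cigar = f[6],
                           seq = f[10], md = if (length(md)) md[1] else NULL,
                           score = sam_as_score(f), target_kind = target_kind,
                           reference = reference)
  }
  out[!vapply(out, is.null, logical(1))]
}

sam_as_score <- function(f) {
  as_tag <- grep("^AS:i:", f[-(1:11)], value = TRUE)
  if (length(as_tag)) as.numeric(sub("^AS:i:", "", as_tag[1])) else NA_real_
}

sam_record <- function(qname, flag, rname, pos0, cigar, seq, md, score,
                       target_kind, reference) {
  tk <- tokenize_cigar(cigar)
  op <- tk$op; len <- tk$len
  lead_clip <- if (op[1] %in% c("S", "H")) len[1] else 0L
  trail_clip <- if (op[length(op)] %in% c("S", "H")) len[length(op)] else 0L
  core <- !(op %in% c("S", "H", "P"))
  qlen <- sum(len[op %in% c("M", "I", "S", "=", "X")]) +
    sum(len[op == "H"])
  walk <- if (any(op == "M")) {
    if (!is.null(md)) {
      resolve_m_by_md(op[core], len[core], md)
    } else if (!is.null(reference) && !is.null(reference[[rname]]) &&
               seq != "*") {
      resolve_m_by_reference(op[core], len[core], toupper(seq),
                             reference[[rname]],
                             qstart = lead_clip, tstart = pos0)
    } else {
      stopf("read %s: CIGAR has plain M but no MD tag and no reference; re-align with --eqx or provide the reference", qname)
    }
  } else {
    code <- c("=" = OP_M, "X" = OP_X, "I" = OP_I, "D" = OP_D, "N" = OP_N)[op[core]]
    make_walk(code, len[core])
  }
  reversed <- bitwAnd(flag, 16L) > 0L
  qs <- lead_clip; qe <- qlen - trail_clip
  if (reversed) { tmp <- qs; qs <- qlen - qe; qe <- qlen - tmp }
  new_alignment(
    query_id = qname, query_length = qlen, target_id = rname,
    target_kind = target_kind, strand = if (reversed) "-" else "+",
    query_start = qs, query_end = qe,
    target_start = pos0, target_end = pos0 + walk_target_len(walk),
    walk = walk,
    is_primary = bitwAnd(flag, 256L) == 0L && bitwAnd(flag, 2048L) == 0L,
    score = score,
    query_seq = if (seq != "*") toupper(seq) else NULL)
}

parse_bam <- function(path, target_kind, reference = NULL) {
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = c("MD", "AS"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  n <- length(b$qname)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (is.na(b$pos[i])) next
    out[[i]] <- sam_record(
      qname = b$qname[i], flag = b$flag[i],
      rname = as.character(b$rname[i]), pos0 = b$pos[i] - 1L,
      cigar = b$cigar[i], seq = as.character(b$seq[i]),
      md = if (!is.null(b$tag$MD)) b$tag$MD[i] else NULL,
      score = if (!is.null(b$tag$AS)) as.numeric(b$tag$AS[i]) else NA_real_,
      target_kind = target_kind, reference = reference)
  }
  out[!vapply(out, is.null, logical(1))]
}

# Reference-space blocks of a walk: aligned (M/X, merged across I/D) blocks
# and N gaps, as 0-based half-open intervals on the target.
walk_ref_blocks <- function(rec) {
  w <- rec$walk
  consumes <- c(1L, 1L, 0L, 1L, 1L)[w[, "op"]] * w[, "len"]
  ends <- rec$target_start + cumsum(consumes)
  starts <- ends - consumes
  is_n <- w[, "op"] == OP_N
  aligned <- w[, "op"] %in% c(OP_M, OP_X)
  list(aligned = cbind(start = starts[aligned], end = ends[aligned]),
       gaps = cbind(start = starts[is_n], end = ends[is_n]))
}

# cg-style CIGAR string of a walk, written with =/X (never plain M).
walk_to_cigar <- function(w) {
  ch <- c("=", "X", "I", "D", "N")[w[, "op"]]
  paste0(w[, "len"], ch, collapse = "")
}

#' Write alignment records as PAF
#'
#' Emits minimap2-style PAF lines with a \code{cg:Z:} tag written in
#' \code{=}/\code{X} operations and a \code{tp:A:} primary/secondary tag,
#' so files round-trip through \code{\link{parse_alignments}}.
#'
#' @param alignments list of alignment records.
#' @param path output path.
#' @param target_lengths optional named vector of target sequence lengths
#'   (column 7; 0 when unknown).
#' @export
write_paf <- function(alignments, path, target_lengths = NULL) {
  lines <- vapply(alignments, function(a) {
    tl <- if (!is.null(target_lengths)) target_lengths[[a$target_id]] else 0L
    matches <- sum(a$walk[a$walk[, "op"] == OP_M, "len"])
    paste(a$query_id, a$query_length, a$query_start, a$query_end, a$strand,
          a$target_id, tl, a$target_start, a$target_end, matches,
          walk_target_len(a$walk), 60L,
          paste0("tp:A:", if (isTRUE(a$is_primary)) "P" else "S"),
          paste0("cg:Z:", walk_to_cigar(a$walk)), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
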