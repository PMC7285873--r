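# Deterministic synthetic-corpus generator.
#
# Generates genomes, transcriptomes, annotations and reads whose governing
# parameters are fully known, together with their *exact* alignments (no
# aligner involved), so that every characterization operation can be
# validated by closed-loop parameter recovery.  The sampling code here is
# deliberately independent of the simulator module: recovery tests are
# genuine cross-checks, not self-consistency checks.

#' Specification of a synthetic corpus
#'
#' Defaults describe a realistic small ONT RNA-seq training set: moderately
#' sized multi-exon genes, log-normal expression, base-call error rates of
#' 5/3/3 percent (mismatch/insertion/deletion), an intron-retention chain
#' with rare first-intron retention but strongly elevated conditional
#' retention, an 85 percent sense-strand ratio and a small unaligned
#' fraction.
#'
#' @param n_genes number of genes.
#' @param exons_per_gene integer range (min, max).
#' @param exon_len,intron_len integer ranges (nt).
#' @param spacer inter-genic spacer length (nt).
#' @param minus_strand_prob probability a gene is annotated on the minus
#'   strand.
#' @param plant_homopolymers plant known homopolymer runs in exons.
#' @param hp_len_range planted run length range.
#' @param expr_meanlog,expr_sdlog log-normal expression law.
#' @param mis_rate,ins_rate,del_rate target error rates per aligned
#'   reference base.
#' @param mis_mix,ins_mix,del_mix per-type length-mixture parameters.
#' @param markov_self self-stickiness of the error-type chain: the chain is
#'   \code{self * I + (1 - self) * 1 s'} where \code{s} is the stationary
#'   distribution implied by the rates and mixture means.
#' @param ratio_shape Beta parameters of the aligned ratio, or NULL for
#'   full-length reads.
#' @param flank_meanlog,flank_sdlog log-normal head/tail flank law.
#' @param strand_ratio sense-strand fraction.
#' @param unaligned_fraction fraction of reads that do not align.
#' @param unaligned_meanlog10,unaligned_sdlog10 log10-normal law of
#'   unaligned read lengths.
#' @param ir_chain IR chain (p_first, p_retain_given_spliced,
#'   p_retain_given_retained), or NULL to disable IR.
#' @param hp_mean_slope,hp_sd_slope,hp_sd_intercept homopolymer read-length
#'   law: read length ~ Normal(slope * L, sd_slope * L + sd_intercept).
#' @return a \code{fixture_spec} list.
#' @export
fixture_spec <- function(n_genes = 50L,
                         exons_per_gene = c(2L, 6L),
                         exon_len = c(100L, 400L),
                         intron_len = c(80L, 400L),
                         spacer = 200L,
                         minus_strand_prob = 0.5,
                         plant_homopolymers = FALSE,
                         hp_len_range = c(5L, 20L),
                         expr_meanlog = 3, expr_sdlog = 1.2,
                         mis_rate = 0.05, ins_rate = 0.03, del_rate = 0.03,
                         mis_mix = list(w = 0.4, lambda = 0.9, p_geom = 0.75),
                         ins_mix = list(w = 0.5, shape = 1.1, scale = 1.6,
                                        p_geom = 0.6),
                         del_mix = list(w = 0.5, shape = 1.1, scale = 1.6,
                                        p_geom = 0.6),
                         markov_self = 0.2,
                         ratio_shape = c(5, 2),
                         flank_meanlog = 2.2, flank_sdlog = 0.6,
                         strand_ratio = 0.85,
                         unaligned_fraction = 0.05,
                         unaligned_meanlog10 = 2.5, unaligned_sdlog10 = 0.3,
                         ir_chain = NULL,
                         hp_mean_slope = 0.9, hp_sd_slope = 0.05,
                         hp_sd_intercept = 0.3) {
  spec <- as.list(environment())
  stopifnot(mis_rate >= 0, ins_rate >= 0, del_rate >= 0,
            mis_rate + del_rate < 1,
            strand_ratio >= 0, strand_ratio <= 1,
            unaligned_fraction >= 0, unaligned_fraction <= 1)
  if (!is.null(ir_chain)) {
    stopifnot(length(ir_chain) == 3L, all(ir_chain >= 0), all(ir_chain <= 1))
    if (mis_rate + ins_rate + del_rate > 0) {
      stopf("IR fixtures require zero error rates (exact genomic alignments)")
    }
  }
  class(spec) <- "fixture_spec"
  spec
}

# Derived error-process parameters of a spec: per-type mixture means, the
# stationary type distribution, the full transition matrix and the mean
# match-stretch length that realizes the target rates.
fixture_error_process <- function(spec) {
  mean_pois_trunc <- function(l) l / (1 - exp(-l))
  mean_weib_disc <- function(k, s) {
    x <- 1:2000
    p <- stats::pweibull(x + 0.5, k, s) - stats::pweibull(pmax(x - 0.5, 0.5), k, s)
    sum(x * p) / sum(p)
  }
  m <- c(mis = spec$mis_mix$w * mean_pois_trunc(spec$mis_mix$lambda) +
           (1 - spec$mis_mix$w) / spec$mis_mix$p_geom,
         ins = spec$ins_mix$w * mean_weib_disc(spec$ins_mix$shape, spec$ins_mix$scale) +
           (1 - spec$ins_mix$w) / spec$ins_mix$p_geom,
         del = spec$del_mix$w * mean_weib_disc(spec$del_mix$shape, spec$del_mix$scale) +
           (1 - spec$del_mix$w) / spec$del_mix$p_geom)
  rates <- c(mis = spec$mis_rate, ins = spec$ins_rate, del = spec$del_rate)
  if (sum(rates) == 0) {
    return(list(means = m, stationary = rep(1 / 3, 3), P = NULL,
                match_mean = Inf, rates = rates))
  }
  s <- (rates / m) / sum(rates / m)
  P <- spec$markov_self * diag(3) +
    (1 - spec$markov_self) * matrix(s, 3, 3, byrow = TRUE)
  dimnames(P) <- list(ERR_TYPES, ERR_TYPES)
  e_ref <- s[1] * m[1] + s[3] * m[3]
  r_cons <- rates["mis"] + rates["del"]
  match_mean <- e_ref * (1 - r_cons) / r_cons
  list(means = m, stationary = s, P = P, match_mean = unname(match_mean),
       rates = rates)
}

# sample integers uniformly from [lo, hi] (safe for lo == hi)
sample_range <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

plant_run <- function(seq_chars, base, start, len) {
  seq_chars[start:(start + len - 1L)] <- base
  # enforce maximality: flanks differ from the run base
  others <- setdiff(DNA_BASES, base)
  if (start > 1L) seq_chars[start - 1L] <- sample(others, 1L)
  if (start + len <= length(seq_chars)) {
    seq_chars[start + len] <- sample(others, 1L)
  }
  seq_chars
}

#' Generate a synthetic genome, transcriptome and annotation
#'
#' @param spec a \code{fixture_spec}.
#' @return list with \code{genome} (named character vector),
#'   \code{transcriptome}, \code{annotation} (a \code{tx_annotation}),
#'   \code{tpm} (named true-expression vector summing to 1e6) and
#'   \code{planted_runs} (data.frame of planted homopolymer runs in
#'   transcript coordinates, plus-strand genes only).
#' @export
make_reference <- function(spec) {
  n <- spec$n_genes
  chrom_parts <- character(0)
  offset <- 0L
  exon_rows <- list()
  planted <- list()
  for (g in seq_len(n)) {
    tid <- sprintf("T%04d", g)
    gid <- sprintf("G%04d", g)
    strand <- if (stats::runif(1) < spec$minus_strand_prob) "-" else "+"
    n_e <- sample_range(spec$exons_per_gene[1], spec$exons_per_gene[2])
    e_lens <- sample_range(spec$exon_len[1], spec$exon_len[2], n_e)
    i_lens <- if (n_e > 1L) {
      sample_range(spec$intron_len[1], spec$intron_len[2], n_e - 1L)
    } else integer(0)
    pieces <- character(0)
    pos <- offset
    tx_off <- 0L
    for (e in seq_len(n_e)) {
      chars <- sample(DNA_BASES, e_lens[e], replace = TRUE)
      if (spec$plant_homopolymers && e_lens[e] >= spec$hp_len_range[2] + 10L) {
        base <- sample(DNA_BASES, 1L)
        len <- sample_range(spec$hp_len_range[1], spec$hp_len_range[2])
        start <- sample.int(e_lens[e] - len - 2L, 1L) + 1L  # interior
        chars <- plant_run(chars, base, start, len)
        if (strand == "+") {
          planted[[length(planted) + 1L]] <- data.frame(
            transcript_id = tid, base = base,
            start = tx_off + start - 1L, length = len,
            stringsAsFactors = FALSE)
        }
      }
      pieces <- c(pieces, paste(chars, collapse = ""))
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        transcript_id = tid, gene_id = gid, chrom = "chr1", strand = strand,
        start = pos, end = pos + e_lens[e], stringsAsFactors = FALSE)
      pos <- pos + e_lens[e]
      tx_off <- tx_off + e_lens[e]
      if (e < n_e) {
        pieces <- c(pieces, paste(sample(DNA_BASES, i_lens[e], replace = TRUE),
                                  collapse = ""))
        pos <- pos + i_lens[e]
      }
    }
    pieces <- c(pieces, paste(sample(DNA_BASES, spec$spacer, replace = TRUE),
                              collapse = ""))
    chrom_parts <- c(chrom_parts, pieces)
    offset <- pos + spec$spacer
  }
  genome <- c(chr1 = paste(chrom_parts, collapse = ""))
  annotation <- build_annotation(do.call(rbind, exon_rows))
  transcriptome <- vapply(annotation, spliced_sequence, character(1),
                          genome = genome)
  names(transcriptome) <- vapply(annotation, `[[`, character(1), "transcript_id")
  w <- stats::rlnorm(n, spec$expr_meanlog, spec$expr_sdlog)
  tpm <- w / sum(w) * 1e6
  names(tpm) <- names(transcriptome)
  list(genome = genome, transcriptome = transcriptome,
       annotation = annotation, tpm = tpm,
       planted_runs = if (length(planted)) do.call(rbind, planted) else
         data.frame(transcript_id = character(0), base = character(0),
                    start = integer(0), length = integer(0)))
}

# Independent samplers for the fixture error process (rejection-style,
# intentionally not shared with the model code).
fx_sample_len <- function(type, spec) {
  mix <- switch(type, spec$mis_mix, spec$ins_mix, spec$del_mix)
  if (stats::runif(1) < mix$w) {
    if (type == 1L) {
      repeat { x <- stats::rpois(1L, mix$lambda); if (x >= 1L) return(x) }
    }
    repeat {
      x <- as.integer(round(stats::rweibull(1L, mix$shape, mix$scale)))
      if (x >= 1L) return(x)
    }
  }
  stats::rgeom(1L, mix$p_geom) + 1L
}

# One error walk over `A` aligned reference bases under the spec's process.
fx_error_walk <- function(A, spec, proc) {
  if (sum(proc$rates) == 0) return(cbind(op = OP_M, len = as.integer(A)))
  # match stretches on support {1, 2, ...} so that consecutive errors never
  # abut: abutting same-type errors would merge in the walk and make the
  # type chain unidentifiable from alignments
  p_match <- 1 / max(proc$match_mean, 1)
  cumP <- t(apply(proc$P, 1, cumsum))
  ops <- integer(0); lens <- integer(0)
  consumed <- 0L
  state <- NA_integer_
  repeat {
    m <- stats::rgeom(1L, p_match) + 1L
    if (consumed + m >= A) {
      if (A - consumed > 0L) { ops <- c(ops, OP_M); lens <- c(lens, A - consumed) }
      break
    }
    if (m > 0L) { ops <- c(ops, OP_M); lens <- c(lens, m); consumed <- consumed + m }
    state <- if (is.na(state)) {
      sample.int(3L, 1L, prob = proc$stationary)
    } else {
      u <- stats::runif(1)
      1L + (u > cumP[state, 1]) + (u > cumP[state, 2])
    }
    l <- fx_sample_len(state, spec)
    if (state != 2L) {  # mis or del consume reference
      l <- min(l, A - consumed)
      consumed <- consumed + l
    }
    ops <- c(ops, c(OP_X, OP_I, OP_D)[state])
    lens <- c(lens, l)
    if (consumed >= A) break
  }
  make_walk(ops, lens)
}

# Genomic-orientation IR state vector for a transcript pattern.
fx_genomic_states <- function(pattern, strand) {
  if (strand == "-") rev(pattern) else pattern
}

#' Generate synthetic reads with exact alignments
#'
#' Draws reads from the spec's true parameters -- source transcript by
#' expression, optional IR pattern from the true chain, aligned ratio,
#' flanks, strand, and error walks from the true mixtures and type chain --
#' and emits their exact alignment records directly (no aligner).  With an
#' IR chain the reads are full-length and error-free, and matching genome
#' alignment records (M through retained introns, N across spliced ones)
#' are emitted as well.
#'
#' @param spec a \code{fixture_spec}.
#' @param ref references from \code{\link{make_reference}}.
#' @param n_reads number of reads (including unaligned ones).
#' @param emit_sequences also construct the read sequences (slower; only
#'   needed when the sequences themselves are under test).
#' @return list with \code{transcriptome_alignments},
#'   \code{genome_alignments} (NULL unless IR), \code{unaligned_lengths},
#'   \code{truth} (per-read data.frame), \code{ir_patterns} (list, NULL
#'   entries for intron-less reads) and optionally \code{sequences}.
#' @export
make_reads_with_truth <- function(spec, ref, n_reads, emit_sequences = FALSE) {
  proc <- fixture_error_process(spec)
  n_un <- as.integer(round(n_reads * spec$unaligned_fraction))
  n_al <- n_reads - n_un
  tids <- sample(names(ref$tpm), n_al, replace = TRUE, prob = ref$tpm)
  ann_ids <- vapply(ref$annotation, `[[`, character(1), "transcript_id")
  tx_aligns <- vector("list", n_al)
  g_aligns <- if (!is.null(spec$ir_chain)) vector("list", n_al)
  ir_patterns <- vector("list", n_al)
  truth <- vector("list", n_al)
  seqs <- if (emit_sequences) character(n_al)
  for (i in seq_len(n_al)) {
    tid <- tids[i]
    tx <- ref$annotation[[match(tid, ann_ids)]]
    n_int <- nrow(tx$introns)
    pattern <- NULL
    if (!is.null(spec$ir_chain) && n_int > 0L) {
      pattern <- logical(n_int)
      pattern[1] <- stats::runif(1) < spec$ir_chain[1]
      if (n_int > 1L) for (j in 2:n_int) {
        p <- if (pattern[j - 1]) spec$ir_chain[3] else spec$ir_chain[2]
        pattern[j] <- stats::runif(1) < p
      }
      ir_patterns[[i]] <- pattern
    }
    mol_len <- transcript_length(tx) +
      if (!is.null(pattern)) sum(tx$introns[pattern, "end"] -
                                   tx$introns[pattern, "start"]) else 0L
    ratio <- if (is.null(spec$ratio_shape)) 1 else {
      stats::rbeta(1, spec$ratio_shape[1], spec$ratio_shape[2])
    }
    A <- max(1L, as.integer(round(ratio * mol_len)))
    start <- mol_len - A  # 3'-anchored
    head_len <- as.integer(round(stats::rlnorm(1, spec$flank_meanlog,
                                               spec$flank_sdlog)))
    tail_len <- as.integer(round(stats::rlnorm(1, spec$flank_meanlog,
                                               spec$flank_sdlog)))
    strand <- if (stats::runif(1) < spec$strand_ratio) "+" else "-"
    rid <- sprintf("fx%06d", i)
    if (is.null(pattern) || !any(pattern)) {
      walk <- fx_error_walk(A, spec, proc)
      # molecule == spliced transcript; alignment is plain
      qlen_core <- walk_query_len(walk)
      tx_aligns[[i]] <- new_alignment(
        query_id = rid, query_length = head_len + qlen_core + tail_len,
        target_id = tid, target_kind = "transcriptome", strand = strand,
        query_start = head_len, query_end = head_len + qlen_core,
        target_start = start, target_end = start + A, walk = walk,
        score = sum(walk[walk[, "op"] == OP_M, "len"]))
      if (!is.null(spec$ir_chain)) {
        g_aligns[[i]] <- fx_genome_alignment(rid, tx, rep(FALSE, n_int),
                                             head_len, tail_len, strand)
      }
    } else {
      # IR read: full-length, error-free (enforced by fixture_spec)
      walk <- fx_ir_tx_walk(tx, pattern)
      qlen_core <- walk_query_len(walk)
      tx_aligns[[i]] <- new_alignment(
        query_id = rid, query_length = head_len + qlen_core + tail_len,
        target_id = tid, target_kind = "transcriptome", strand = strand,
        query_start = head_len, query_end = head_len + qlen_core,
        target_start = 0L, target_end = transcript_length(tx), walk = walk,
        score = sum(walk[walk[, "op"] == OP_M, "len"]))
      g_aligns[[i]] <- fx_genome_alignment(rid, tx, pattern, head_len,
                                           tail_len, strand)
    }
    truth[[i]] <- data.frame(
      read_id = rid, transcript_id = tid, strand = strand, tstart = start,
      aligned_len = A, head_len = head_len, tail_len = tail_len,
      mol_len = mol_len, stringsAsFactors = FALSE)
    if (emit_sequences) {
      seqs[i] <- fx_realize_sequence(tx_aligns[[i]], ref$transcriptome[[tid]])
    }
  }
  unaligned_lengths <- if (n_un > 0L) {
    pmax(20L, as.integer(round(10^stats::rnorm(n_un, spec$unaligned_meanlog10,
                                               spec$unaligned_sdlog10))))
  } else integer(0)
  list(transcriptome_alignments = tx_aligns,
       genome_alignments = g_aligns,
       unaligned_lengths = unaligned_lengths,
       truth = do.call(rbind, truth),
       ir_patterns = ir_patterns,
       sequences = if (emit_sequences) stats::setNames(seqs, vapply(tx_aligns, `[[`, character(1), "query_id")))
}

# Transcriptome-space walk of a full-length IR read: M over exon blocks,
# I runs where a retained intron inserts sequence (transcript order).
fx_ir_tx_walk <- function(tx, pattern) {
  n_e <- nrow(tx$exons)
  e_lens <- tx$exons[, "end"] - tx$exons[, "start"]
  i_lens_genomic <- if (n_e > 1L) {
    # genomic gap lengths, genomic order
    tx$exons[-1L, "start"] - tx$exons[-n_e, "end"]
  } else integer(0)
  # in transcript order
  e_lens_tx <- if (tx$strand == "-") rev(e_lens) else e_lens
  i_lens_tx <- if (tx$strand == "-") rev(i_lens_genomic) else i_lens_genomic
  ops <- integer(0); lens <- integer(0)
  for (e in seq_len(n_e)) {
    ops <- c(ops, OP_M); lens <- c(lens, e_lens_tx[e])
    if (e < n_e && pattern[e]) {
      ops <- c(ops, OP_I); lens <- c(lens, i_lens_tx[e])
    }
  }
  make_walk(ops, lens)
}

# Genome-space alignment of a full-length read: M over exons and retained
# introns, N across spliced introns.  Coordinates and op order are genomic.
fx_genome_alignment <- function(rid, tx, pattern, head_len, tail_len, strand) {
  n_e <- nrow(tx$exons)
  states_genomic <- fx_genomic_states(pattern, tx$strand)
  ops <- integer(0); lens <- integer(0)
  for (e in seq_len(n_e)) {
    ops <- c(ops, OP_M); lens <- c(lens, tx$exons[e, "end"] - tx$exons[e, "start"])
    if (e < n_e) {
      gap <- tx$exons[e + 1L, "start"] - tx$exons[e, "end"]
      if (states_genomic[e]) {
        ops <- c(ops, OP_M); lens <- c(lens, gap)
      } else {
        ops <- c(ops, OP_N); lens <- c(lens, gap)
      }
    }
  }
  walk <- make_walk(ops, lens)
  qlen_core <- walk_query_len(walk)
  g_strand <- if ((tx$strand == "-") == (strand == "-")) "+" else "-"
  new_alignment(
    query_id = rid, query_length = head_len + qlen_core + tail_len,
    target_id = tx$chrom, target_kind = "genome", strand = g_strand,
    query_start = head_len, query_end = head_len + qlen_core,
    target_start = tx$exons[1, "start"], target_end = tx$exons[n_e, "end"],
    walk = walk, score = qlen_core)
}

# Realize the read sequence implied by an exact transcriptome alignment.
fx_realize_sequence <- function(a, tx_seq) {
  w <- a$walk
  out <- character(nrow(w))
  tpos <- a$target_start
  for (j in seq_len(nrow(w))) {
    o <- w[j, "op"]; l <- w[j, "len"]
    if (o == OP_M) {
      out[j] <- substring(tx_seq, tpos + 1L, tpos + l)
      tpos <- tpos + l
    } else if (o == OP_X) {
      ref <- strsplit(substring(tx_seq, tpos + 1L, tpos + l), "")[[1]]
      out[j] <- paste(substitute_bases(ref), collapse = "")
      tpos <- tpos + l
    } else if (o == OP_I) {
      out[j] <- paste(sample(DNA_BASES, l, replace = TRUE), collapse = "")
    } else if (o %in% c(OP_D, OP_N)) {
      tpos <- tpos + l
    }
  }
  core <- paste(out, collapse = "")
  read <- paste0(random_dna(a$query_start), core,
                 random_dna(a$query_length - a$query_end))
  if (a$strand == "-") revcomp(read) else read
}

#' Generate homopolymer-focused reads
#'
#' Full-length, otherwise error-free reads whose only distortions are
#' homopolymer length changes drawn from the spec's true law
#' (Normal(slope * L, sd_slope * L + sd_intercept), rounded, clamped at 0).
#' Length changes are realized as deletion/insertion runs in the interior
#' of each reference run, so the emitted walks are exact.
#'
#' @param spec a \code{fixture_spec} with \code{plant_homopolymers = TRUE}.
#' @param ref references from \code{\link{make_reference}}.
#' @param n_reads number of reads.
#' @param min_len minimum run length modelled.
#' @return list with \code{alignments} and \code{observations} (the true
#'   per-run (base, ref_len, read_len) table).
#' @export
make_hp_reads <- function(spec, ref, n_reads, min_len = 5L) {
  tids <- sample(names(ref$tpm), n_reads, replace = TRUE, prob = ref$tpm)
  aligns <- vector("list", n_reads)
  obs <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    tid <- tids[i]
    seq <- ref$transcriptome[[tid]]
    runs <- find_homopolymers(seq, min_len)
    L <- nchar(seq)
    if (!nrow(runs)) {
      aligns[[i]] <- new_alignment(sprintf("hp%06d", i), L, tid,
                                   "transcriptome", "+", 0L, L, 0L, L,
                                   cbind(op = OP_M, len = L), score = L)
      next
    }
    mu <- spec$hp_mean_slope * runs$length
    sd <- spec$hp_sd_slope * runs$length + spec$hp_sd_intercept
    new_len <- pmax(0L, as.integer(round(stats::rnorm(nrow(runs), mu, sd))))
    ops <- integer(0); lens <- integer(0)
    pos <- 0L
    for (j in seq_len(nrow(runs))) {
      s <- runs$start[j]; l <- runs$length[j]; k <- new_len[j]
      # split point inside the run; a deletion must stay within the run,
      # so it can start no later than offset k (k = 0 deletes the full run)
      split_off <- if (k < l) min(max(1L, l %/% 2L), k) else {
        min(l - 1L, max(1L, l %/% 2L))
      }
      pre <- s - pos + split_off
      ops <- c(ops, OP_M); lens <- c(lens, pre)
      if (k < l) {
        ops <- c(ops, OP_D); lens <- c(lens, l - k)
      } else if (k > l) {
        ops <- c(ops, OP_I); lens <- c(lens, k - l)
      }
      pos <- s + split_off + if (k < l) l - k else 0L
      obs_j <- data.frame(base = runs$base[j], ref_len = l, read_len = k,
                          stringsAsFactors = FALSE)
      obs[[i]] <- if (is.null(obs[[i]])) obs_j else rbind(obs[[i]], obs_j)
    }
    ops <- c(ops, OP_M); lens <- c(lens, L - pos)
    walk <- make_walk(ops, lens)
    aligns[[i]] <- new_alignment(sprintf("hp%06d", i), walk_query_len(walk),
                                 tid, "transcriptome", "+", 0L,
                                 walk_query_len(walk), 0L, L, walk,
                                 score = sum(walk[walk[, "op"] == OP_M, "len"]))
  }
  list(alignments = aligns,
       observations = do.call(rbind, obs[!vapply(obs, is.null, logical(1))]))
}
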