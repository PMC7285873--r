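# Stage two: read simulation with full per-read ground truth.
#
# Construction order for one sense read:
#   transcript (by expression) -> IR pattern -> IR-expanded template ->
#   anatomy (head, aligned slice, tail) -> template slice ->
#   homopolymer expansion/contraction (modified runs masked) ->
#   error layout over unmasked positions -> error application ->
#   random-base flanks -> optional reverse complement (antisense).
# Ground truth is stored in template/slice coordinates with an orientation
# flag, so the sense construction is the single source of coordinate truth.
#
# Reads are generated in fixed-size blocks whose RNG streams derive
# deterministically from the master seed and the block index; worker
# processes pick up whole blocks, so output is byte-identical for any
# worker count.

#' Select source transcripts by expression
#'
#' Categorical draw with probability TPM / 1e6 per transcript.
#'
#' @param expression an \code{expression_profile}.
#' @param n number of draws.
#' @return character vector of transcript ids.
#' @export
select_transcript <- function(expression, n = 1L) {
  if (!nrow(expression)) stopf("empty expression profile")
  keep <- expression$tpm > 0
  sample(expression$transcript_id[keep], n, replace = TRUE,
         prob = expression$tpm[keep])
}

# Insert forced-match runs for masked intervals into a layout sampled over
# the unmasked length.  `masked` is a sorted matrix of 0-based half-open
# intervals on the final (post-homopolymer) slice of total length `total`.
interleave_mask <- function(layout, masked, total) {
  if (!nrow(masked)) return(layout)
  mask_len <- masked[, "end"] - masked[, "start"]
  if (is.null(layout) || !nrow(layout)) {
    return(merge_walk(cbind(op = rep(1L, nrow(masked)),
                            len = as.integer(mask_len))))
  }
  # boundaries in unmasked coordinates: cumulative unmasked length before
  # each mask
  cs <- masked[, "start"] - c(0, cumsum(mask_len))[seq_len(nrow(masked))]
  op <- layout[, "op"]; len <- layout[, "len"]
  refc <- ifelse(op != 3L, len, 0L)
  cum <- cumsum(refc); pre <- cum - refc
  # split rows containing a boundary strictly inside
  pieces_op <- vector("list", length(op)); pieces_len <- pieces_op
  pieces_pre <- pieces_op
  for (j in seq_along(op)) {
    bs <- cs[cs > pre[j] & cs < cum[j]]
    if (!length(bs)) {
      pieces_op[[j]] <- op[j]; pieces_len[[j]] <- len[j]; pieces_pre[[j]] <- pre[j]
    } else {
      cuts <- c(pre[j], bs, cum[j])
      pl <- diff(cuts)
      pieces_op[[j]] <- rep(op[j], length(pl))
      pieces_len[[j]] <- pl
      pieces_pre[[j]] <- cuts[-length(cuts)]
    }
  }
  p_op <- unlist(pieces_op); p_len <- unlist(pieces_len)
  p_pre <- unlist(pieces_pre)
  key <- c(p_pre, cs - 0.25)
  ord <- order(key, c(seq_along(p_op), rep(0L, length(cs))))
  all_op <- c(p_op, rep(1L, length(cs)))[ord]
  all_len <- c(p_len, mask_len)[ord]
  merge_walk(cbind(op = all_op, len = as.integer(all_len)))
}

# Per-base uniform mutation layout for unaligned reads: each template base
# independently becomes an error with probability `rate`, split evenly
# among single-base mismatch, insertion (inserted before the base, which
# is kept) and deletion.
uniform_error_layout <- function(len, rate) {
  u <- stats::runif(len)
  # 0 = no error, 1 = mis, 2 = ins, 3 = del
  ty <- ifelse(u >= rate, 0L, pmin(2L, as.integer(u %/% (rate / 3))) + 1L)
  ty[u < rate & u >= 2 * rate / 3] <- 3L
  op1 <- c(1L, 2L, 3L, 4L)[ty + 1L]   # ins handled below, del direct
  # insertion keeps the template base: emit an I row then an M row
  is_ins <- ty == 2L
  reps <- 1L + is_ins
  out_op <- integer(sum(reps))
  pos <- cumsum(reps)
  out_op[pos] <- ifelse(is_ins, 1L, op1)
  out_op[pos - (reps - 1L)] <- ifelse(is_ins, 3L, op1)
  make_walk(out_op, rep(1L, length(out_op)))
}

template_for <- function(tid, pattern, transcriptome, genotype_cache,
                         annotation, genome) {
  if (!any(pattern)) {
    return(list(seq = transcriptome[[tid]],
                ir_records = data.frame(intron_index = integer(0),
                                        genomic_start = integer(0),
                                        genomic_end = integer(0),
                                        length = integer(0))))
  }
  key <- paste0(tid, "|", paste(as.integer(pattern), collapse = ""))
  hit <- genotype_cache[[key]]
  if (!is.null(hit)) return(hit)
  ann_ids <- attr(genotype_cache, "ann_ids")
  tx <- attr(genotype_cache, "annotation")[[match(tid, ann_ids)]]
  tmpl <- build_template(tx, genome, pattern)
  genotype_cache[[key]] <- tmpl
  tmpl
}

# Truth rows are accumulated as small per-read chunks of parallel vectors
# (read_id, event, read_pos, ref_pos, len_ref, len_read, bases) in a plain
# pre-allocated list, collected into one data.frame per block.
truth_collect <- function(chunks, n) {
  ch <- chunks[seq_len(n)]
  if (!n) return(empty_truth_df())
  fast_df(
    read_id = rep(vapply(ch, `[[`, character(1), 1L),
                  vapply(ch, function(x) length(x[[2]]), integer(1))),
    event = unlist(lapply(ch, `[[`, 2L), use.names = FALSE),
    read_pos = as.integer(unlist(lapply(ch, `[[`, 3L), use.names = FALSE)),
    ref_pos = as.integer(unlist(lapply(ch, `[[`, 4L), use.names = FALSE)),
    len_ref = as.integer(unlist(lapply(ch, `[[`, 5L), use.names = FALSE)),
    len_read = as.integer(unlist(lapply(ch, `[[`, 6L), use.names = FALSE)),
    bases = unlist(lapply(ch, `[[`, 7L), use.names = FALSE))
}

empty_truth_df <- function() {
  fast_df(read_id = character(0), event = character(0), read_pos = integer(0),
          ref_pos = integer(0), len_ref = integer(0), len_read = integer(0),
          bases = character(0))
}

simulate_block <- function(profile, transcriptome, genome, annotation,
                           global_idx, n_unaligned_total, block_seed, opts) {
  set.seed(block_seed)
  n_b <- length(global_idx)
  is_un <- global_idx <= n_unaligned_total
  ann_ids <- if (!is.null(annotation)) {
    vapply(annotation, `[[`, character(1), "transcript_id")
  }
  intron_counts <- if (!is.null(annotation)) {
    stats::setNames(vapply(annotation, function(t) nrow(t$introns), integer(1)),
                    ann_ids)
  }
  cache <- new.env(parent = emptyenv())
  attr(cache, "annotation") <- annotation
  attr(cache, "ann_ids") <- ann_ids
  seqs <- character(n_b); ids <- character(n_b)
  m_category <- character(n_b); m_tid <- character(n_b)
  m_strand <- character(n_b); m_tstart <- integer(n_b)
  m_alen <- integer(n_b); m_head <- integer(n_b); m_tail <- integer(n_b)
  tchunks <- vector("list", 5L * n_b + 8L); tn <- 0L

  ## -- unaligned reads ------------------------------------------------------
  un_local <- which(is_un)
  if (length(un_local)) {
    tids <- select_transcript(profile$expression, length(un_local))
    lens <- sample_unaligned_length(profile$length_model, length(un_local))
    for (k in seq_along(un_local)) {
      i <- un_local[k]
      tid <- tids[k]
      L <- nchar(transcriptome[[tid]])
      len <- min(lens[k], L)
      start <- if (L > len) sample.int(L - len + 1L, 1L) - 1L else 0L
      slice <- substring(transcriptome[[tid]], start + 1L, start + len)
      res <- NULL
      for (try in 1:10) {
        layout <- uniform_error_layout(len, profile$unaligned_error_rate)
        res <- apply_errors(slice, layout)
        if (nchar(res$seq) > 0L) break
      }
      if (nchar(res$seq) == 0L) {
        res <- list(seq = slice,
                    events = fast_df(type = character(0), read_pos = integer(0),
                                     ref_pos = integer(0), len_ref = integer(0),
                                     len_read = integer(0), bases = character(0)))
      }
      strand <- if (stats::runif(1) < profile$strand_ratio) "+" else "-"
      seq <- if (strand == "-") revcomp(res$seq) else res$seq
      id <- sprintf("%s!%s!%d!%d!0!0!%d!unaligned", tid, strand, start, len,
                    global_idx[i] - 1L)
      ids[i] <- id; seqs[i] <- seq
      ev <- res$events
      if (nrow(ev)) {
        tn <- tn + 1L
        tchunks[[tn]] <- list(id, ev$type, ev$read_pos, ev$ref_pos,
                              ev$len_ref, ev$len_read, ev$bases)
      }
      m_category[i] <- "unaligned"; m_tid[i] <- tid; m_strand[i] <- strand
      m_tstart[i] <- start; m_alen[i] <- len; m_head[i] <- 0L; m_tail[i] <- 0L
    }
  }

  ## -- aligned reads --------------------------------------------------------
  al_local <- which(!is_un)
  if (length(al_local)) {
    n_a <- length(al_local)
    tids <- select_transcript(profile$expression, n_a)
    use_ir <- opts$with_ir && !is.null(profile$ir_model) &&
      !is.null(annotation) && !is.null(genome)
    patterns <- vector("list", n_a)
    templates <- vector("list", n_a)
    for (k in seq_len(n_a)) {
      n_int <- if (use_ir && tids[k] %in% ann_ids) intron_counts[[tids[k]]] else 0L
      patterns[[k]] <- if (use_ir && n_int > 0L) {
        sample_ir_pattern(profile$ir_model, n_int)
      } else {
        logical(n_int)
      }
      templates[[k]] <- template_for(tids[k], patterns[[k]], transcriptome,
                                     cache, annotation, genome)
    }
    tmpl_lens <- vapply(templates, function(t) nchar(t$seq), integer(1))
    anat <- sample_read_anatomy(profile$length_model, tmpl_lens)
    if (opts$start_mode == "anchor3") {
      starts <- tmpl_lens - anat[, "aligned"]
    } else {
      starts <- vapply(seq_len(n_a), function(k) {
        room <- tmpl_lens[k] - anat[k, "aligned"]
        if (room > 0L) sample.int(room + 1L, 1L) - 1L else 0L
      }, integer(1))
    }
    slices <- substring(vapply(templates, `[[`, character(1), "seq"),
                        starts + 1L, starts + anat[, "aligned"])
    # homopolymer stage
    hp <- vector("list", n_a)
    mod_slices <- slices
    use_hp <- !opts$perfect && !is.null(profile$homopolymer_model)
    if (use_hp) {
      for (k in seq_len(n_a)) {
        h <- apply_homopolymer_effects(slices[k], profile$homopolymer_model)
        hp[[k]] <- h
        mod_slices[k] <- h$seq
      }
    }
    masked_len <- vapply(seq_len(n_a), function(k) {
      if (is.null(hp[[k]])) 0L else {
        as.integer(sum(hp[[k]]$masked[, "end"] - hp[[k]]$masked[, "start"]))
      }
    }, integer(1))
    unmasked <- nchar(mod_slices) - masked_len
    # error layouts over unmasked positions
    layouts <- vector("list", n_a)
    if (!opts$perfect) {
      need <- which(unmasked >= 1L)
      if (length(need)) {
        sampled <- sample_error_layouts(profile$error_model, unmasked[need])
        layouts[need] <- sampled
      }
    }
    strands <- ifelse(stats::runif(n_a) < profile$strand_ratio, "+", "-")
    flank_seqs_h <- random_dna(anat[, "head"])
    flank_seqs_t <- random_dna(anat[, "tail"])
    for (k in seq_len(n_a)) {
      i <- al_local[k]
      h <- hp[[k]]
      masked <- if (is.null(h)) {
        matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
      } else h$masked
      tmpl <- templates[[k]]
      head_len <- anat[k, "head"]; tail_len <- anat[k, "tail"]
      id <- sprintf("%s!%s!%d!%d!%d!%d!%d!aligned", tids[k], strands[k],
                    starts[k], anat[k, "aligned"], head_len, tail_len,
                    global_idx[i] - 1L)
      if (nrow(tmpl$ir_records)) {
        nr <- nrow(tmpl$ir_records)
        tn <- tn + 1L
        tchunks[[tn]] <- list(id, rep("ir", nr), rep(NA_integer_, nr),
                              tmpl$ir_records$intron_index,
                              tmpl$ir_records$length, rep(NA_integer_, nr),
                              rep("", nr))
      }
      if (!is.null(h) && nrow(h$records)) {
        tn <- tn + 1L
        tchunks[[tn]] <- list(id, rep("homopolymer", nrow(h$records)),
                              h$records$new_start, h$records$ref_start,
                              h$records$len_ref, h$records$len_read,
                              h$records$base)
      }
      if (opts$perfect || (is.null(layouts[[k]]) && nrow(masked) == 0L)) {
        core <- mod_slices[k]
      } else {
        full_layout <- interleave_mask(layouts[[k]], masked, nchar(mod_slices[k]))
        res <- apply_errors(mod_slices[k], full_layout)
        core <- res$seq
        ev <- res$events
        if (nrow(ev)) {
          tn <- tn + 1L
          tchunks[[tn]] <- list(id, ev$type, ev$read_pos, ev$ref_pos,
                                ev$len_ref, ev$len_read, ev$bases)
        }
      }
      if (head_len > 0L) {
        tn <- tn + 1L
        tchunks[[tn]] <- list(id, "head", 0L, NA_integer_, 0L, head_len,
                              flank_seqs_h[k])
      }
      if (tail_len > 0L) {
        tn <- tn + 1L
        tchunks[[tn]] <- list(id, "tail", head_len + nchar(core), NA_integer_,
                              0L, tail_len, flank_seqs_t[k])
      }
      sense_read <- paste0(flank_seqs_h[k], core, flank_seqs_t[k])
      seq <- if (strands[k] == "-") revcomp(sense_read) else sense_read
      ids[i] <- id; seqs[i] <- seq
      m_category[i] <- "aligned"; m_tid[i] <- tids[k]; m_strand[i] <- strands[k]
      m_tstart[i] <- starts[k]; m_alen[i] <- anat[k, "aligned"]
      m_head[i] <- head_len; m_tail[i] <- tail_len
    }
  }
  meta <- fast_df(read_id = ids, category = m_category, transcript_id = m_tid,
                  strand = m_strand, tstart = m_tstart, aligned_len = m_alen,
                  head_len = m_head, tail_len = m_tail)
  list(ids = ids, seqs = seqs, meta = meta, truth = truth_collect(tchunks, tn))
}

#' Simulate nanopore RNA-seq reads
#'
#' @param profile a \code{nanotx_profile} from \code{\link{characterize}}
#'   or \code{\link{load_profile}}.
#' @param transcriptome named character vector of transcript sequences.
#' @param n_reads number of reads to generate; a fraction
#'   \code{profile$unaligned_fraction} of them (rounded) are unaligned
#'   reads mutated at \code{profile$unaligned_error_rate}.
#' @param genome,annotation required only when IR simulation is active.
#' @param seed master seed; every source of randomness derives from it.
#' @param n_workers worker processes; output is byte-identical for any
#'   worker count with the same seed.
#' @param perfect skip homopolymer and error mutation entirely.
#' @param with_ir simulate intron retention (needs an IR model, genome and
#'   annotation).
#' @param start_mode where the aligned slice sits on the template:
#'   \code{"anchor3"} (3' end, direct-RNA library behaviour; default) or
#'   \code{"uniform"}.
#' @param block_size reads per deterministic RNG block.
#' @return object of class \code{simulated_reads}: list with \code{reads}
#'   (data.frame: \code{read_id}, \code{sequence}, \code{category},
#'   \code{transcript_id}, \code{strand}, \code{tstart},
#'   \code{aligned_len}, \code{head_len}, \code{tail_len}) and
#'   \code{truth} (one row per introduced event).
#' @export
simulate_reads <- function(profile, transcriptome, n_reads,
                           genome = NULL, annotation = NULL, seed = 1L,
                           n_workers = 1L, perfect = FALSE,
                           with_ir = !is.null(profile$ir_model),
                           start_mode = c("anchor3", "uniform"),
                           block_size = 2500L) {
  stopifnot(inherits(profile, "nanotx_profile"))
  start_mode <- match.arg(start_mode)
  if (!is_count(n_reads) || n_reads <= 0) stopf("n_reads must be a positive integer")
  n_reads <- as.integer(n_reads)
  n_un <- if (is.null(profile$length_model$unaligned_kde)) 0L else {
    as.integer(round(n_reads * profile$unaligned_fraction))
  }
  opts <- list(perfect = perfect, with_ir = with_ir, start_mode = start_mode)
  blocks <- split(seq_len(n_reads),
                  (seq_len(n_reads) - 1L) %/% as.integer(block_size))
  run_one <- function(b) {
    simulate_block(profile, transcriptome, genome, annotation,
                   global_idx = blocks[[b]], n_unaligned_total = n_un,
                   block_seed = derive_seed(seed, b), opts = opts)
  }
  results <- if (n_workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_along(blocks), run_one,
                       mc.cores = as.integer(n_workers))
  } else {
    lapply(seq_along(blocks), run_one)
  }
  reads <- do.call(rbind, lapply(results, `[[`, "meta"))
  reads$sequence <- unlist(lapply(results, `[[`, "seqs"))
  reads <- reads[, c("read_id", "sequence", "category", "transcript_id",
                     "strand", "tstart", "aligned_len", "head_len", "tail_len")]
  truth <- do.call(rbind, lapply(results, `[[`, "truth"))
  rownames(reads) <- NULL; rownames(truth) <- NULL
  structure(list(reads = reads, truth = truth, n_reads = n_reads,
                 seed = seed),
            class = "simulated_reads")
}

#' @export
print.simulated_reads <- function(x, ...) {
  cat(sprintf("%d simulated reads (%d aligned, %d unaligned), %d truth events\n",
              x$n_reads, sum(x$reads$category == "aligned"),
              sum(x$reads$category == "unaligned"), nrow(x$truth)))
  invisible(x)
}

#' Simulate reads from a fitted profile
#'
#' S3 \code{simulate} method; thin wrapper over
#' \code{\link{simulate_reads}} with \code{nsim} reads.
#'
#' @param object a \code{nanotx_profile}.
#' @param nsim number of reads.
#' @param seed master seed.
#' @param ... further arguments to \code{\link{simulate_reads}}
#'   (\code{transcriptome} is required).
#' @return a \code{simulated_reads} object.
#' @importFrom stats simulate
#' @export
simulate.nanotx_profile <- function(object, nsim = 1, seed = 1L, ...) {
  simulate_reads(object, n_reads = nsim, seed = seed, ...)
}

#' Write simulated reads and their ground truth
#'
#' The read id encodes provenance as
#' \code{<transcript>!<strand>!<tstart>!<aligned_len>!<head>!<tail>!<serial>!<aligned|unaligned>};
#' the truth TSV carries one row per introduced event (errors, homopolymer
#' changes, retained introns, flanks) with coordinates and bases
#' sufficient for byte-exact reconstruction.
#'
#' @param sim a \code{simulated_reads} object.
#' @param fasta_path output FASTA.
#' @param truth_path output TSV.
#' @export
write_simulated_reads <- function(sim, fasta_path, truth_path) {
  if (anyDuplicated(sim$reads$read_id)) stopf("read id collision")
  seqs <- sim$reads$sequence
  names(seqs) <- sim$reads$read_id
  write_fasta(seqs, fasta_path)
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fasta = fasta_path, truth = truth_path))
}

#' Parse a simulated read id
#'
#' @param read_id id string produced by the simulator.
#' @return data.frame with the decoded fields.
#' @export
parse_read_id <- function(read_id) {
  parts <- strsplit(read_id, "!", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 8L
  if (any(bad)) stopf("malformed read id: %s", read_id[bad][1])
  m <- do.call(rbind, parts)
  data.frame(read_id = read_id, transcript_id = m[, 1], strand = m[, 2],
             tstart = as.integer(m[, 3]), aligned_len = as.integer(m[, 4]),
             head_len = as.integer(m[, 5]), tail_len = as.integer(m[, 6]),
             serial = as.integer(m[, 7]), category = m[, 8],
             stringsAsFactors = FALSE)
}

# Apply recorded error rows (post-homopolymer slice coordinates) to a
# sequence.  Events are applied in decreasing reference position; at equal
# positions insertions are applied last, so they land before the bases
# they precede in the read.
replay_error_rows <- function(s, ev) {
  if (!nrow(ev)) return(s)
  ord <- order(-ev$ref_pos, ev$event == "ins")
  ev <- ev[ord, , drop = FALSE]
  for (j in seq_len(nrow(ev))) {
    p <- ev$ref_pos[j]
    if (ev$event[j] == "mis") {
      s <- paste0(substr(s, 1, p), ev$bases[j],
                  substr(s, p + ev$len_ref[j] + 1L, nchar(s)))
    } else if (ev$event[j] == "del") {
      s <- paste0(substr(s, 1, p), substr(s, p + ev$len_ref[j] + 1L, nchar(s)))
    } else {  # ins
      s <- paste0(substr(s, 1, p), ev$bases[j], substr(s, p + 1L, nchar(s)))
    }
  }
  s
}

#' Reconstruct a simulated read from its ground truth
#'
#' Deterministically rebuilds the read sequence from the reference
#' interval encoded in the read id plus the truth rows; used to verify
#' ground-truth completeness.
#'
#' @param read_id simulated read id.
#' @param truth truth data.frame (rows for this read are selected by id).
#' @param transcriptome named character vector of transcript sequences.
#' @param genome,annotation needed only for reads with retained introns.
#' @return the reconstructed read sequence.
#' @export
replay_read <- function(read_id, truth, transcriptome, genome = NULL,
                        annotation = NULL) {
  rows <- truth[truth$read_id == read_id, , drop = FALSE]
  replay_read_rows(read_id, rows, transcriptome, genome, annotation)
}

#' Verify ground-truth completeness of a simulation
#'
#' Replays every read's truth rows and compares against the emitted
#' sequence.
#'
#' @param sim a \code{simulated_reads} object.
#' @param transcriptome,genome,annotation references used for simulation.
#' @return number of mismatching reads (0 on success), invisibly; truth
#'   failures raise detailed messages via attributes.
#' @export
verify_truth <- function(sim, transcriptome, genome = NULL, annotation = NULL) {
  truth_split <- split(seq_len(nrow(sim$truth)), sim$truth$read_id)
  bad <- character(0)
  for (i in seq_len(nrow(sim$reads))) {
    id <- sim$reads$read_id[i]
    idx <- truth_split[[id]]
    rows <- if (is.null(idx)) sim$truth[0, , drop = FALSE] else {
      sim$truth[idx, , drop = FALSE]
    }
    rec <- replay_read_rows(id, rows, transcriptome, genome, annotation)
    if (!identical(rec, sim$reads$sequence[i])) bad <- c(bad, id)
  }
  if (length(bad)) attr(bad, "n") <- length(bad)
  invisible(bad)
}

# Core of replay: `rows` are the truth rows of this read only.
replay_read_rows <- function(read_id, rows, transcriptome, genome = NULL,
                             annotation = NULL) {
  info <- parse_read_id(read_id)
  ir <- rows[rows$event == "ir", , drop = FALSE]
  if (nrow(ir)) {
    ann_ids <- vapply(annotation, `[[`, character(1), "transcript_id")
    tx <- annotation[[match(info$transcript_id, ann_ids)]]
    pattern <- logical(nrow(tx$introns))
    pattern[ir$ref_pos] <- TRUE
    template <- build_template(tx, genome, pattern)$seq
  } else {
    template <- transcriptome[[info$transcript_id]]
  }
  s <- substring(template, info$tstart + 1L, info$tstart + info$aligned_len)
  hp <- rows[rows$event == "homopolymer", , drop = FALSE]
  if (nrow(hp)) {
    hp <- hp[order(-hp$ref_pos), , drop = FALSE]
    for (j in seq_len(nrow(hp))) {
      s <- paste0(substr(s, 1, hp$ref_pos[j]),
                  strrep(hp$bases[j], hp$len_read[j]),
                  substr(s, hp$ref_pos[j] + hp$len_ref[j] + 1L, nchar(s)))
    }
  }
  s <- replay_error_rows(s, rows[rows$event %in% ERR_TYPES, , drop = FALSE])
  head_row <- rows[rows$event == "head", , drop = FALSE]
  tail_row <- rows[rows$event == "tail", , drop = FALSE]
  s <- paste0(if (nrow(head_row)) head_row$bases else "", s,
              if (nrow(tail_row)) tail_row$bases else "")
  if (info$strand == "-") s <- revcomp(s)
  s
}

#' Convert simulated ground truth into exact alignment records
#'
#' For reads simulated without intron retention and homopolymer stages,
#' the truth rows determine the read's alignment to its source transcript
#' exactly; this builds those alignment records so a simulation can be
#' re-characterized without running an aligner.  Unaligned-category reads
#' are skipped (their lengths are returned separately).
#'
#' @param sim a \code{simulated_reads} object whose truth contains no
#'   \code{ir} or \code{homopolymer} rows.
#' @return list with \code{alignments} (one exact record per aligned read)
#'   and \code{unaligned_lengths}.
#' @export
truth_to_alignments <- function(sim) {
  if (any(sim$truth$event %in% c("ir", "homopolymer"))) {
    stopf("truth contains ir/homopolymer rows; exact transcript-space walks are only defined for error-only simulations")
  }
  err <- sim$truth[sim$truth$event %in% ERR_TYPES, , drop = FALSE]
  by_read <- split(seq_len(nrow(err)), err$read_id)
  reads <- sim$reads
  out <- vector("list", nrow(reads))
  n_out <- 0L
  for (i in seq_len(nrow(reads))) {
    if (reads$category[i] != "aligned") next
    idx <- by_read[[reads$read_id[i]]]
    A <- reads$aligned_len[i]
    if (is.null(idx)) {
      walk <- cbind(op = OP_M, len = A)
    } else {
      ev <- err[idx, , drop = FALSE]
      # layout order: ascending ref position, insertions first at ties
      o <- order(ev$ref_pos, ev$event != "ins")
      ev <- ev[o, , drop = FALSE]
      op_code <- c(mis = OP_X, ins = OP_I, del = OP_D)[ev$event]
      consumes <- ev$event != "ins"
      n_ev <- nrow(ev)
      ops <- integer(2L * n_ev + 1L); lens <- integer(2L * n_ev + 1L)
      cur <- 0L; j <- 0L
      for (e in seq_len(n_ev)) {
        gap <- ev$ref_pos[e] - cur
        if (gap > 0L) { j <- j + 1L; ops[j] <- OP_M; lens[j] <- gap }
        j <- j + 1L; ops[j] <- op_code[e]
        lens[j] <- max(ev$len_ref[e], ev$len_read[e])
        cur <- ev$ref_pos[e] + ev$len_ref[e]
      }
      if (A - cur > 0L) { j <- j + 1L; ops[j] <- OP_M; lens[j] <- A - cur }
      walk <- make_walk(ops[seq_len(j)], lens[seq_len(j)])
    }
    qlen_core <- walk_query_len(walk)
    n_out <- n_out + 1L
    out[[n_out]] <- new_alignment(
      query_id = reads$read_id[i],
      query_length = reads$head_len[i] + qlen_core + reads$tail_len[i],
      target_id = reads$transcript_id[i], target_kind = "transcriptome",
      strand = reads$strand[i],
      query_start = reads$head_len[i],
      query_end = reads$head_len[i] + qlen_core,
      target_start = reads$tstart[i], target_end = reads$tstart[i] + A,
      walk = walk,
      score = sum(walk[walk[, "op"] == OP_M, "len"]))
  }
  un <- reads$category == "unaligned"
  list(alignments = out[seq_len(n_out)],
       unaligned_lengths = nchar(reads$sequence[un]))
}
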