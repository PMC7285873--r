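# Intron retention (IR): detection from genomic alignments, a first-order
# Markov chain over per-intron states {spliced, retained}, and template
# expansion at simulation time.
#
# A retained intron physically lengthens the sequenced molecule, so
# simulation expands the transcript template with the retained introns'
# genomic sequence *before* the read-length model is applied.

#' Detect intron retention events
#'
#' A read's transcript is assigned by its best primary transcriptome
#' alignment; its genomic alignment is then inspected over each of that
#' transcript's introns.  An intron is called retained when the genomic
#' alignment covers at least \code{min_coverage} of the intron span with
#' aligned (M/X) blocks and no splice (N) operation traverses it; an intron
#' traversed by an N gap within the read's span is spliced; introns outside
#' the read's genomic span are uncovered (\code{NA}).
#'
#' @param genome_alignments list of primary genome alignment records.
#' @param transcriptome_alignments list of primary transcriptome alignment
#'   records (assigns each read to a transcript).
#' @param annotation a \code{tx_annotation}.
#' @param min_coverage minimum aligned-block coverage of an intron span for
#'   a retained call (default 0.9).
#' @return object of class \code{ir_observations}: list with
#'   \code{observations} (per read: \code{read_id}, \code{transcript_id},
#'   \code{states} logical vector with NA = uncovered) and \code{report}
#'   (per-transcript data.frame: \code{transcript_id}, \code{intron_index},
#'   genomic interval, \code{reads_covering}, \code{reads_retaining},
#'   \code{frequency}).
#' @export
detect_ir <- function(genome_alignments, transcriptome_alignments, annotation,
                      min_coverage = 0.9) {
  tx_of <- list()
  for (a in transcriptome_alignments) {
    if (isTRUE(a$is_primary) && is.null(tx_of[[a$query_id]])) {
      tx_of[[a$query_id]] <- a$target_id
    }
  }
  ann_ids <- vapply(annotation, `[[`, character(1), "transcript_id")
  obs <- list()
  missing_tx <- character(0)
  for (g in genome_alignments) {
    if (!isTRUE(g$is_primary)) next
    tid <- tx_of[[g$query_id]]
    if (is.null(tid)) next
    k <- match(tid, ann_ids)
    if (is.na(k)) { missing_tx <- c(missing_tx, tid); next }
    tx <- annotation[[k]]
    n_int <- nrow(tx$introns)
    if (n_int == 0L) next
    if (tx$chrom != g$target_id) next
    blocks <- walk_ref_blocks(g)
    states <- rep(NA, n_int)
    for (i in seq_len(n_int)) {
      s <- tx$introns[i, "start"]; e <- tx$introns[i, "end"]
      if (s < g$target_start || e > g$target_end) next  # uncovered
      gaps <- blocks$gaps
      spanned <- nrow(gaps) > 0L &&
        any(gaps[, "start"] <= s & gaps[, "end"] >= e)
      if (spanned) { states[i] <- FALSE; next }
      al <- blocks$aligned
      ov <- pmin(al[, "end"], e) - pmax(al[, "start"], s)
      cov <- sum(ov[ov > 0]) / (e - s)
      states[i] <- cov >= min_coverage
    }
    obs[[length(obs) + 1L]] <- list(read_id = g$query_id, transcript_id = tid,
                                    states = states)
  }
  if (length(missing_tx)) {
    warnf("%d reads assigned to transcripts absent from the annotation; skipped",
          length(missing_tx))
  }
  report <- build_ir_report(obs, annotation, ann_ids)
  structure(list(observations = obs, report = report),
            class = "ir_observations")
}

build_ir_report <- function(obs, annotation, ann_ids) {
  if (!length(obs)) {
    return(data.frame(transcript_id = character(0), intron_index = integer(0),
                      chrom = character(0), start = integer(0), end = integer(0),
                      reads_covering = integer(0), reads_retaining = integer(0),
                      frequency = numeric(0)))
  }
  tids <- vapply(obs, `[[`, character(1), "transcript_id")
  rows <- lapply(unique(tids), function(tid) {
    tx <- annotation[[match(tid, ann_ids)]]
    st <- do.call(rbind, lapply(obs[tids == tid], `[[`, "states"))
    covering <- colSums(!is.na(st))
    retaining <- colSums(st, na.rm = TRUE)
    data.frame(transcript_id = tid, intron_index = seq_len(ncol(st)),
               chrom = tx$chrom, start = tx$introns[, "start"],
               end = tx$introns[, "end"], reads_covering = covering,
               reads_retaining = retaining,
               frequency = ifelse(covering > 0, retaining / covering, NA_real_),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.ir_observations <- function(x, ...) {
  n_ret <- length(unique(x$report$transcript_id[x$report$reads_retaining > 0]))
  cat(sprintf("IR observations: %d reads over %d transcripts; %d transcripts with >= 1 retained intron\n",
              length(x$observations),
              length(unique(x$report$transcript_id)), n_ret))
  invisible(x)
}

#' Fit the intron-retention Markov chain
#'
#' First-order chain over ordered intron states: \code{p_first} is the
#' retention frequency of the transcript's first intron; the two transition
#' probabilities condition on the previous intron's state.  Transitions are
#' counted over consecutive covered intron pairs only (uncovered introns
#' break the chain).  When a conditioning state has fewer than
#' \code{smooth_below} counts, add-one smoothing is applied to that row.
#'
#' @param observations an \code{ir_observations} object (or bare list of
#'   observations).
#' @param smooth_below count threshold under which add-one smoothing kicks
#'   in (default 5).
#' @return object of class \code{ir_model}: \code{p_first},
#'   \code{p_retain_given_spliced}, \code{p_retain_given_retained}, and the
#'   backing \code{counts}.
#' @export
fit_ir_model <- function(observations, smooth_below = 5L) {
  obs <- if (inherits(observations, "ir_observations")) {
    observations$observations
  } else {
    observations
  }
  if (!length(obs)) stopf("no IR observations")
  first <- c(0L, 0L)  # (covered, retained) for intron 1
  trans <- matrix(0L, 2, 2, dimnames = list(c("spliced", "retained"),
                                            c("spliced", "retained")))
  any_covered <- FALSE
  for (o in obs) {
    st <- o$states
    if (all(is.na(st))) next
    any_covered <- TRUE
    if (!is.na(st[1])) first <- first + c(1L, as.integer(st[1]))
    if (length(st) > 1L) {
      a <- st[-length(st)]; b <- st[-1L]
      ok <- !is.na(a) & !is.na(b)
      if (any(ok)) {
        for (k in which(ok)) {
          trans[a[k] + 1L, b[k] + 1L] <- trans[a[k] + 1L, b[k] + 1L] + 1L
        }
      }
    }
  }
  if (!any_covered) stopf("no covered introns in observations")
  est_row <- function(row) {
    unname(if (sum(row) < smooth_below) (row[2] + 1) / (sum(row) + 2)
           else row[2] / sum(row))
  }
  p_first <- if (first[1] == 0L) 0 else first[2] / first[1]
  model <- list(p_first = p_first,
                p_retain_given_spliced = est_row(trans[1, ]),
                p_retain_given_retained = est_row(trans[2, ]),
                counts = list(first = first, transitions = trans))
  class(model) <- "ir_model"
  model
}

#' @export
print.ir_model <- function(x, ...) {
  cat("Intron-retention Markov chain\n")
  cat(sprintf("  P(first intron retained)        = %.4f\n", x$p_first))
  cat(sprintf("  P(retained | previous spliced)  = %.4f\n",
              x$p_retain_given_spliced))
  cat(sprintf("  P(retained | previous retained) = %.4f\n",
              x$p_retain_given_retained))
  invisible(x)
}

#' Sample an intron-retention pattern
#'
#' @param model an \code{ir_model}.
#' @param n_introns number of introns (0 gives an empty pattern).
#' @return logical vector of retained states, 5' to 3'.
#' @export
sample_ir_pattern <- function(model, n_introns) {
  if (n_introns == 0L) return(logical(0))
  out <- logical(n_introns)
  out[1] <- stats::runif(1) < model$p_first
  if (n_introns > 1L) {
    for (i in 2:n_introns) {
      p <- if (out[i - 1]) model$p_retain_given_retained else model$p_retain_given_spliced
      out[i] <- stats::runif(1) < p
    }
  }
  out
}

# Forward marginal retention probabilities of the chain; independent
# oracle used in tests against empirical pattern frequencies.
ir_forward_marginals <- function(model, n_introns) {
  if (n_introns == 0L) return(numeric(0))
  p <- numeric(n_introns)
  p[1] <- model$p_first
  for (i in seq_len(n_introns - 1L)) {
    p[i + 1] <- p[i] * model$p_retain_given_retained +
      (1 - p[i]) * model$p_retain_given_spliced
  }
  p
}

#' Build an IR-expanded transcript template
#'
#' Splices the transcript's exons and inserts the genomic sequence of every
#' retained intron at its junction; minus-strand transcripts use the
#' reverse-complemented genomic sequence, so the template reads 5' to 3' in
#' transcript orientation.  An all-spliced pattern reproduces the spliced
#' transcript sequence exactly.
#'
#' @param tx a transcript entry of a \code{tx_annotation}.
#' @param genome named character vector of chromosome sequences.
#' @param pattern logical retention vector, one state per intron (5' to 3'
#'   transcript order).
#' @return list with \code{seq} (template) and \code{ir_records}
#'   (data.frame of retained introns: \code{intron_index},
#'   \code{genomic_start}, \code{genomic_end}, \code{length}).
#' @export
build_template <- function(tx, genome, pattern) {
  n_int <- nrow(tx$introns)
  if (length(pattern) != n_int) {
    stopf("pattern length %d != intron count %d for %s",
          length(pattern), n_int, tx$transcript_id)
  }
  if (!tx$chrom %in% names(genome)) {
    stopf("chromosome %s missing from genome", tx$chrom)
  }
  chrseq <- genome[[tx$chrom]]
  # genomic order of introns: pattern index i is the transcript's i-th
  # intron; on the minus strand that is the genomically (n-i+1)-th gap
  genomic_idx <- if (tx$strand == "-") rev(seq_len(n_int)) else seq_len(n_int)
  retained_genomic <- rep(FALSE, n_int)
  retained_genomic[genomic_idx[which(pattern)]] <- TRUE
  introns_genomic <- if (tx$strand == "-" && n_int > 1L) {
    tx$introns[rev(seq_len(n_int)), , drop = FALSE]
  } else {
    tx$introns
  }
  parts <- character(0)
  for (e in seq_len(nrow(tx$exons))) {
    parts <- c(parts, substring(chrseq, tx$exons[e, "start"] + 1L, tx$exons[e, "end"]))
    if (e < nrow(tx$exons) && retained_genomic[e]) {
      parts <- c(parts, substring(chrseq, introns_genomic[e, "start"] + 1L,
                                  introns_genomic[e, "end"]))
    }
  }
  s <- paste(parts, collapse = "")
  if (tx$strand == "-") s <- revcomp(s)
  ridx <- which(pattern)
  ir_records <- data.frame(
    intron_index = ridx,
    genomic_start = tx$introns[ridx, "start"],
    genomic_end = tx$introns[ridx, "end"],
    length = tx$introns[ridx, "end"] - tx$introns[ridx, "start"])
  list(seq = s, ir_records = ir_records)
}
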