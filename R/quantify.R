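# Transcript abundance estimation from multi-mapping long-read alignments.
#
# Long reads usually identify their source isoform, but reads from shared
# exons remain ambiguous.  Ambiguity is resolved RSEM-style: keep every
# alignment within a score fraction of the read's best, then apportion
# reads among compatible transcripts by expectation-maximization.  TPM is
# count-based: one read evidences one molecule, with no effective-length
# divisor (see the methods vignette).

#' Build the read-transcript compatibility matrix
#'
#' For each read, alignments scoring at least \code{min_score_frac} of the
#' read's best score are kept (PAF records use matching bases as the
#' score); compatible transcripts are deduplicated.
#'
#' @param alignments list of transcriptome alignment records, including
#'   secondaries.
#' @param min_score_frac score-fraction cutoff relative to the best
#'   alignment of the read (default 0.8).
#' @return object of class \code{compatibility_matrix}: list with
#'   \code{reads} (named list: read id -> character vector of transcript
#'   ids) and \code{n_unaligned} (always 0 here; unaligned reads never
#'   reach the alignment parser).
#' @export
build_compatibility <- function(alignments, min_score_frac = 0.8) {
  if (!length(alignments)) {
    return(structure(list(reads = list(), n_unaligned = 0L),
                     class = "compatibility_matrix"))
  }
  qid <- vapply(alignments, `[[`, character(1), "query_id")
  tid <- vapply(alignments, `[[`, character(1), "target_id")
  score <- vapply(alignments, function(a) {
    if (is.finite(a$score)) a$score else sum(a$walk[a$walk[, "op"] == OP_M, "len"])
  }, numeric(1))
  reads <- lapply(split(seq_along(alignments), qid), function(idx) {
    best <- max(score[idx])
    keep <- idx[score[idx] >= min_score_frac * best]
    unique(tid[keep])
  })
  structure(list(reads = reads, n_unaligned = 0L),
            class = "compatibility_matrix")
}

new_expression_profile <- function(transcript_id, est_count, tpm, total_reads) {
  p <- data.frame(transcript_id = transcript_id, est_count = est_count,
                  tpm = tpm, stringsAsFactors = FALSE)
  attr(p, "total_reads") <- total_reads
  class(p) <- c("expression_profile", "data.frame")
  p
}

#' Estimate transcript abundance by expectation-maximization
#'
#' Reads with identical compatibility sets are collapsed into equivalence
#' classes.  Abundances start uniform over observed transcripts; the
#' E-step distributes each read over its compatible transcripts in
#' proportion to current abundances, the M-step re-estimates abundances
#' from the expected counts.  Iteration stops when no abundance moves by
#' more than \code{tol}.  The procedure is deterministic, and the
#' observed-data log-likelihood is non-decreasing across iterations.
#'
#' @param matrix_ a \code{compatibility_matrix} (or bare list: read ->
#'   transcript ids).
#' @param max_iter iteration cap (default 100).
#' @param tol convergence threshold on the maximum absolute abundance
#'   change (default 1e-6).
#' @return an \code{expression_profile}: data.frame with
#'   \code{transcript_id}, \code{est_count} (expected reads) and
#'   \code{tpm} (sums to 1e6); attribute \code{loglik_trace} records the
#'   per-iteration log-likelihood.
#' @export
em_quantify <- function(matrix_, max_iter = 100L, tol = 1e-6) {
  reads <- if (inherits(matrix_, "compatibility_matrix")) matrix_$reads else matrix_
  reads <- Filter(length, reads)
  if (!length(reads)) stopf("empty compatibility matrix")
  # equivalence classes
  key <- vapply(reads, function(t) paste(sort(t), collapse = "\r"), character(1))
  cls <- split(seq_along(reads), key)
  cls_tx <- lapply(cls, function(idx) sort(reads[[idx[1]]]))
  cls_n <- vapply(cls, length, numeric(1))
  tx <- sort(unique(unlist(cls_tx)))
  K <- length(tx); N <- sum(cls_n)
  cls_ti <- lapply(cls_tx, match, tx)
  tau <- rep(1 / K, K)
  ll_trace <- numeric(0)
  # flattened class-transcript incidence for vectorized E-step
  flat_cls <- rep(seq_along(cls_ti), lengths(cls_ti))
  flat_ti <- unlist(cls_ti)
  for (it in seq_len(max_iter)) {
    denom_c <- rowsum(tau[flat_ti], flat_cls)[, 1]
    ll_trace <- c(ll_trace, sum(cls_n * log(denom_c)))
    z <- cls_n[flat_cls] * tau[flat_ti] / denom_c[flat_cls]
    counts <- numeric(K)
    agg <- rowsum(z, flat_ti)
    counts[as.integer(rownames(agg))] <- agg[, 1]
    tau_new <- counts / N
    delta <- max(abs(tau_new - tau))
    tau <- tau_new
    if (delta < tol) break
  }
  prof <- new_expression_profile(tx, est_count = tau * N, tpm = tau * 1e6,
                                 total_reads = N)
  attr(prof, "loglik_trace") <- ll_trace
  attr(prof, "iterations") <- length(ll_trace)
  prof
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("Expression profile: %d transcripts, %g assigned reads\n",
              nrow(x), attr(x, "total_reads")))
  top <- utils::head(x[order(-x$tpm), ], 5L)
  print.data.frame(top, row.names = FALSE)
  invisible(x)
}

#' Coefficient of determination between two expression profiles
#'
#' R-squared of the least-squares fit of profile \code{b}'s abundance on
#' profile \code{a}'s, computed on log10(TPM + 1) over transcripts where
#' either profile is non-zero (a transcript missing from one profile
#' counts as 0 TPM).
#'
#' @param a,b \code{expression_profile} objects (or data.frames with
#'   \code{transcript_id} and \code{tpm}).
#' @return R-squared in [0, 1].
#' @export
expression_r2 <- function(a, b) {
  universe <- union(a$transcript_id, b$transcript_id)
  ta <- a$tpm[match(universe, a$transcript_id)]; ta[is.na(ta)] <- 0
  tb <- b$tpm[match(universe, b$transcript_id)]; tb[is.na(tb)] <- 0
  keep <- ta > 0 | tb > 0
  if (sum(keep) < 3L) stopf("fewer than 3 shared transcripts")
  la <- log10(ta[keep] + 1); lb <- log10(tb[keep] + 1)
  summary(stats::lm(lb ~ la))$r.squared
}

#' Load a user-supplied expression profile
#'
#' @param path tab-delimited file with a header and columns
#'   \code{transcript_id} and \code{tpm} (or \code{est_count}, which is
#'   renormalized to TPM).
#' @param reference_ids optional character vector of known transcript ids;
#'   unknown transcripts are dropped with a warning and the remainder
#'   renormalized.
#' @return an \code{expression_profile} with TPM summing to 1e6.
#' @export
load_user_expression <- function(path, reference_ids = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  if (!"transcript_id" %in% names(d)) {
    if ("target_id" %in% names(d)) d$transcript_id <- d$target_id
    else stopf("expression file %s lacks a transcript_id column", path)
  }
  val <- if ("tpm" %in% names(d)) d$tpm else if ("est_count" %in% names(d)) {
    d$est_count
  } else {
    stopf("expression file %s lacks a tpm or est_count column", path)
  }
  if (!nrow(d)) stopf("empty expression file: %s", path)
  if (any(val < 0)) stopf("negative abundance in %s", path)
  if (!is.null(reference_ids)) {
    known <- d$transcript_id %in% reference_ids
    if (!all(known)) {
      warnf("%d transcripts in %s absent from the reference; dropped",
            sum(!known), path)
      d <- d[known, , drop = FALSE]; val <- val[known]
    }
  }
  if (!nrow(d) || sum(val) == 0) stopf("no usable expression rows in %s", path)
  tpm <- val / sum(val) * 1e6
  new_expression_profile(d$transcript_id, est_count = rep(NA_real_, nrow(d)),
                         tpm = tpm, total_reads = NA_real_)
}
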