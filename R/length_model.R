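# Read-length model: joint KDE of (log10 transcript length, aligned ratio),
# flank (head/tail) KDE, unaligned-read length KDE, and the strand ratio.
#
# ONT transcriptome reads are frequently truncated relative to their source
# molecule, and the degree of truncation depends on the molecule's length.
# The model therefore works on the *aligned ratio* (aligned span / source
# transcript length, in (0,1]) conditioned on log10 transcript length,
# rather than on absolute read length.

#' Fit the read-length and flank model
#'
#' @param alignments list of primary transcriptome alignment records (one
#'   best alignment per aligned read).
#' @param transcript_lengths named integer vector: spliced length of every
#'   aligned target transcript.
#' @param unaligned_lengths integer vector of read lengths for reads that
#'   produced no alignment (may be empty).
#' @return object of class \code{length_model} with components
#'   \code{joint_kde} (2D KDE over log10 transcript length and aligned
#'   ratio), \code{flank_kde} (2D KDE over log1p head/tail lengths),
#'   \code{unaligned_kde} (1D KDE over log10 unaligned read lengths, or
#'   \code{NULL}) and \code{n_training}.
#' @export
fit_length_model <- function(alignments, transcript_lengths,
                             unaligned_lengths = integer(0)) {
  alignments <- Filter(function(a) isTRUE(a$is_primary), alignments)
  n <- length(alignments)
  if (n < 30L) stopf("refusing to fit a length model on %d aligned reads (need >= 30)", n)
  tid <- vapply(alignments, `[[`, character(1), "target_id")
  tl <- transcript_lengths[tid]
  if (anyNA(tl)) stopf("missing transcript length for %s", tid[which(is.na(tl))[1]])
  if (any(tl <= 0)) stopf("transcript of length 0 in training set")
  span <- vapply(alignments, function(a) a$target_end - a$target_start, numeric(1))
  ratio <- span / tl
  if (any(ratio > 1)) {
    warnf("%d training reads have aligned ratio > 1 (alignment artefacts); clipping to 1",
          sum(ratio > 1))
    ratio <- pmin(ratio, 1)
  }
  head_len <- vapply(alignments, function(a) a$query_start, numeric(1))
  tail_len <- vapply(alignments, function(a) a$query_length - a$query_end, numeric(1))
  model <- list(
    joint_kde = fit_kde2d(unname(log10(tl)), unname(ratio)),
    flank_kde = fit_kde2d(log1p(head_len), log1p(tail_len)),
    unaligned_kde = if (length(unaligned_lengths)) {
      fit_kde1d(unaligned_lengths, scale = "log10")
    },
    n_training = n)
  class(model) <- "length_model"
  model
}

#' @export
print.length_model <- function(x, ...) {
  cat(sprintf("Read-length model: %d training reads\n", x$n_training))
  cat(sprintf("  aligned ratio: mean %.3f (KDE bandwidths %.4f / %.4f)\n",
              mean(x$joint_kde$y), x$joint_kde$bw_x, x$joint_kde$bw_y))
  cat(sprintf("  flanks: mean head %.1f nt, mean tail %.1f nt\n",
              mean(expm1(x$flank_kde$x)), mean(expm1(x$flank_kde$y))))
  if (!is.null(x$unaligned_kde)) {
    cat(sprintf("  unaligned-read lengths: %d training reads\n",
                x$unaligned_kde$n))
  }
  invisible(x)
}

# Vectorized ratio draw conditional on transcript (template) lengths,
# with rejection into (0,1].  Falls back to empirical resampling of the
# training ratios after 1000 fruitless rounds.
sample_aligned_ratio <- function(model, template_lens) {
  n <- length(template_lens)
  out <- rep(NA_real_, n)
  lx <- log10(template_lens)
  todo <- seq_len(n)
  for (round in 1:1000) {
    r <- sample_kde2d_conditional(model$joint_kde, lx[todo])
    ok <- r > 0 & r <= 1 & round(r * template_lens[todo]) >= 1
    out[todo[ok]] <- r[ok]
    todo <- todo[!ok]
    if (!length(todo)) break
  }
  if (length(todo)) {
    warnf("ratio sampling fell back to empirical resampling for %d reads", length(todo))
    pool <- model$joint_kde$y[model$joint_kde$y > 0 & model$joint_kde$y <= 1]
    out[todo] <- sample(pool, length(todo), replace = TRUE)
  }
  out
}

#' Sample the anatomy of a simulated read
#'
#' Draws (head flank, aligned length, tail flank) for a read of a source
#' molecule of length \code{transcript_length}: the aligned ratio comes
#' from the joint KDE conditioned on log10 length, the flanks jointly from
#' the flank KDE.
#'
#' @param model a \code{length_model}.
#' @param transcript_length length (nt) of the source molecule (after any
#'   intron-retention expansion); may be a vector.
#' @return integer matrix with columns \code{head}, \code{aligned},
#'   \code{tail}, one row per element of \code{transcript_length}.
#' @export
sample_read_anatomy <- function(model, transcript_length) {
  stopifnot(all(transcript_length >= 1))
  n <- length(transcript_length)
  ratio <- sample_aligned_ratio(model, transcript_length)
  aligned <- pmax(1L, as.integer(round(ratio * transcript_length)))
  aligned <- pmin(aligned, as.integer(transcript_length))
  fl <- sample_kde2d(model$flank_kde, n)
  head <- pmax(0L, as.integer(round(expm1(fl[, 1]))))
  tail <- pmax(0L, as.integer(round(expm1(fl[, 2]))))
  cbind(head = head, aligned = aligned, tail = tail)
}

# Sample unaligned-read lengths (integer, >= 1).
sample_unaligned_length <- function(model, n) {
  if (is.null(model$unaligned_kde)) stopf("model has no unaligned-read KDE")
  pmax(1L, as.integer(round(sample_kde1d(model$unaligned_kde, n))))
}

#' Infer the sense/antisense strand ratio
#'
#' The strand ratio is the fraction of training reads aligned in the
#' annotated sense direction of their transcript (transcriptome targets
#' define sense as \code{+}).
#'
#' @param alignments list of primary transcriptome alignment records.
#' @return object of class \code{strand_stats}: list with
#'   \code{strand_ratio} and \code{n}.
#' @export
infer_strand_stats <- function(alignments) {
  alignments <- Filter(function(a) isTRUE(a$is_primary), alignments)
  n <- length(alignments)
  if (n == 0L) stopf("no primary alignments; cannot infer strand ratio")
  plus <- sum(vapply(alignments, function(a) a$strand == "+", logical(1)))
  structure(list(strand_ratio = plus / n, n = n), class = "strand_stats")
}

#' @export
print.strand_stats <- function(x, ...) {
  cat(sprintf("Strand ratio: %.4f sense (n = %d)\n", x$strand_ratio, x$n))
  invisible(x)
}
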