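# Stage one: learn all models from alignments of training reads.

#' Characterize nanopore RNA-seq reads
#'
#' Fits every component model from alignments of training reads and
#' returns the complete profile used by \code{\link{simulate_reads}}:
#' read-length and flank KDEs, strand ratio, base-call error model,
#' transcript expression (by EM over multi-mapping alignments), and --
#' when genome alignments and an annotation are supplied -- the intron
#' retention chain; when reference sequences are supplied, the
#' homopolymer length model.
#'
#' @param transcriptome_alignments list of transcriptome alignment records
#'   (primaries and secondaries; secondaries feed expression estimation).
#' @param transcript_lengths named integer vector of spliced transcript
#'   lengths (defaults to the lengths of \code{transcriptome} if given).
#' @param transcriptome optional named character vector of transcript
#'   sequences; enables the homopolymer model.
#' @param genome_alignments optional list of genome alignment records
#'   (enables IR modelling together with \code{annotation}).
#' @param annotation optional \code{tx_annotation}.
#' @param unaligned_lengths integer vector of lengths of reads that did not
#'   align (may be empty).
#' @param hp_min_len minimum homopolymer run length modelled (default 5).
#' @param unaligned_error_rate base-level error rate applied to simulated
#'   unaligned reads (default 0.9).
#' @param min_score_frac secondary-alignment score cutoff for expression
#'   estimation (default 0.8).
#' @return object of class \code{nanotx_profile}.
#' @export
characterize <- function(transcriptome_alignments,
                         transcript_lengths = NULL,
                         transcriptome = NULL,
                         genome_alignments = NULL,
                         annotation = NULL,
                         unaligned_lengths = integer(0),
                         hp_min_len = 5L,
                         unaligned_error_rate = 0.9,
                         min_score_frac = 0.8) {
  if (is.null(transcript_lengths)) {
    if (is.null(transcriptome)) {
      stopf("provide transcript_lengths or transcriptome sequences")
    }
    transcript_lengths <- nchar(transcriptome)
  }
  primaries <- Filter(function(a) isTRUE(a$is_primary), transcriptome_alignments)
  strand <- infer_strand_stats(primaries)
  length_model <- fit_length_model(primaries, transcript_lengths,
                                   unaligned_lengths)
  events <- extract_error_events(primaries)
  error_model <- fit_error_model(events)
  expression <- em_quantify(build_compatibility(transcriptome_alignments,
                                                min_score_frac))
  attr(expression, "loglik_trace") <- NULL
  attr(expression, "iterations") <- NULL
  ir_model <- NULL
  if (!is.null(genome_alignments) && !is.null(annotation)) {
    obs <- detect_ir(genome_alignments, transcriptome_alignments, annotation)
    if (length(obs$observations)) ir_model <- fit_ir_model(obs)
  }
  hp_model <- NULL
  if (!is.null(transcriptome)) {
    hp_obs <- extract_homopolymer_observations(primaries, transcriptome,
                                               hp_min_len)
    if (nrow(hp_obs)) {
      hp_model <- suppressWarnings(fit_homopolymer_model(hp_obs, hp_min_len))
    }
  }
  n_aligned <- length(unique(vapply(primaries, `[[`, character(1), "query_id")))
  n_un <- length(unaligned_lengths)
  new_profile(
    length_model = length_model, error_model = error_model,
    ir_model = ir_model, homopolymer_model = hp_model,
    expression = expression, strand_ratio = strand$strand_ratio,
    unaligned_fraction = if (n_aligned + n_un > 0) n_un / (n_aligned + n_un) else 0,
    unaligned_error_rate = unaligned_error_rate,
    metadata = list(tool = "nanotxsim",
                    version = as.character(utils::packageVersion("nanotxsim")),
                    trained = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                    n_aligned_reads = n_aligned,
                    n_unaligned_reads = n_un))
}

#' @export
print.nanotx_profile <- function(x, ...) {
  cat("nanopore RNA-seq read profile\n")
  cat(sprintf("  strand ratio %.3f | unaligned fraction %.3f\n",
              x$strand_ratio, x$unaligned_fraction))
  print(x$length_model)
  print(x$error_model)
  if (!is.null(x$ir_model)) print(x$ir_model) else cat("  (no IR model)\n")
  if (!is.null(x$homopolymer_model)) print(x$homopolymer_model)
  else cat("  (no homopolymer model)\n")
  cat(sprintf("  expression: %d transcripts\n", nrow(x$expression)))
  invisible(x)
}

#' @export
summary.nanotx_profile <- function(object, ...) {
  x <- object
  s <- list(
    strand_ratio = x$strand_ratio,
    unaligned_fraction = x$unaligned_fraction,
    error_rates = x$error_model$rates,
    total_error_rate = sum(x$error_model$rates),
    mixture_means = vapply(x$error_model$mixtures, mixture_mean, numeric(1)),
    mean_aligned_ratio = mean(x$length_model$joint_kde$y),
    n_transcripts = nrow(x$expression),
    ir = if (!is.null(x$ir_model)) {
      c(p_first = x$ir_model$p_first,
        p_retain_given_spliced = x$ir_model$p_retain_given_spliced,
        p_retain_given_retained = x$ir_model$p_retain_given_retained)
    })
  class(s) <- "summary.nanotx_profile"
  s
}

#' @export
print.summary.nanotx_profile <- function(x, ...) {
  cat(sprintf("strand ratio        %.4f\n", x$strand_ratio))
  cat(sprintf("unaligned fraction  %.4f\n", x$unaligned_fraction))
  cat(sprintf("error rates         mis %.4f  ins %.4f  del %.4f  (total %.4f)\n",
              x$error_rates["mis"], x$error_rates["ins"], x$error_rates["del"],
              x$total_error_rate))
  cat(sprintf("mean aligned ratio  %.3f\n", x$mean_aligned_ratio))
  if (!is.null(x$ir)) {
    cat(sprintf("IR chain            first %.4f | ret|spl %.4f | ret|ret %.4f\n",
                x$ir["p_first"], x$ir["p_retain_given_spliced"],
                x$ir["p_retain_given_retained"]))
  }
  invisible(x)
}
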