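# On-disk model profile: human-readable JSON for scalars and coefficients,
# TSV for KDE training points, matrices and expression.  A saved profile
# round-trips losslessly (numbers at full precision) and is the unit that
# ships between the characterization and simulation stages.

PROFILE_VERSION <- "1"

fmt_num <- function(x) sprintf("%.17g", x)

write_tsv_full <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], fmt_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Save a characterization profile to a directory
#'
#' Writes \code{model.json}, \code{length_kde.tsv}, \code{unaligned.json},
#' \code{error_mixtures.json}, \code{error_markov.tsv},
#' \code{match_lengths.tsv}, \code{ir_markov.json} (if present),
#' \code{homopolymer.json} (if present) and \code{expression.tsv}.
#'
#' @param bundle a \code{nanotx_profile}.
#' @param directory output directory (created if needed).
#' @return the directory, invisibly.
#' @export
save_profile <- function(bundle, directory) {
  stopifnot(inherits(bundle, "nanotx_profile"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  lm <- bundle$length_model
  em <- bundle$error_model
  top <- list(
    profile_version = PROFILE_VERSION,
    metadata = bundle$metadata,
    strand_ratio = bundle$strand_ratio,
    unaligned_fraction = bundle$unaligned_fraction,
    unaligned_error_rate = bundle$unaligned_error_rate,
    length_model = list(
      n_training = lm$n_training,
      joint_bw = c(lm$joint_kde$bw_x, lm$joint_kde$bw_y),
      flank_bw = c(lm$flank_kde$bw_x, lm$flank_kde$bw_y)),
    match_kde_bw = em$match_kde$bw)
  jsonlite::write_json(top, file.path(directory, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_tsv_full(
    data.frame(kind = c(rep("joint", lm$joint_kde$n), rep("flank", lm$flank_kde$n)),
               x = c(lm$joint_kde$x, lm$flank_kde$x),
               y = c(lm$joint_kde$y, lm$flank_kde$y)),
    file.path(directory, "length_kde.tsv"))
  ua <- lm$unaligned_kde
  jsonlite::write_json(
    if (is.null(ua)) list(points = list()) else
      list(points = ua$points, bw = ua$bw, scale = ua$scale),
    file.path(directory, "unaligned.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(rates = as.list(em$rates), pi = as.list(em$pi),
         n_events = em$n_events, mixtures = em$mixtures),
    file.path(directory, "error_mixtures.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  mk <- as.data.frame(em$markov)
  mk <- cbind(from = rownames(em$markov), mk)
  write_tsv_full(mk, file.path(directory, "error_markov.tsv"))
  write_tsv_full(data.frame(log1p_len = em$match_kde$points),
                 file.path(directory, "match_lengths.tsv"))
  if (!is.null(bundle$ir_model)) {
    im <- bundle$ir_model
    jsonlite::write_json(
      list(p_first = im$p_first,
           p_retain_given_spliced = im$p_retain_given_spliced,
           p_retain_given_retained = im$p_retain_given_retained,
           counts = list(first = im$counts$first,
                         transitions = im$counts$transitions)),
      file.path(directory, "ir_markov.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  if (!is.null(bundle$homopolymer_model)) {
    hm <- bundle$homopolymer_model
    jsonlite::write_json(list(min_len = hm$min_len, per_base = hm$per_base),
                         file.path(directory, "homopolymer.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  expr <- data.frame(target_id = bundle$expression$transcript_id,
                     est_count = bundle$expression$est_count,
                     tpm = bundle$expression$tpm)
  write_tsv_full(expr, file.path(directory, "expression.tsv"))
  jsonlite::write_json(list(total_reads = attr(bundle$expression, "total_reads")),
                       file.path(directory, "expression_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(directory)
}

require_file <- function(directory, name) {
  p <- file.path(directory, name)
  if (!file.exists(p)) stopf("profile is missing mandatory file %s", name)
  p
}

check_fraction <- function(x, what) {
  if (!is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    stopf("corrupt profile: %s = %s is not a fraction in [0, 1]", what,
          format(x))
  }
  x
}

#' Load a characterization profile from a directory
#'
#' @param directory a directory written by \code{\link{save_profile}}.
#' @return a \code{nanotx_profile}; optional components (IR, homopolymer)
#'   absent on disk load as \code{NULL}.
#' @export
load_profile <- function(directory) {
  top <- jsonlite::read_json(require_file(directory, "model.json"),
                             simplifyVector = TRUE)
  if (!identical(as.character(top$profile_version), PROFILE_VERSION)) {
    warnf("profile version %s differs from supported version %s",
          top$profile_version, PROFILE_VERSION)
  }
  kde <- utils::read.delim(require_file(directory, "length_kde.tsv"))
  jo <- kde[kde$kind == "joint", ]
  fl <- kde[kde$kind == "flank", ]
  joint <- structure(list(x = jo$x, y = jo$y,
                          bw_x = top$length_model$joint_bw[1],
                          bw_y = top$length_model$joint_bw[2], n = nrow(jo)),
                     class = "nanotx_kde2d")
  flank <- structure(list(x = fl$x, y = fl$y,
                          bw_x = top$length_model$flank_bw[1],
                          bw_y = top$length_model$flank_bw[2], n = nrow(fl)),
                     class = "nanotx_kde2d")
  ua <- jsonlite::read_json(require_file(directory, "unaligned.json"),
                            simplifyVector = TRUE)
  unaligned <- if (length(ua$points)) {
    structure(list(points = ua$points, bw = ua$bw, scale = ua$scale,
                   n = length(ua$points)), class = "nanotx_kde1d")
  }
  length_model <- structure(
    list(joint_kde = joint, flank_kde = flank, unaligned_kde = unaligned,
         n_training = top$length_model$n_training), class = "length_model")

  emj <- jsonlite::read_json(require_file(directory, "error_mixtures.json"),
                             simplifyVector = TRUE)
  mk <- utils::read.delim(require_file(directory, "error_markov.tsv"))
  markov <- as.matrix(mk[, ERR_TYPES])
  rownames(markov) <- mk$from
  markov <- markov[ERR_TYPES, , drop = FALSE]
  ml <- utils::read.delim(require_file(directory, "match_lengths.tsv"))
  rates <- unlist(emj$rates)[ERR_TYPES]
  for (r in rates) check_fraction(r, "error rate")
  error_model <- structure(
    list(rates = rates,
         mixtures = lapply(emj$mixtures, function(m) m[!vapply(m, is.null, logical(1))]),
         match_kde = structure(list(points = ml$log1p_len, bw = top$match_kde_bw,
                                    scale = "log1p", n = nrow(ml)),
                               class = "nanotx_kde1d"),
         markov = markov, pi = unlist(emj$pi)[ERR_TYPES],
         n_events = emj$n_events), class = "error_model")

  ir_model <- NULL
  if (file.exists(file.path(directory, "ir_markov.json"))) {
    ij <- jsonlite::read_json(file.path(directory, "ir_markov.json"),
                              simplifyVector = TRUE)
    ir_model <- structure(
      list(p_first = check_fraction(ij$p_first, "p_first"),
           p_retain_given_spliced = check_fraction(ij$p_retain_given_spliced,
                                                   "p_retain_given_spliced"),
           p_retain_given_retained = check_fraction(ij$p_retain_given_retained,
                                                    "p_retain_given_retained"),
           counts = list(first = ij$counts$first,
                         transitions = matrix(as.integer(ij$counts$transitions),
                                              2, 2,
                                              dimnames = list(c("spliced", "retained"),
                                                              c("spliced", "retained"))))),
      class = "ir_model")
  }
  hp_model <- NULL
  if (file.exists(file.path(directory, "homopolymer.json"))) {
    hj <- jsonlite::read_json(file.path(directory, "homopolymer.json"),
                              simplifyVector = TRUE)
    hp_model <- structure(list(min_len = as.integer(hj$min_len),
                               per_base = hj$per_base),
                          class = "homopolymer_model")
  }
  expr <- utils::read.delim(require_file(directory, "expression.tsv"))
  emeta <- jsonlite::read_json(file.path(directory, "expression_meta.json"),
                               simplifyVector = TRUE)
  expression <- new_expression_profile(
    as.character(expr$target_id), expr$est_count, expr$tpm,
    total_reads = if (is.null(emeta$total_reads)) NA_real_ else emeta$total_reads)
  new_profile(
    length_model = length_model, error_model = error_model,
    ir_model = ir_model, homopolymer_model = hp_model,
    expression = expression,
    strand_ratio = check_fraction(top$strand_ratio, "strand_ratio"),
    unaligned_fraction = check_fraction(top$unaligned_fraction,
                                        "unaligned_fraction"),
    unaligned_error_rate = check_fraction(top$unaligned_error_rate,
                                          "unaligned_error_rate"),
    metadata = top$metadata)
}

new_profile <- function(length_model, error_model, expression,
                        ir_model = NULL, homopolymer_model = NULL,
                        strand_ratio = 1, unaligned_fraction = 0,
                        unaligned_error_rate = 0.9, metadata = list()) {
  check_fraction(strand_ratio, "strand_ratio")
  check_fraction(unaligned_fraction, "unaligned_fraction")
  check_fraction(unaligned_error_rate, "unaligned_error_rate")
  structure(list(length_model = length_model, error_model = error_model,
                 ir_model = ir_model, homopolymer_model = homopolymer_model,
                 expression = expression, strand_ratio = strand_ratio,
                 unaligned_fraction = unaligned_fraction,
                 unaligned_error_rate = unaligned_error_rate,
                 metadata = metadata),
            class = "nanotx_profile")
}
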