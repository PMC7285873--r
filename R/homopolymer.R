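# Homopolymer length model.
#
# ONT base callers mis-estimate the length of single-base runs (mostly
# contractions via deletions).  Per base, the read-run length given a
# reference-run length L is modelled as Normal(mean(L), sd(L)), where
# mean(L) is a continuous two-segment linear regression (breakpoint chosen
# by grid search over integer candidates) and sd(L) an ordinary linear
# regression of per-length standard deviations.  During simulation each
# reference run of length >= min_len is replaced by a run of the drawn
# length, and the modified interval is masked from generic error placement
# so that homopolymer deletions are not double-counted.

#' Find homopolymer runs in a sequence
#'
#' @param sequence DNA string.
#' @param min_len minimum run length reported (default 5).
#' @return data.frame with \code{base}, \code{start} (0-based) and
#'   \code{length}, for every maximal run of length >= \code{min_len},
#'   left to right.
#' @export
find_homopolymers <- function(sequence, min_len = 5L) {
  r <- rle(strsplit(sequence, "", fixed = TRUE)[[1]])
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= min_len & r$values %in% DNA_BASES
  fast_df(base = r$values[keep],
          start = (ends - r$lengths)[keep],
          length = r$lengths[keep])
}

#' Measure homopolymer lengths on reads
#'
#' For every reference run of length >= \code{min_len} lying fully inside
#' an alignment's target span, the read-side run length is the reference
#' length minus deleted bases within the run plus inserted bases strictly
#' inside the run (insertions in a homopolymer interior are taken to extend
#' the run; when the record carries the read sequence, only insertions of
#' the run's base are counted).  Runs truncated by an alignment boundary
#' are skipped.
#'
#' @param alignments list of alignment records with resolved walks.
#' @param reference_sequences named character vector of target sequences.
#' @param min_len minimum reference run length (default 5).
#' @return data.frame of observations: \code{base}, \code{ref_len},
#'   \code{read_len}.
#' @export
extract_homopolymer_observations <- function(alignments, reference_sequences,
                                             min_len = 5L) {
  runs_by_target <- list()
  out <- vector("list", length(alignments))
  for (k in seq_along(alignments)) {
    a <- alignments[[k]]
    if (!isTRUE(a$is_primary)) next
    runs <- runs_by_target[[a$target_id]]
    if (is.null(runs)) {
      seq <- reference_sequences[[a$target_id]]
      if (is.null(seq)) stopf("reference %s not provided", a$target_id)
      runs <- find_homopolymers(seq, min_len)
      runs_by_target[[a$target_id]] <- runs
    }
    if (!nrow(runs)) next
    inside <- runs$start >= a$target_start &
      (runs$start + runs$length) <= a$target_end
    if (!any(inside)) next
    w <- a$walk
    cons_ref <- ifelse(w[, "op"] %in% c(OP_M, OP_X, OP_D, OP_N), w[, "len"], 0L)
    ref_end <- a$target_start + cumsum(cons_ref)
    ref_start <- ref_end - cons_ref
    cons_read <- ifelse(w[, "op"] %in% c(OP_M, OP_X, OP_I), w[, "len"], 0L)
    read_end <- a$query_start + cumsum(cons_read)
    read_start <- read_end - cons_read
    obs <- lapply(which(inside), function(j) {
      s <- runs$start[j]; e <- s + runs$length[j]
      ov <- pmin(ref_end, e) - pmax(ref_start, s)
      # deletions overlapping the run
      del_in <- sum(ov[w[, "op"] == OP_D & ov > 0])
      # skipped (N) regions overlapping the run: run not sequenced; skip
      if (any(w[, "op"] == OP_N & ov > 0)) return(NULL)
      # insertions strictly inside the run interior
      ins_j <- which(w[, "op"] == OP_I & ref_start > s & ref_start < e)
      ins_in <- 0L
      for (i2 in ins_j) {
        bases <- if (!is.null(a$query_seq)) {
          substring(a$query_seq, read_start[i2] + 1L, read_end[i2])
        } else NULL
        ins_in <- ins_in + if (is.null(bases)) w[i2, "len"] else {
          sum(strsplit(bases, "")[[1]] == runs$base[j])
        }
      }
      data.frame(base = runs$base[j], ref_len = runs$length[j],
                 read_len = max(0L, runs$length[j] - del_in + ins_in),
                 stringsAsFactors = FALSE)
    })
    obs <- obs[!vapply(obs, is.null, logical(1))]
    if (length(obs)) out[[k]] <- do.call(rbind, obs)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(base = character(0), ref_len = integer(0),
                      read_len = integer(0)))
  }
  do.call(rbind, out)
}

# Continuous two-segment least squares: mean = b0 + b1*L + b2*max(L - bp, 0),
# breakpoint chosen by grid search over integer candidates minimizing SSE.
fit_segmented <- function(x, y) {
  ux <- sort(unique(x))
  if (length(ux) == 1L) {
    return(list(breakpoint = ux[1], intercept = mean(y), slope1 = 0, slope2 = 0))
  }
  if (length(ux) == 2L) {
    f <- stats::lm(y ~ x)
    return(list(breakpoint = ux[2], intercept = unname(stats::coef(f)[1]),
                slope1 = unname(stats::coef(f)[2]), slope2 = 0))
  }
  cand <- ux[ux > min(ux) & ux < max(ux)]
  best <- NULL
  for (bp in cand) {
    h <- pmax(x - bp, 0)
    f <- stats::lm(y ~ x + h)
    sse <- sum(stats::resid(f)^2)
    if (is.null(best) || sse < best$sse) {
      cf <- stats::coef(f)
      cf[is.na(cf)] <- 0
      best <- list(sse = sse, breakpoint = bp, intercept = unname(cf[1]),
                   slope1 = unname(cf[2]), slope2 = unname(cf[3]))
    }
  }
  best$sse <- NULL
  best
}

predict_segmented <- function(seg, L) {
  seg$intercept + seg$slope1 * L + seg$slope2 * pmax(L - seg$breakpoint, 0)
}

#' Fit the homopolymer length model
#'
#' @param observations data.frame from
#'   \code{\link{extract_homopolymer_observations}}.
#' @param min_len minimum reference run length modelled (default 5).
#' @param min_obs per-base observation count below which the base falls
#'   back to an identity mean model with SD 0.5 (default 30).
#' @return object of class \code{homopolymer_model}: per base, \code{mean}
#'   (two-segment regression) and \code{sd} (linear regression of
#'   per-length SD on reference length; predictions clamped >= 0.1), plus
#'   observation counts.
#' @export
fit_homopolymer_model <- function(observations, min_len = 5L, min_obs = 30L) {
  per_base <- list()
  for (b in DNA_BASES) {
    d <- observations[observations$base == b, , drop = FALSE]
    if (nrow(d) < min_obs) {
      warnf("only %d homopolymer observations for base %s; falling back to identity mean, SD 0.5",
            nrow(d), b)
      per_base[[b]] <- list(
        mean = list(breakpoint = min_len, intercept = 0, slope1 = 1, slope2 = 0),
        sd = list(intercept = 0.5, slope = 0), n = nrow(d), fallback = TRUE)
      next
    }
    seg <- fit_segmented(d$ref_len, d$read_len)
    grp <- split(d$read_len, d$ref_len)
    gl <- as.integer(names(grp))
    gsd <- vapply(grp, function(v) if (length(v) > 1L) stats::sd(v) else NA_real_,
                  numeric(1))
    ok <- !is.na(gsd)
    sd_fit <- if (sum(ok) >= 2L) {
      f <- stats::lm(gsd[ok] ~ gl[ok])
      list(intercept = unname(stats::coef(f)[1]), slope = unname(stats::coef(f)[2]))
    } else {
      list(intercept = if (any(ok)) gsd[ok][1] else 0.5, slope = 0)
    }
    per_base[[b]] <- list(mean = seg, sd = sd_fit, n = nrow(d), fallback = FALSE)
  }
  structure(list(min_len = as.integer(min_len), per_base = per_base),
            class = "homopolymer_model")
}

#' @export
print.homopolymer_model <- function(x, ...) {
  cat(sprintf("Homopolymer model (min run length %d)\n", x$min_len))
  for (b in DNA_BASES) {
    m <- x$per_base[[b]]
    cat(sprintf("  %s: n = %d, mean(L) = %.3f + %.3f*L (+ %.3f beyond L = %g)%s\n",
                b, m$n, m$mean$intercept, m$mean$slope1, m$mean$slope2,
                m$mean$breakpoint, if (isTRUE(m$fallback)) " [fallback]" else ""))
  }
  invisible(x)
}

#' Predict read homopolymer length moments
#'
#' @param model a \code{homopolymer_model}.
#' @param base run base.
#' @param ref_len reference run length (vectorized).
#' @return list with \code{mean} and \code{sd} (clamped >= 0.1).
#' @export
predict_homopolymer <- function(model, base, ref_len) {
  m <- model$per_base[[base]]
  list(mean = predict_segmented(m$mean, ref_len),
       sd = pmax(0.1, m$sd$intercept + m$sd$slope * ref_len))
}

#' Apply homopolymer expansion/contraction to a template
#'
#' Every run of length >= \code{min_len} is replaced by a run of length
#' drawn from the fitted Normal (rounded, clamped at 0; 0 deletes the run
#' entirely).  Returns the modified sequence, per-run records, and the
#' modified intervals in new-sequence coordinates, which the simulator
#' masks from generic error placement.
#'
#' @param template_seq template DNA string.
#' @param model a \code{homopolymer_model}.
#' @return list with \code{seq}, \code{records} (data.frame: \code{base},
#'   \code{ref_start}, \code{len_ref}, \code{len_read}, \code{new_start}),
#'   and \code{masked} (matrix of 0-based half-open intervals on the new
#'   sequence).
#' @export
apply_homopolymer_effects <- function(template_seq, model) {
  runs <- find_homopolymers(template_seq, model$min_len)
  if (!nrow(runs)) {
    return(list(seq = template_seq,
                records = fast_df(base = character(0), ref_start = integer(0),
                                  len_ref = integer(0), len_read = integer(0),
                                  new_start = integer(0)),
                masked = matrix(integer(0), 0, 2,
                                dimnames = list(NULL, c("start", "end")))))
  }
  new_len <- integer(nrow(runs))
  for (b in unique(runs$base)) {
    sel <- runs$base == b
    pred <- predict_homopolymer(model, b, runs$length[sel])
    draw <- stats::rnorm(sum(sel), pred$mean, pred$sd)
    new_len[sel] <- pmax(0L, as.integer(round(draw)))
  }
  # rebuild: segments between runs are untouched
  seg_start <- c(0L, runs$start + runs$length)
  seg_end <- c(runs$start, nchar(template_seq))
  pieces <- character(2L * nrow(runs) + 1L)
  pieces[seq(1L, by = 2L, length.out = nrow(runs) + 1L)] <-
    substring(template_seq, seg_start + 1L, seg_end)
  pieces[seq(2L, by = 2L, length.out = nrow(runs))] <-
    strrep(runs$base, new_len)
  shift <- cumsum(c(0L, new_len - runs$length))[seq_len(nrow(runs))]
  new_start <- runs$start + shift
  list(seq = paste(pieces, collapse = ""),
       records = fast_df(base = runs$base, ref_start = runs$start,
                         len_ref = runs$length, len_read = new_len,
                         new_start = new_start),
       masked = cbind(start = new_start, end = new_start + new_len))
}
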