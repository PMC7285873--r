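# Base-call error model.
#
# An aligned read is decomposed into an alternating sequence of match
# stretches and error events (mismatch / insertion / deletion runs).  The
# model has four parts:
#   * per-type error rates per aligned reference base;
#   * error-length distributions: a truncated-Poisson/Geometric mixture for
#     mismatch run lengths and discretized-Weibull/Geometric mixtures for
#     insertion and deletion lengths, fitted by EM with random restarts;
#   * a KDE over match-stretch lengths (the inter-error distances,
#     including the zero stretches between abutting errors);
#   * a first-order Markov chain over consecutive error types, with an
#     initial distribution over the first error type of a read.

ERR_TYPES <- c("mis", "ins", "del")

#' Extract error events from aligned reads
#'
#' Walks every primary alignment and collects error events (X runs as
#' mismatches, I runs as insertions, D runs as deletions), the match
#' stretches between them, the first-error types and consecutive-type
#' bigram counts.  N (splice) operations close the current segment without
#' emitting an error.  Unaligned reads carry no events and are excluded by
#' construction.
#'
#' @param alignments list of alignment records with resolved =/X walks.
#' @return object of class \code{error_events}: list with \code{events}
#'   (data.frame \code{read}, \code{type}, \code{length}), \code{matches}
#'   (integer vector of match-stretch lengths), \code{first_types},
#'   \code{bigrams} (3x3 count matrix), \code{aligned_ref_bases},
#'   \code{type_bases} and \code{rates}.
#' @export
extract_error_events <- function(alignments) {
  alignments <- Filter(function(a) isTRUE(a$is_primary), alignments)
  if (!length(alignments)) stopf("no primary alignments")
  nrows <- vapply(alignments, function(a) nrow(a$walk), integer(1))
  op <- unlist(lapply(alignments, function(a) a$walk[, "op"]), use.names = FALSE)
  len <- unlist(lapply(alignments, function(a) a$walk[, "len"]), use.names = FALSE)
  read <- rep(seq_along(alignments), nrows)
  # segments: new read or an N op starts a new segment
  seg <- cumsum(c(TRUE, read[-1] != read[-length(read)]) | op == OP_N)
  is_err <- op %in% c(OP_X, OP_I, OP_D)
  if (any(op == OP_M & c(op[-1], 0L) == OP_M & seg == c(seg[-1], -1L))) {
    stopf("adjacent unmerged M ops encountered")
  }
  err_idx <- which(is_err)
  type <- op[err_idx] - 1L  # X->1 mis, I->2 ins, D->3 del
  # match stretch before each error: preceding M run in the same segment
  prev_ok <- err_idx > 1L
  prev_idx <- pmax(err_idx - 1L, 1L)
  m_before <- ifelse(prev_ok & op[prev_idx] == OP_M & seg[prev_idx] == seg[err_idx],
                     len[prev_idx], 0L)
  # trailing stretch per segment: final M run (or 0 if segment ends in error)
  seg_last <- which(c(seg[-1] != seg[-length(seg)], TRUE))
  trailing <- ifelse(op[seg_last] == OP_M, len[seg_last], 0L)
  # segments with zero errors contribute their (single) M run via `trailing`
  matches <- c(m_before, trailing)
  matches <- matches[order(c(err_idx, seg_last))]  # stable, order irrelevant
  # first error type per segment and bigrams of consecutive errors
  err_seg <- seg[err_idx]
  first_of_seg <- c(TRUE, err_seg[-1] != err_seg[-length(err_seg)])
  first_types <- type[first_of_seg]
  bigrams <- matrix(0L, 3, 3, dimnames = list(ERR_TYPES, ERR_TYPES))
  if (length(type) > 1L) {
    same <- err_seg[-1] == err_seg[-length(err_seg)]
    if (any(same)) {
      tt <- table(factor(type[-length(type)][same], levels = 1:3),
                  factor(type[-1][same], levels = 1:3))
      bigrams <- bigrams + as.integer(tt)
      dim(bigrams) <- c(3, 3); dimnames(bigrams) <- list(ERR_TYPES, ERR_TYPES)
    }
  }
  aligned_ref <- sum(len[op %in% c(OP_M, OP_X, OP_D)])
  type_bases <- vapply(1:3, function(t) sum(len[err_idx][type == t]), numeric(1))
  names(type_bases) <- ERR_TYPES
  structure(list(
    events = data.frame(read = read[err_idx], type = type, length = len[err_idx]),
    matches = as.integer(matches),
    first_types = first_types,
    bigrams = bigrams,
    aligned_ref_bases = aligned_ref,
    type_bases = type_bases,
    rates = type_bases / aligned_ref,
    n_reads = length(alignments)), class = "error_events")
}

#' @export
print.error_events <- function(x, ...) {
  cat(sprintf("Error events from %d reads, %.3g aligned reference bases\n",
              x$n_reads, x$aligned_ref_bases))
  cat(sprintf("  rates: mis %.4f, ins %.4f, del %.4f\n",
              x$rates["mis"], x$rates["ins"], x$rates["del"]))
  invisible(x)
}

#' Summarize consecutive match/error stretch lengths
#'
#' Evaluation utility: tabulates the lengths of consecutive match stretches
#' and of error events per type, for comparing empirical against simulated
#' reads.
#'
#' @param alignments list of alignment records.
#' @return list with \code{match_lengths} (table), \code{error_lengths}
#'   (table over all error events), \code{per_type} (list of tables), and
#'   \code{n_events}.
#' @export
measure_segment_lengths <- function(alignments) {
  ev <- extract_error_events(alignments)
  list(match_lengths = table(ev$matches),
       error_lengths = table(ev$events$length),
       per_type = lapply(1:3, function(t) table(ev$events$length[ev$events$type == t])),
       n_events = nrow(ev$events))
}

## ---- length mixtures -----------------------------------------------------

# Discrete densities on support {1, 2, ...}
dgeom1 <- function(x, p) stats::dgeom(x - 1L, p)
dpois_trunc <- function(x, lambda) {
  stats::dpois(x, lambda) / (1 - exp(-lambda))
}
dweibull_disc <- function(x, shape, scale) {
  lo <- stats::pweibull(pmax(x - 0.5, 0.5), shape, scale)
  hi <- stats::pweibull(x + 0.5, shape, scale)
  (hi - lo) / (1 - stats::pweibull(0.5, shape, scale))
}

rpois_trunc <- function(n, lambda) {
  stats::qpois(stats::runif(n, stats::ppois(0, lambda), 1), lambda)
}
rweibull_disc <- function(n, shape, scale) {
  u0 <- stats::pweibull(0.5, shape, scale)
  pmax(1L, as.integer(round(stats::qweibull(stats::runif(n, u0, 1), shape, scale))))
}

mixture_density <- function(x, mix) {
  if (mix$family == "geometric") return(dgeom1(x, mix$p_geom))
  f1 <- if (mix$family == "poisson") dpois_trunc(x, mix$lambda)
        else dweibull_disc(x, mix$shape, mix$scale)
  mix$w * f1 + (1 - mix$w) * dgeom1(x, mix$p_geom)
}

mixture_mean <- function(mix) {
  if (mix$family == "geometric") return(1 / mix$p_geom)
  xs <- 1:5000
  m1 <- sum(xs * (if (mix$family == "poisson") dpois_trunc(xs, mix$lambda)
                  else dweibull_disc(xs, mix$shape, mix$scale)))
  mix$w * m1 + (1 - mix$w) / mix$p_geom
}

sample_mixture <- function(mix, n) {
  if (n == 0L) return(integer(0))
  if (mix$family == "geometric") {
    return(as.integer(stats::rgeom(n, mix$p_geom) + 1L))
  }
  use1 <- stats::runif(n) < mix$w
  out <- integer(n)
  n1 <- sum(use1)
  if (n1) {
    out[use1] <- if (mix$family == "poisson") rpois_trunc(n1, mix$lambda)
                 else rweibull_disc(n1, mix$shape, mix$scale)
  }
  out[!use1] <- as.integer(stats::rgeom(n - n1, mix$p_geom) + 1L)
  out
}

# Weighted geometric MLE on {1,2,...}: p = 1/mean.
fit_geom_weighted <- function(v, w) min(1, sum(w) / sum(w * v))

# EM fit of a two-component mixture (comp1 = truncated Poisson or
# discretized Weibull, comp2 = Geometric) on integer lengths >= 1.
# 5 random restarts; best log-likelihood kept.
fit_length_mixture <- function(lengths, family = c("poisson", "weibull"),
                               n_restarts = 5L, max_iter = 200L, tol = 1e-8) {
  family <- match.arg(family)
  lengths <- as.integer(lengths)
  stopifnot(all(lengths >= 1L))
  tab <- table(lengths)
  v <- as.integer(names(tab)); cnt <- as.numeric(tab)
  n <- sum(cnt)
  if (length(lengths) < 10L) {
    p <- fit_geom_weighted(v, cnt)
    return(list(family = "geometric", p_geom = p, w = 0,
                mean = 1 / p, n = n, loglik = sum(cnt * log(dgeom1(v, p)))))
  }
  if (all(v == 1L)) {
    warnf("all %s lengths equal 1; degenerate fit replaced by Geometric(p = 1)", family)
    return(list(family = "geometric", p_geom = 1, w = 0, mean = 1, n = n,
                loglik = 0))
  }
  mu <- sum(cnt * v) / n
  comp1_dens <- function(par) {
    if (family == "poisson") dpois_trunc(v, par[1]) else dweibull_disc(v, par[1], par[2])
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    w <- stats::runif(1, 0.2, 0.8)
    par <- if (family == "poisson") {
      max(0.1, mu * stats::runif(1, 0.5, 1.5))
    } else {
      c(stats::runif(1, 0.6, 2.0), max(0.5, mu * stats::runif(1, 0.5, 1.5)))
    }
    p_geom <- min(1 - 1e-9, 1 / mu * stats::runif(1, 0.5, 1.5))
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      f1 <- pmax(comp1_dens(par), 1e-300)
      f2 <- pmax(dgeom1(v, p_geom), 1e-300)
      denom <- w * f1 + (1 - w) * f2
      g1 <- w * f1 / denom
      ll <- sum(cnt * log(denom))
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
      ll_old <- ll
      # M-step
      w <- sum(cnt * g1) / n
      w <- min(max(w, 1e-6), 1 - 1e-6)
      p_geom <- fit_geom_weighted(v, cnt * (1 - g1))
      p_geom <- min(max(p_geom, 1e-9), 1 - 1e-9)
      if (family == "poisson") {
        m1 <- sum(cnt * g1 * v) / sum(cnt * g1)
        par <- if (m1 <= 1 + 1e-9) 1e-3 else {
          stats::uniroot(function(l) l / (1 - exp(-l)) - m1,
                         c(1e-8, m1 + 1))$root
        }
      } else {
        obj <- function(lp) {
          d <- pmax(dweibull_disc(v, exp(lp[1]), exp(lp[2])), 1e-300)
          -sum(cnt * g1 * log(d))
        }
        o <- stats::optim(log(par), obj, control = list(maxit = 25))
        par <- exp(o$par)
      }
    }
    f1 <- pmax(comp1_dens(par), 1e-300)
    f2 <- pmax(dgeom1(v, p_geom), 1e-300)
    ll <- sum(cnt * log(w * f1 + (1 - w) * f2))
    if (is.null(best) || ll > best$loglik) {
      best <- if (family == "poisson") {
        list(family = family, w = w, lambda = par, p_geom = p_geom, loglik = ll)
      } else {
        list(family = family, w = w, shape = par[1], scale = par[2],
             p_geom = p_geom, loglik = ll)
      }
    }
  }
  best$n <- n
  best$mean <- mixture_mean(best)
  best
}

## ---- model fitting -------------------------------------------------------

#' Fit the base-call error model
#'
#' @param events an \code{error_events} object from
#'   \code{\link{extract_error_events}}.
#' @param min_events minimum total number of error events required.
#' @return object of class \code{error_model}: per-type \code{rates},
#'   length \code{mixtures} (mis: truncated Poisson/Geometric; ins, del:
#'   discretized Weibull/Geometric), \code{match_kde}, Markov transition
#'   matrix \code{markov} (rows: current type, columns: next type, add-one
#'   smoothed) and initial distribution \code{pi}.
#' @export
fit_error_model <- function(events, min_events = 500L) {
  stopifnot(inherits(events, "error_events"))
  if (nrow(events$events) < min_events) {
    stopf("only %d error events; need >= %d to fit the error model",
          nrow(events$events), min_events)
  }
  lens <- split(events$events$length, factor(events$events$type, levels = 1:3))
  mixtures <- list(
    mis = fit_length_mixture(lens[[1]], "poisson"),
    ins = fit_length_mixture(lens[[2]], "weibull"),
    del = fit_length_mixture(lens[[3]], "weibull"))
  markov <- (events$bigrams + 1) / rowSums(events$bigrams + 1)
  pi0 <- tabulate(events$first_types, nbins = 3L)
  pi0 <- if (sum(pi0) == 0) rep(1 / 3, 3) else pi0 / sum(pi0)
  names(pi0) <- ERR_TYPES
  model <- list(rates = events$rates, mixtures = mixtures,
                match_kde = fit_kde1d(events$matches, scale = "log1p"),
                markov = markov, pi = pi0,
                n_events = nrow(events$events))
  stopifnot(all(abs(rowSums(model$markov) - 1) < 1e-9))
  class(model) <- "error_model"
  model
}

#' @export
print.error_model <- function(x, ...) {
  cat("Base-call error model\n")
  cat(sprintf("  rates: mis %.4f, ins %.4f, del %.4f (total %.4f)\n",
              x$rates["mis"], x$rates["ins"], x$rates["del"], sum(x$rates)))
  for (t in ERR_TYPES) {
    m <- x$mixtures[[t]]
    cat(sprintf("  %s lengths: %s mixture, mean %.2f nt\n", t,
                m$family, m$mean))
  }
  cat("  transition matrix:\n")
  print(round(x$markov, 3))
  invisible(x)
}

# Stationary distribution of the type chain (left eigenvector), used as an
# independent oracle in tests.
markov_stationary <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

## ---- layout sampling -----------------------------------------------------

# Vectorized Markov-type draws: `cur` integer vector of current states,
# cum 3x3 row-cumulative matrix.
step_markov <- function(cur, cum) {
  u <- stats::runif(length(cur))
  1L + (u > cum[cur, 1]) + (u > cum[cur, 2])
}

sample_match_lengths <- function(model, n) {
  pmax(0L, as.integer(round(sample_kde1d(model$match_kde, n))))
}

sample_type_lengths <- function(model, types) {
  out <- integer(length(types))
  for (t in 1:3) {
    sel <- types == t
    if (any(sel)) out[sel] <- sample_mixture(model$mixtures[[t]], sum(sel))
  }
  out
}

#' Sample error layouts for simulated reads
#'
#' Generates, for each requested aligned reference length, an alternating
#' sequence of match stretches and error events: match lengths from the
#' match KDE, the first error type from the initial distribution, later
#' types from the Markov chain, and lengths from the per-type mixtures.
#' The process stops once reference consumption (matches + mismatches +
#' deletions) reaches the target; the final event is truncated to fit.
#' Consecutive insertions (possible across a zero match stretch) are
#' merged.
#'
#' @param model an \code{error_model}.
#' @param aligned_ref_lens integer vector of reference lengths to cover.
#' @return list of layout matrices with columns \code{op} (1 = match,
#'   2 = mismatch, 3 = insertion, 4 = deletion) and \code{len}; reference
#'   consumption of each layout equals its requested length exactly.
#' @export
sample_error_layouts <- function(model, aligned_ref_lens) {
  n <- length(aligned_ref_lens)
  stopifnot(all(aligned_ref_lens >= 1L))
  if (sum(model$rates) == 0) {
    return(lapply(aligned_ref_lens, function(a) {
      cbind(op = 1L, len = as.integer(a))
    }))
  }
  cum <- t(apply(model$markov, 1, cumsum))
  # expected reference consumption per (match, error) pair, for sizing
  mean_match <- mean(pmax(0, round(expm1(model$match_kde$points))))
  stat <- markov_stationary(model$markov)
  mean_err_ref <- stat[1] * model$mixtures$mis$mean + stat[3] * model$mixtures$del$mean
  per_pair <- max(mean_match + mean_err_ref, 1)
  out <- vector("list", n)
  todo <- seq_len(n)
  target <- as.integer(aligned_ref_lens)
  # per-read partially built layouts for the (rare) extension case
  partial_ops <- vector("list", n); partial_lens <- vector("list", n)
  partial_cons <- integer(n)
  cur_state <- rep(NA_integer_, n)
  round_i <- 0L
  while (length(todo)) {
    round_i <- round_i + 1L
    need <- target[todo] - partial_cons[todo]
    E <- max(10L, as.integer(ceiling(max(need) / per_pair * 1.3)) + 10L)
    E <- min(E, max(10L, as.integer(ceiling(3e6 / length(todo)))))
    m <- matrix(sample_match_lengths(model, length(todo) * E), ncol = E)
    ty <- matrix(0L, length(todo), E)
    ty[, 1] <- ifelse(is.na(cur_state[todo]),
                      findInterval(stats::runif(length(todo)),
                                   cumsum(model$pi)) + 1L,
                      step_markov(cur_state[todo], cum))
    if (E > 1L) for (j in 2:E) ty[, j] <- step_markov(ty[, j - 1], cum)
    ln <- matrix(sample_type_lengths(model, as.integer(ty)), ncol = E)
    ref_c <- m + ifelse(ty == 1L | ty == 3L, ln, 0L)
    done_now <- logical(length(todo))
    for (ii in seq_along(todo)) {
      i <- todo[ii]
      cons <- partial_cons[i] + cumsum(ref_c[ii, ])
      k <- which(cons >= target[i])[1]
      if (is.na(k)) {  # extend next round
        partial_ops[[i]] <- c(partial_ops[[i]],
                              rbind(1L, ty[ii, ] + 1L))
        partial_lens[[i]] <- c(partial_lens[[i]], rbind(m[ii, ], ln[ii, ]))
        partial_cons[i] <- cons[E]
        cur_state[i] <- ty[ii, E]
        next
      }
      ops <- c(partial_ops[[i]], rbind(1L, ty[ii, 1:k] + 1L))
      lens <- c(partial_lens[[i]], rbind(m[ii, 1:k], ln[ii, 1:k]))
      # truncate to exact consumption
      refc <- ifelse(ops == 1L | ops == 2L | ops == 4L, lens, 0L)
      cc <- cumsum(refc)
      over <- cc[length(cc)] - target[i]
      if (over > 0L) {
        # walk back from the end, trimming consuming ops
        j <- length(ops)
        while (over > 0L) {
          if (refc[j] > 0L) {
            trim <- min(over, lens[j])
            lens[j] <- lens[j] - trim
            over <- over - trim
          }
          j <- j - 1L
        }
      } else if (ops[length(ops)] == 3L && cc[length(cc)] == target[i]) {
        # keep trailing insertion only if target was already met before it:
        # it was, since insertions consume nothing -- keep it.
      }
      keep <- lens > 0L
      w <- merge_walk(cbind(op = ops[keep], len = as.integer(lens[keep])))
      out[[i]] <- w
      done_now[ii] <- TRUE
    }
    todo <- todo[!done_now]
    if (round_i > 10000L) stopf("error-layout sampling failed to terminate")
  }
  out
}

#' Apply an error layout to a template sequence
#'
#' Mismatched bases are substituted uniformly among the three alternatives,
#' inserted bases are uniform over \{A,C,G,T\}, deleted bases are dropped.
#' Event records carry read coordinates, template (reference) offsets and
#' the realized bases, sufficient for byte-exact replay.
#'
#' @param template_seq template DNA string; the layout must consume exactly
#'   \code{nchar(template_seq)} reference bases.
#' @param layout layout matrix from \code{\link{sample_error_layouts}}.
#' @return list with \code{seq} (the mutated read) and \code{events}
#'   (data.frame \code{type}, \code{read_pos}, \code{ref_pos},
#'   \code{len_ref}, \code{len_read}, \code{bases}; 0-based offsets).
#' @export
apply_errors <- function(template_seq, layout) {
  L <- nchar(template_seq)
  if (!nrow(layout)) stopf("empty error layout")
  op <- layout[, "op"]; len <- layout[, "len"]
  ref_c <- ifelse(op != 3L, len, 0L)
  read_c <- ifelse(op != 4L, len, 0L)
  if (sum(ref_c) != L) {
    stopf("layout consumes %d reference bases but template has %d", sum(ref_c), L)
  }
  ref_end <- cumsum(ref_c); ref_start <- ref_end - ref_c
  read_end <- cumsum(read_c); read_start <- read_end - read_c
  tc <- strsplit(template_seq, "", fixed = TRUE)[[1]]
  # substitutions
  mis <- which(op == 2L)
  if (length(mis)) {
    idx <- sequence(len[mis]) + rep(ref_start[mis], len[mis])
    tc[idx] <- substitute_bases(tc[idx])
  }
  # deletions: drop template positions
  del <- which(op == 4L)
  keep <- rep(TRUE, L)
  if (length(del)) {
    keep[sequence(len[del]) + rep(ref_start[del], len[del])] <- FALSE
  }
  core <- tc[keep]
  # insertions: uniform random bases, spliced in at their read positions
  ins <- which(op == 3L)
  if (length(ins)) {
    n_ins <- sum(len[ins])
    ins_chars <- sample(DNA_BASES, n_ins, replace = TRUE)
    # anchor: number of kept-template chars preceding the insertion
    kept_before <- ref_start[ins] - vapply(ref_start[ins], function(p) {
      if (!length(del)) 0L else sum(pmin(len[del], pmax(0L, p - ref_start[del])))
    }, integer(1))
    key <- c(seq_along(core), rep(kept_before + 0.5, len[ins]) +
               sequence(len[ins]) * 1e-9)
    combined <- c(core, ins_chars)
    core <- combined[order(key)]
  }
  seq <- paste(core, collapse = "")
  ev <- which(op != 1L)
  type <- ERR_TYPES[op[ev] - 1L]
  events <- fast_df(
    type = type,
    read_pos = read_start[ev],
    ref_pos = ref_start[ev],
    len_ref = ref_c[ev],
    len_read = read_c[ev],
    bases = ifelse(op[ev] == 4L,
                   substring(template_seq, ref_start[ev] + 1L,
                             ref_start[ev] + ref_c[ev]),
                   substring(seq, read_start[ev] + 1L,
                             read_start[ev] + read_c[ev])))
  list(seq = seq, events = events)
}
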