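test_that("event extraction decomposes walks into errors and match stretches", {
  ev0 <- extract_error_events(list(aln("r", "t", wk(M = 10))))
  expect_equal(nrow(ev0$events), 0L)
  expect_equal(as.integer(ev0$matches), 10L)
  expect_equal(unname(sum(ev0$rates)), 0)

  ev <- extract_error_events(list(aln("r", "t",
                                      wk(M = 5, X = 2, M = 3, D = 1, M = 4))))
  expect_equal(ev$events$type, c(1L, 3L))        # mis, del
  expect_equal(ev$events$length, c(2L, 1L))
  expect_equal(sort(as.integer(ev$matches)), c(3L, 4L, 5L))
  expect_equal(unname(ev$rates["mis"]), 2 / 15)
  expect_equal(unname(ev$rates["del"]), 1 / 15)
  # abutting errors record a zero match stretch between them
  ev2 <- extract_error_events(list(aln("r", "t", wk(M = 5, X = 1, D = 2, M = 3))))
  expect_true(0L %in% ev2$matches)
})

test_that("fixture error rates are recovered from extracted events", {
  co <- std_corpus()
  ev <- extract_error_events(co$rd$transcriptome_alignments)
  proc <- nanotxsim:::fixture_error_process(co$spec)
  expect_lt(max(abs(ev$rates - proc$rates)), 0.004)
})

test_that("mixture fitting recovers a pure geometric length law", {
  set.seed(31)
  x <- stats::rgeom(20000, 0.4) + 1L
  f <- nanotxsim:::fit_length_mixture(x, "poisson")
  expect_lt(abs(f$mean - 1 / 0.4) / (1 / 0.4), 0.05)
  f2 <- nanotxsim:::fit_length_mixture(x, "weibull")
  expect_lt(abs(f2$mean - 1 / 0.4) / (1 / 0.4), 0.05)
})

test_that("mixture fitting matches known two-component laws", {
  set.seed(32)
  y <- c(nanotxsim:::rpois_trunc(6000, 2.5), stats::rgeom(4000, 0.5) + 1L)
  f <- nanotxsim:::fit_length_mixture(y, "poisson")
  expect_lt(abs(f$mean - mean(y)) / mean(y), 0.02)
  z <- c(nanotxsim:::rweibull_disc(6000, 1.3, 2.2), stats::rgeom(4000, 0.55) + 1L)
  f2 <- nanotxsim:::fit_length_mixture(z, "weibull")
  expect_lt(abs(f2$mean - mean(z)) / mean(z), 0.02)
})

test_that("degenerate and sparse length sets fall back as documented", {
  expect_warning(f <- nanotxsim:::fit_length_mixture(rep(1L, 600), "weibull"),
                 "Geometric")
  expect_equal(f$family, "geometric")
  expect_equal(f$p_geom, 1)
  f2 <- nanotxsim:::fit_length_mixture(c(1L, 2L, 1L, 3L), "weibull")
  expect_equal(f2$family, "geometric")  # < 10 events
})

test_that("the error-type Markov chain is recovered within 3 SE", {
  P <- matrix(c(.5, .25, .25, .3, .4, .3, .2, .3, .5), 3, 3, byrow = TRUE)
  set.seed(33)
  st <- integer(10000); st[1] <- 1L
  for (i in 2:10000) st[i] <- sample.int(3L, 1L, prob = P[st[i - 1], ])
  walk <- wk(M = 10)  # placeholder; build events object directly
  big <- table(factor(st[-10000], levels = 1:3), factor(st[-1], levels = 1:3))
  ev <- structure(list(
    events = data.frame(read = 1L, type = st, length = 1L),
    matches = rep(5L, 100), first_types = st[1],
    bigrams = matrix(as.integer(big), 3, 3,
                     dimnames = list(nanotxsim:::ERR_TYPES,
                                     nanotxsim:::ERR_TYPES)),
    aligned_ref_bases = 1e5,
    type_bases = c(mis = 1, ins = 1, del = 1),
    rates = c(mis = .01, ins = .01, del = .01), n_reads = 1L),
    class = "error_events")
  suppressWarnings(m <- fit_error_model(ev))
  n_row <- rowSums(ev$bigrams)
  for (i in 1:3) for (j in 1:3) {
    se <- sqrt(P[i, j] * (1 - P[i, j]) / n_row[i])
    expect_lt(abs(m$markov[i, j] - P[i, j]), 3 * se)
  }
  expect_true(all(abs(rowSums(m$markov) - 1) < 1e-9))
})

test_that("unseen conditioning states get uniform rows after smoothing", {
  ev <- structure(list(
    events = data.frame(read = 1L, type = rep(1L, 600), length = rep(2L, 600)),
    matches = rep(4L, 601), first_types = 1L,
    bigrams = matrix(c(599L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L), 3, 3,
                     byrow = TRUE,
                     dimnames = list(nanotxsim:::ERR_TYPES,
                                     nanotxsim:::ERR_TYPES)),
    aligned_ref_bases = 5000, type_bases = c(mis = 1200, ins = 0, del = 0),
    rates = c(mis = .24, ins = 0, del = 0), n_reads = 1L),
    class = "error_events")
  suppressWarnings(m <- fit_error_model(ev))
  expect_equal(unname(m$markov[2, ]), rep(1 / 3, 3))
  expect_equal(unname(m$markov[3, ]), rep(1 / 3, 3))
})

test_that("layouts consume the requested reference length exactly", {
  em <- std_corpus()$prof$error_model
  set.seed(34)
  lens <- sample(50:800, 2000, replace = TRUE)
  lay <- sample_error_layouts(em, lens)
  consumed <- vapply(lay, function(w) {
    sum(w[w[, "op"] %in% c(1L, 2L, 4L), "len"])
  }, numeric(1))
  expect_equal(as.integer(consumed), lens)
  # consecutive insertions are merged
  for (w in lay[1:200]) {
    if (nrow(w) > 1L) expect_true(all(w[-1L, "op"] != w[-nrow(w), "op"] |
                                        w[-1L, "op"] != 3L))
  }
})

test_that("a zero-rate model yields a single match layout", {
  em <- std_corpus()$prof$error_model
  em$rates[] <- 0
  lay <- sample_error_layouts(em, c(100L, 7L))
  expect_equal(lay[[1]], cbind(op = 1L, len = 100L))
  expect_equal(lay[[2]], cbind(op = 1L, len = 7L))
})

test_that("sampled layouts reproduce the model's aggregate error rates", {
  em <- std_corpus()$prof$error_model
  set.seed(35)
  lay <- sample_error_layouts(em, rep(500L, 3000))
  ops <- unlist(lapply(lay, function(w) rep(w[, "op"], w[, "len"])))
  ref_bases <- sum(ops != 3L)
  rates <- c(mis = sum(ops == 2L), ins = sum(ops == 3L),
             del = sum(ops == 4L)) / ref_bases
  expect_lt(max(abs(rates - em$rates)), 0.004)
})

test_that("sampled error types converge to the chain's stationary law", {
  em <- std_corpus()$prof$error_model
  set.seed(36)
  lay <- sample_error_layouts(em, rep(400L, 2500))
  types <- unlist(lapply(lay, function(w) w[w[, "op"] != 1L, "op"])) - 1L
  emp <- tabulate(types, 3L) / length(types)
  stat <- nanotxsim:::markov_stationary(em$markov)
  # the stationary law weights events; insertion events are unaffected by
  # truncation so tolerance reflects Monte-Carlo error plus edge effects
  expect_lt(max(abs(emp - stat)), 0.02)
})

test_that("applying errors substitutes, inserts and deletes as recorded", {
  expect_error(apply_errors("ACGT", wk(M = 2)), "consumes")
  r0 <- apply_errors("ACGTACGT", wk(M = 8))
  expect_equal(r0$seq, "ACGTACGT")
  expect_equal(nrow(r0$events), 0L)

  set.seed(37)
  r1 <- apply_errors("AAAA", wk(M = 1, D = 2, M = 1))
  expect_equal(r1$seq, "AA")
  expect_equal(r1$events$type, "del")
  expect_equal(r1$events$ref_pos, 1L)
  expect_equal(r1$events$len_ref, 2L)
  expect_equal(r1$events$bases, "AA")

  r2 <- apply_errors("CCCC", wk(X = 2, M = 2))
  expect_equal(nchar(r2$seq), 4L)
  expect_false(substr(r2$seq, 1, 1) == "C")  # substituted among alternatives
  expect_equal(substr(r2$seq, 3, 4), "CC")
})

test_that("recorded events replay any mutated read byte-exactly", {
  em <- std_corpus()$prof$error_model
  set.seed(38)
  for (i in 1:300) {
    L <- sample(20:400, 1)
    tmpl <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  collapse = "")
    lay <- sample_error_layouts(em, L)[[1]]
    res <- apply_errors(tmpl, lay)
    ev <- res$events
    ev$event <- ev$type
    expect_identical(nanotxsim:::replay_error_rows(tmpl, ev), res$seq)
  }
})

test_that("segment-length histograms conserve event counts", {
  alns <- std_corpus()$rd$transcriptome_alignments[1:300]
  seg <- measure_segment_lengths(alns)
  ev <- extract_error_events(alns)
  expect_equal(seg$n_events, nrow(ev$events))
  expect_equal(sum(seg$error_lengths), nrow(ev$events))
  expect_equal(sum(seg$match_lengths), length(ev$matches))

  perfect <- list(aln("p1", "t", wk(M = 500)), aln("p2", "t", wk(M = 300)))
  seg0 <- measure_segment_lengths(perfect)
  expect_equal(length(seg0$error_lengths), 0L)
})

test_that("simulated segment lengths match the training distribution", {
  co <- std_corpus()
  ta <- truth_to_alignments(hpless_sim(co, 250, 41))
  # simulated reads draw lengths from the *fitted* mixtures, so the
  # comparison against the empirical training histogram is made at a
  # sample size where the parametric fit residual is below resolution
  set.seed(42)
  train_sub <- sample(co$rd$transcriptome_alignments, 250)
  seg_train <- measure_segment_lengths(train_sub)
  seg_sim <- measure_segment_lengths(ta$alignments)
  # chi-square over pooled error-length bins
  bins <- c(1:5, Inf)
  pool <- function(tab) {
    v <- as.integer(names(tab)); n <- as.numeric(tab)
    vapply(seq_len(length(bins) - 1L), function(k) {
      sum(n[v >= bins[k] & v < bins[k + 1L]])
    }, numeric(1))
  }
  o <- pool(seg_sim$error_lengths); e <- pool(seg_train$error_lengths)
  keep <- e > 0
  test <- suppressWarnings(stats::chisq.test(rbind(o[keep], e[keep])))
  expect_gt(test$p.value, 0.01)
})
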