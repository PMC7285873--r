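test_that("homopolymer runs are found as maximal left-to-right runs", {
  expect_equal(nrow(find_homopolymers("ACGT", 5)), 0L)
  r <- find_homopolymers("AAAAACCCCCC", 5)
  expect_equal(r$base, c("A", "C"))
  expect_equal(r$start, c(0L, 5L))
  expect_equal(r$length, c(5L, 6L))
  # below threshold and interrupted runs are excluded
  expect_equal(nrow(find_homopolymers("AAAATAAAA", 5)), 0L)
})

test_that("planted reference runs are recalled exactly", {
  co <- hp_corpus()
  pl <- co$ref$planted_runs
  expect_gt(nrow(pl), 20L)
  for (tid in unique(pl$transcript_id)) {
    found <- find_homopolymers(co$ref$transcriptome[[tid]], 5)
    p <- pl[pl$transcript_id == tid, ]
    for (j in seq_len(nrow(p))) {
      expect_true(any(found$base == p$base[j] & found$start == p$start[j] &
                        found$length == p$length[j]))
    }
  }
})

test_that("read-side run lengths are measured through the edit walk", {
  ref <- c(t1 = paste0("CGT", strrep("A", 10), "CGTCG"))
  perfect <- aln("r1", "t1", wk(M = 18))
  obs <- extract_homopolymer_observations(list(perfect), ref, 5)
  expect_equal(obs$base, "A")
  expect_equal(obs$ref_len, 10L)
  expect_equal(obs$read_len, 10L)
  # 3-base deletion inside the run contracts it to 7
  contracted <- aln("r2", "t1", wk(M = 8, D = 3, M = 7))
  obs2 <- extract_homopolymer_observations(list(contracted), ref, 5)
  expect_equal(obs2$read_len, 7L)
  # insertion strictly inside the run expands it
  expanded <- aln("r3", "t1", wk(M = 8, I = 2, M = 10))
  obs3 <- extract_homopolymer_observations(list(expanded), ref, 5)
  expect_equal(obs3$read_len, 12L)
  # run truncated by the alignment boundary is skipped
  truncated <- aln("r4", "t1", wk(M = 7), target_start = 0L)
  obs4 <- extract_homopolymer_observations(list(truncated), ref, 5)
  expect_equal(nrow(obs4), 0L)
})

test_that("extraction reproduces the fixture generator's observations", {
  co <- hp_corpus()
  obs <- extract_homopolymer_observations(co$reads$alignments,
                                          co$ref$transcriptome, 5)
  expect_equal(nrow(obs), nrow(co$reads$observations))
  a1 <- stats::aggregate(read_len ~ ref_len, obs, mean)
  a2 <- stats::aggregate(read_len ~ ref_len, co$reads$observations, mean)
  m <- merge(a1, a2, by = "ref_len")
  expect_equal(m[[2]], m[[3]], tolerance = 1e-12)
})

test_that("segmented regressions recover the generating homopolymer law", {
  co <- hp_corpus()
  obs <- extract_homopolymer_observations(co$reads$alignments,
                                          co$ref$transcriptome, 5)
  m <- fit_homopolymer_model(obs, 5)
  for (b in c("A", "C", "G", "T")) {
    pred <- predict_homopolymer(m, b, 5:20)
    expect_lt(max(abs(pred$mean - 0.9 * (5:20)) / (0.9 * (5:20))), 0.05)
    sd_true <- 0.05 * (5:20) + 0.3
    expect_lt(max(abs(pred$sd - sd_true)), 0.25)
  }
})

test_that("identity observations give an identity mean model and near-zero SD", {
  obs <- data.frame(
    base = rep(c("A", "C", "G", "T"), each = 60),
    ref_len = rep(rep(c(5L, 8L, 12L), each = 20), 4))
  obs$read_len <- obs$ref_len
  m <- fit_homopolymer_model(obs, 5)
  pred <- predict_homopolymer(m, "A", c(5, 8, 12))
  expect_equal(pred$mean, c(5, 8, 12), tolerance = 1e-8)
  expect_equal(pred$sd, rep(0.1, 3))  # clamped at the floor
})

test_that("sparse bases fall back to the identity model with a warning", {
  obs <- data.frame(base = rep("A", 100), ref_len = rep(6L, 100),
                    read_len = rep(5L, 100))
  w <- capture_warnings(m <- fit_homopolymer_model(obs, 5))
  expect_true(any(grepl("falling back", w)))  # one warning per sparse base
  pred <- predict_homopolymer(m, "C", 10)
  expect_equal(pred$mean, 10)
  expect_equal(pred$sd, 0.5)
})

test_that("applying an identity model leaves the sequence unchanged", {
  m <- structure(list(min_len = 5L, per_base = stats::setNames(lapply(1:4, function(i) {
    list(mean = list(breakpoint = 5, intercept = 0, slope1 = 1, slope2 = 0),
         sd = list(intercept = 0, slope = 0), n = 100L, fallback = FALSE)
  }), c("A", "C", "G", "T"))), class = "homopolymer_model")
  tmpl <- paste0("CGT", strrep("A", 12), "CG", strrep("T", 7), "ACG")
  res <- apply_homopolymer_effects(tmpl, m)
  expect_identical(res$seq, tmpl)
  expect_equal(res$records$len_read, res$records$len_ref)
})

test_that("a fixed contraction is applied deterministically with exact bookkeeping", {
  m <- structure(list(min_len = 5L, per_base = stats::setNames(lapply(1:4, function(i) {
    list(mean = list(breakpoint = 5, intercept = -2, slope1 = 1, slope2 = 0),
         sd = list(intercept = -1, slope = 0), n = 100L, fallback = FALSE)
  }), c("A", "C", "G", "T"))), class = "homopolymer_model")
  # sd clamps to 0.1; use mean 18 for run 20 and round(rnorm(18, 0.1)) ~ 18
  m$per_base$A$mean$intercept <- -2
  tmpl <- paste0("CG", strrep("A", 20), "TC")
  set.seed(71)
  reps <- replicate(50, {
    r <- apply_homopolymer_effects(tmpl, m)
    c(nchar(r$seq), r$records$len_read)
  })
  expect_true(all(abs(reps[2, ] - 18) <= 1))  # sd floor 0.1 keeps it at 18 +/- 0
  # sequence length arithmetic is exact
  expect_true(all(reps[1, ] == 4 + reps[2, ]))
})

test_that("modified runs are masked, non-overlapping, and flanks untouched", {
  co <- hp_corpus()
  obs <- extract_homopolymer_observations(co$reads$alignments,
                                          co$ref$transcriptome, 5)
  m <- fit_homopolymer_model(obs, 5)
  set.seed(72)
  for (i in 1:30) {
    tid <- sample(names(co$ref$transcriptome), 1)
    tmpl <- co$ref$transcriptome[[tid]]
    res <- apply_homopolymer_effects(tmpl, m)
    rec <- res$records
    expect_equal(nchar(res$seq),
                 nchar(tmpl) + sum(rec$len_read - rec$len_ref))
    if (nrow(res$masked) > 1L) {
      expect_true(all(res$masked[-1L, "start"] >=
                        res$masked[-nrow(res$masked), "end"]))
    }
    # bytes outside the runs are identical
    runs <- find_homopolymers(tmpl, 5)
    pre <- substr(tmpl, 1, runs$start[1])
    expect_identical(substr(res$seq, 1, runs$start[1]), pre)
  }
})

test_that("draws at a fixed reference length match model moments", {
  co <- hp_corpus()
  obs <- extract_homopolymer_observations(co$reads$alignments,
                                          co$ref$transcriptome, 5)
  m <- fit_homopolymer_model(obs, 5)
  tmpl <- paste0("CG", strrep("A", 15), "TC")
  set.seed(73)
  draws <- replicate(4000, apply_homopolymer_effects(tmpl, m)$records$len_read)
  pred <- predict_homopolymer(m, "A", 15)
  se_mean <- pred$sd / sqrt(4000)
  expect_lt(abs(mean(draws) - pred$mean), 3 * se_mean + 0.3)  # + rounding bias
  expect_lt(abs(stats::sd(draws) - pred$sd), 0.15)
})
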