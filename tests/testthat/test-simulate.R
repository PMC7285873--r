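test_that("transcript selection follows expression probabilities", {
  p <- nanotxsim:::new_expression_profile(c("a", "b", "z"), c(3, 1, 0),
                                          c(750000, 250000, 0), 4)
  set.seed(81)
  draws <- select_transcript(p, 100000)
  f <- table(factor(draws, levels = c("a", "b", "z"))) / 1e5
  se <- sqrt(0.75 * 0.25 / 1e5)
  expect_lt(abs(f[["a"]] - 0.75), 3 * se)
  expect_equal(unname(f[["z"]]), 0)  # zero TPM never selected
  single <- nanotxsim:::new_expression_profile("only", 1, 1e6, 1)
  expect_true(all(select_transcript(single, 50) == "only"))
  expect_error(select_transcript(p[0, ], 1), "empty")
})

test_that("uniform error layouts consume the template exactly at high rates", {
  set.seed(82)
  for (len in c(1L, 5L, 50L, 400L)) {
    w <- nanotxsim:::uniform_error_layout(len, 0.9)
    expect_equal(sum(w[w[, "op"] %in% c(1L, 2L, 4L), "len"]), len)
  }
  # rate 0 gives a pure match
  expect_equal(nanotxsim:::uniform_error_layout(30L, 0), cbind(op = 1L, len = 30L))
})

test_that("mask interleaving splices forced matches at the right offsets", {
  lay <- wk(M = 10, X = 2, M = 8)   # consumes 20 unmasked bases
  masked <- cbind(start = c(5L, 15L), end = c(9L, 18L))  # 4 + 3 masked
  full <- nanotxsim:::interleave_mask(lay, masked, 27L)
  expect_equal(sum(full[full[, "op"] != 3L, "len"]), 27L)
  # ops covering the masked intervals must be matches
  pos <- 0L
  for (j in seq_len(nrow(full))) {
    if (full[j, "op"] != 3L) {
      s <- pos; e <- pos + full[j, "len"]
      for (k in seq_len(nrow(masked))) {
        ov <- min(e, masked[k, "end"]) - max(s, masked[k, "start"])
        if (ov > 0) expect_equal(unname(full[j, "op"]), 1L)
      }
      pos <- e
    }
  }
  # empty layout: masks become the whole walk
  full0 <- nanotxsim:::interleave_mask(NULL, cbind(start = 0L, end = 7L), 7L)
  expect_equal(full0, cbind(op = 1L, len = 7L))
})

test_that("perfect sense-only reads are exact transcript substrings", {
  co <- std_corpus()
  prof <- co$prof
  prof$strand_ratio <- 1
  prof$unaligned_fraction <- 0
  prof$length_model$flank_kde <- nanotxsim:::fit_kde2d(rep(0, 50), rep(0, 50))
  sim <- simulate_reads(prof, co$ref$transcriptome, 60, seed = 83,
                        perfect = TRUE)
  expect_true(all(sim$reads$strand == "+"))
  for (i in seq_len(nrow(sim$reads))) {
    expect_true(grepl(sim$reads$sequence[i],
                      co$ref$transcriptome[[sim$reads$transcript_id[i]]],
                      fixed = TRUE))
  }
})

test_that("a strand ratio of 1 yields no antisense reads", {
  co <- std_corpus()
  prof <- co$prof
  prof$strand_ratio <- 1
  sim <- simulate_reads(prof, co$ref$transcriptome, 300, seed = 84)
  expect_true(all(sim$reads$strand == "+"))
})

test_that("aligned and unaligned category counts partition n exactly", {
  co <- std_corpus()
  sim <- simulate_reads(co$prof, co$ref$transcriptome, 777, seed = 85)
  n_un <- sum(sim$reads$category == "unaligned")
  expect_equal(n_un + sum(sim$reads$category == "aligned"), 777L)
  expect_equal(n_un, round(777 * co$prof$unaligned_fraction))
})

test_that("per-transcript read counts follow the expression multinomial", {
  co <- std_corpus()
  sim <- hpless_sim(co, 3000, 86)
  al <- sim$reads[sim$reads$category == "aligned", ]
  obs <- table(factor(al$transcript_id, levels = co$prof$expression$transcript_id))
  p <- co$prof$expression$tpm / 1e6
  test <- suppressWarnings(stats::chisq.test(as.integer(obs), p = p))
  expect_gt(test$p.value, 0.01)
})

test_that("identical seeds give byte-identical output for any worker count", {
  co <- std_corpus()
  s1 <- simulate_reads(co$prof, co$ref$transcriptome, 1200, seed = 87,
                       n_workers = 1, block_size = 300)
  s2 <- simulate_reads(co$prof, co$ref$transcriptome, 1200, seed = 87,
                       n_workers = 4, block_size = 300)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_reads(co$prof, co$ref$transcriptome, 1200, seed = 88,
                       n_workers = 1, block_size = 300)
  expect_false(identical(s1$reads$sequence, s3$reads$sequence))
})

test_that("every simulated read replays byte-exactly from its truth", {
  co <- std_corpus()
  ir <- ir_corpus()
  prof <- co$prof
  prof$ir_model <- fit_ir_model(detect_ir(ir$rd$genome_alignments,
                                          ir$rd$transcriptome_alignments,
                                          ir$ref$annotation))
  sim <- simulate_reads(prof, co$ref$transcriptome, 400,
                        genome = co$ref$genome,
                        annotation = co$ref$annotation, seed = 89,
                        with_ir = TRUE)
  expect_gt(sum(sim$truth$event == "homopolymer"), 0L)
  bad <- verify_truth(sim, co$ref$transcriptome, co$ref$genome,
                      co$ref$annotation)
  expect_length(bad, 0L)
  # uniform start mode preserves the contract too
  sim2 <- simulate_reads(prof, co$ref$transcriptome, 150,
                         genome = co$ref$genome,
                         annotation = co$ref$annotation, seed = 90,
                         with_ir = TRUE, start_mode = "uniform")
  expect_length(verify_truth(sim2, co$ref$transcriptome, co$ref$genome,
                             co$ref$annotation), 0L)
})

test_that("antisense reads are reverse complements of their sense construction", {
  co <- std_corpus()
  sim <- hpless_sim(co, 400, 91)
  minus <- which(sim$reads$strand == "-" & sim$reads$category == "aligned")
  expect_gt(length(minus), 10L)
  for (i in minus[1:10]) {
    id <- sim$reads$read_id[i]
    rows <- sim$truth[sim$truth$read_id == id, , drop = FALSE]
    rec <- nanotxsim:::replay_read_rows(id, rows, co$ref$transcriptome)
    expect_identical(rec, sim$reads$sequence[i])
    # the sense construction is the reverse complement of the emitted read
    sense_rows <- rows
    sense_id <- sub("!-!", "!+!", id, fixed = TRUE)
    sense <- nanotxsim:::replay_read_rows(sense_id, sense_rows,
                                          co$ref$transcriptome)
    expect_identical(revcomp(sense), sim$reads$sequence[i])
  }
})

test_that("unaligned reads carry truth and appear at the configured rate", {
  co <- std_corpus()
  sim <- simulate_reads(co$prof, co$ref$transcriptome, 2000, seed = 92)
  un <- sim$reads[sim$reads$category == "unaligned", ]
  expect_equal(nrow(un), round(2000 * co$prof$unaligned_fraction))
  # per-base mutation density is near the 90% default (events are merged
  # runs, so count mutated bases, not rows)
  ev <- sim$truth[sim$truth$read_id %in% un$read_id, ]
  mut_bases <- sum(pmax(ev$len_ref, ev$len_read))
  dens <- mut_bases / sum(un$aligned_len)
  se <- sqrt(0.9 * 0.1 / sum(un$aligned_len))
  expect_lt(abs(dens - 0.9), 5 * se + 0.01)
  bad <- verify_truth(sim, co$ref$transcriptome)
  expect_length(bad, 0L)
})

test_that("simulate() dispatches on the fitted profile", {
  co <- std_corpus()
  s <- simulate(co$prof, nsim = 25, seed = 93,
                transcriptome = co$ref$transcriptome)
  expect_s3_class(s, "simulated_reads")
  expect_equal(nrow(s$reads), 25L)
  expect_error(simulate_reads(co$prof, co$ref$transcriptome, 0), "positive")
})

test_that("truth-derived alignments satisfy walk invariants and match anatomy", {
  co <- std_corpus()
  sim <- hpless_sim(co, 300, 94)
  ta <- truth_to_alignments(sim)
  for (a in ta$alignments) check_alignment(a)
  al <- sim$reads[sim$reads$category == "aligned", ]
  expect_equal(length(ta$alignments), nrow(al))
  spans <- vapply(ta$alignments, function(a) a$target_end - a$target_start,
                  integer(1))
  expect_equal(spans, al$aligned_len)
})
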