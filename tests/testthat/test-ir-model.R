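test_that("splice gaps and contiguous coverage call intron states correctly", {
  ann <- one_intron_annotation(500L)
  # transcriptome alignment assigns the read to tx1 (spliced length 200)
  taln <- list(aln("r1", "tx1", wk(M = 200)), aln("r2", "tx1", wk(M = 200)))
  # r1: canonical spliced read -- N op exactly spans the intron
  g1 <- aln("r1", "chr1", wk(M = 100, N = 500, M = 100), kind = "genome")
  # r2: contiguous M straight through the 500-nt intron
  g2 <- aln("r2", "chr1", wk(M = 700), kind = "genome")
  obs <- detect_ir(list(g1, g2), taln, ann)
  states <- lapply(obs$observations, `[[`, "states")
  names(states) <- vapply(obs$observations, `[[`, character(1), "read_id")
  expect_false(states[["r1"]])
  expect_true(states[["r2"]])
  # report agrees with raw observations
  expect_equal(obs$report$reads_covering, 2L)
  expect_equal(obs$report$reads_retaining, 1L)
  expect_equal(obs$report$frequency, 0.5)
})

test_that("introns outside the read's genomic span are uncovered", {
  ann <- one_intron_annotation(500L)
  taln <- list(aln("r1", "tx1", wk(M = 90)))
  g <- aln("r1", "chr1", wk(M = 90), kind = "genome")  # first exon only
  obs <- detect_ir(list(g), taln, ann)
  expect_true(is.na(obs$observations[[1]]$states[1]))
  expect_error(fit_ir_model(obs), "no covered")
})

test_that("IR detection is exact on fixture reads with exact alignments", {
  co <- ir_corpus()
  obs <- detect_ir(co$rd$genome_alignments, co$rd$transcriptome_alignments,
                   co$ref$annotation)
  ok <- 0L; tot <- 0L
  for (o in obs$observations) {
    k <- as.integer(sub("fx", "", o$read_id))
    truth <- co$rd$ir_patterns[[k]]
    if (is.null(truth)) next
    tot <- tot + sum(!is.na(o$states))
    ok <- ok + sum(o$states == truth, na.rm = TRUE)
  }
  expect_gt(tot, 1000L)
  expect_equal(ok, tot)
  # report consistency: transcripts with >= 1 retained intron
  n_ret_report <- length(unique(obs$report$transcript_id[
    obs$report$reads_retaining > 0]))
  n_ret_raw <- length(unique(vapply(
    Filter(function(o) any(o$states, na.rm = TRUE), obs$observations),
    `[[`, character(1), "transcript_id")))
  expect_equal(n_ret_report, n_ret_raw)
})

test_that("the fitted chain recovers fixture transition probabilities", {
  co <- ir_corpus()
  obs <- detect_ir(co$rd$genome_alignments, co$rd$transcriptome_alignments,
                   co$ref$annotation)
  m <- fit_ir_model(obs)
  chain <- co$spec$ir_chain
  se_first <- sqrt(chain[1] * (1 - chain[1]) / m$counts$first[1])
  expect_lt(abs(m$p_first - chain[1]), 3 * se_first)
  tr <- m$counts$transitions
  se_s <- sqrt(chain[2] * (1 - chain[2]) / sum(tr[1, ]))
  se_r <- sqrt(chain[3] * (1 - chain[3]) / sum(tr[2, ]))
  expect_lt(abs(m$p_retain_given_spliced - chain[2]), 3 * se_s)
  expect_lt(abs(m$p_retain_given_retained - chain[3]), 3 * se_r)
})

test_that("rare first-intron retention with elevated conditional retention is representable", {
  # the human direct-RNA behaviour: first-intron retention is rare, but
  # retention given a retained predecessor is elevated roughly 41-fold
  m <- structure(list(p_first = 0.0041, p_retain_given_spliced = 0.0041,
                      p_retain_given_retained = 0.1712,
                      counts = list(first = c(10000L, 41L),
                                    transitions = matrix(0L, 2, 2))),
                 class = "ir_model")
  expect_equal(m$p_retain_given_retained / m$p_first, 41.75, tolerance = 0.01)
  set.seed(51)
  pats <- matrix(replicate(20000, sample_ir_pattern(m, 3)), nrow = 3)
  expect_lt(abs(mean(pats[1, ]) - 0.0041), 3 * sqrt(0.0041 * 0.9959 / 20000))
  cond <- c(pats[2, ][pats[1, ]], pats[3, ][pats[2, ]])
  if (length(cond) >= 30L) {
    expect_lt(abs(mean(cond) - 0.1712),
              3 * sqrt(0.1712 * (1 - 0.1712) / length(cond)))
  }
  fwd <- nanotxsim:::ir_forward_marginals(m, 3)
  emp <- rowMeans(pats)
  for (i in 1:3) {
    expect_lt(abs(emp[i] - fwd[i]), 3 * sqrt(fwd[i] * (1 - fwd[i]) / 20000) + 1e-12)
  }
})

test_that("all-spliced observations give zero retention probabilities", {
  obs <- lapply(1:50, function(i) {
    list(read_id = paste0("r", i), transcript_id = "t",
         states = c(FALSE, FALSE, FALSE))
  })
  m <- fit_ir_model(obs)
  expect_equal(m$p_first, 0)
  expect_lt(m$p_retain_given_spliced, 0.02)  # unsmoothed 0/100
})

test_that("pattern sampling handles degenerate inputs", {
  m <- structure(list(p_first = 0, p_retain_given_spliced = 0,
                      p_retain_given_retained = 0, counts = list()),
                 class = "ir_model")
  expect_identical(sample_ir_pattern(m, 0L), logical(0))
  set.seed(52)
  expect_true(all(!replicate(200, sample_ir_pattern(m, 4))))
})

test_that("template building expands retained introns on both strands", {
  co <- ir_corpus()
  ann <- co$ref$annotation
  genome <- co$ref$genome
  for (tx in ann[1:10]) {
    n_int <- nrow(tx$introns)
    spliced <- build_template(tx, genome, rep(FALSE, n_int))
    expect_identical(spliced$seq, co$ref$transcriptome[[tx$transcript_id]])
    if (n_int >= 1L) {
      pattern <- rep(FALSE, n_int); pattern[1] <- TRUE
      one <- build_template(tx, genome, pattern)
      ilen <- unname(tx$introns[1, "end"] - tx$introns[1, "start"])
      expect_equal(nchar(one$seq), nchar(spliced$seq) + ilen)
      expect_equal(one$ir_records$length, unname(ilen))
      # all-retained: template length = transcript + all intron lengths
      full <- build_template(tx, genome, rep(TRUE, n_int))
      expect_equal(nchar(full$seq),
                   nchar(spliced$seq) + sum(tx$introns[, "end"] -
                                              tx$introns[, "start"]))
    }
  }
  expect_error(build_template(ann[[1]], c(nope = "ACGT"),
                              rep(FALSE, nrow(ann[[1]]$introns))),
               "chromosome")
})

test_that("templates reproduce the fixture generator's expanded molecules", {
  co <- ir_corpus()
  ids <- vapply(co$ref$annotation, `[[`, character(1), "transcript_id")
  checked <- 0L
  for (i in seq_along(co$rd$ir_patterns)) {
    p <- co$rd$ir_patterns[[i]]
    if (is.null(p) || !any(p)) next
    tid <- co$rd$truth$transcript_id[i]
    tx <- co$ref$annotation[[match(tid, ids)]]
    tmpl <- build_template(tx, co$ref$genome, p)
    expect_equal(nchar(tmpl$seq), co$rd$truth$mol_len[i])
    checked <- checked + 1L
    if (checked >= 50L) break
  }
  expect_gte(checked, 20L)
})
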