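test_that("compatibility keeps alignments within the score fraction of the best", {
  a1 <- aln("r1", "A", wk(M = 100), score = 100)
  expect_equal(build_compatibility(list(a1))$reads[["r1"]], "A")
  a2 <- aln("r1", "B", wk(M = 75), score = 75, is_primary = FALSE)
  cm <- build_compatibility(list(a1, a2), min_score_frac = 0.8)
  expect_equal(cm$reads[["r1"]], "A")  # 75 < 0.8 * 100
  a3 <- aln("r1", "B", wk(M = 90), score = 90, is_primary = FALSE)
  cm2 <- build_compatibility(list(a1, a3), min_score_frac = 0.8)
  expect_setequal(cm2$reads[["r1"]], c("A", "B"))
})

test_that("reads from exons shared by two isoforms stay ambiguous", {
  # isoform B is a subset of isoform A; a read from the shared exon aligns
  # to both with equal score and must retain both transcripts
  recs <- list(
    aln("shared", "isoA", wk(M = 150), score = 150),
    aln("shared", "isoB", wk(M = 150), score = 150, is_primary = FALSE),
    aln("uniqueA", "isoA", wk(M = 200), score = 200))
  cm <- build_compatibility(recs)
  expect_setequal(cm$reads[["shared"]], c("isoA", "isoB"))
  expect_equal(cm$reads[["uniqueA"]], "isoA")
})

test_that("EM gives all abundance to the only compatible transcript", {
  p <- em_quantify(list(r1 = "t1", r2 = "t1", r3 = "t1"))
  expect_equal(p$tpm, 1e6)
  expect_equal(p$est_count, 3)
  expect_error(em_quantify(list()), "empty")
})

test_that("EM matches the brute-force likelihood oracle to 1e-6", {
  # the canonical instance: 3 unique to A, 1 unique to B, 4 shared
  reads <- c(rep(list("A"), 3), rep(list("B"), 1), rep(list(c("A", "B")), 4))
  names(reads) <- paste0("r", seq_along(reads))
  p <- em_quantify(reads, max_iter = 5000L, tol = 1e-12)
  oracle <- grid_oracle(list("A", "B", c("A", "B")), c(3, 1, 4), c("A", "B"))
  expect_equal(p$tpm[p$transcript_id == "A"] / 1e6, unname(oracle["A"]),
               tolerance = 1e-6)

  set.seed(61)
  for (case in 1:5) {
    tx <- c("A", "B", "C")
    classes <- list("A", "B", "C", c("A", "B"), c("B", "C"), c("A", "B", "C"))
    counts <- stats::rpois(6, 8) + 1
    reads <- rep(classes, counts)
    names(reads) <- paste0("x", seq_along(reads))
    p <- em_quantify(reads, max_iter = 20000L, tol = 1e-13)
    oracle <- grid_oracle(classes, counts, tx)
    est <- p$tpm[match(tx, p$transcript_id)] / 1e6
    expect_equal(unname(est), unname(oracle), tolerance = 1e-6)
  }
})

test_that("symmetric instances give exactly equal abundance", {
  reads <- c(rep(list("A"), 2), rep(list("B"), 2), rep(list(c("A", "B")), 6))
  names(reads) <- paste0("r", seq_along(reads))
  p <- em_quantify(reads)
  expect_identical(p$tpm[1], p$tpm[2])
  expect_equal(sum(p$tpm), 1e6)
})

test_that("EM log-likelihood is non-decreasing and counts are conserved", {
  set.seed(62)
  for (case in 1:5) {
    tx <- paste0("t", 1:6)
    reads <- lapply(1:200, function(i) sample(tx, sample(1:3, 1)))
    names(reads) <- paste0("r", 1:200)
    p <- em_quantify(reads)
    trace <- attr(p, "loglik_trace")
    expect_true(all(diff(trace) >= -1e-9))
    expect_equal(sum(p$est_count), 200)
    expect_equal(sum(p$tpm), 1e6, tolerance = 1e-9)
  }
})

test_that("expression R2 separates identical from permuted profiles", {
  set.seed(63)
  pa <- nanotxsim:::new_expression_profile(
    paste0("T", 1:500), rep(1, 500), numeric(500), 500)
  pa$tpm <- stats::rlnorm(500, 3, 1.5)
  pa$tpm <- pa$tpm / sum(pa$tpm) * 1e6
  expect_equal(suppressWarnings(expression_r2(pa, pa)), 1.0)
  pb <- pa
  pb$tpm <- sample(pb$tpm)
  expect_lt(expression_r2(pa, pb), 0.05)
  expect_error(expression_r2(pa[1:2, ], pa[1:2, ]), "fewer than 3")
})

test_that("user expression files are validated and renormalized", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\ttpm", "t1\t600000", "t2\t400000"), f)
  p <- load_user_expression(f)
  expect_equal(p$tpm, c(600000, 400000))

  writeLines(c("transcript_id\ttpm", "t1\t3", "t2\t1"), f)
  p2 <- load_user_expression(f)
  expect_equal(p2$tpm, c(750000, 250000))

  writeLines(c("transcript_id\ttpm", "t1\t3", "ghost\t1"), f)
  expect_warning(p3 <- load_user_expression(f, reference_ids = c("t1", "t2")),
                 "dropped")
  expect_equal(p3$tpm, 1e6)

  writeLines(c("transcript_id\ttpm", "t1\t-3"), f)
  expect_error(load_user_expression(f), "negative")
  writeLines("transcript_id\ttpm", f)
  expect_error(load_user_expression(f))
})

test_that("fixture expression is recovered by quantification", {
  # a corpus deep enough that every transcript carries informative counts
  set.seed(64)
  spec <- fixture_spec(n_genes = 60L, expr_sdlog = 0.8,
                       unaligned_fraction = 0)
  ref <- make_reference(spec)
  rd <- make_reads_with_truth(spec, ref, 6000)
  est <- em_quantify(build_compatibility(rd$transcriptome_alignments))
  true_prof <- nanotxsim:::new_expression_profile(
    names(ref$tpm), rep(NA_real_, length(ref$tpm)),
    unname(ref$tpm), NA_real_)
  expect_gt(expression_r2(true_prof, est), 0.9)
})
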