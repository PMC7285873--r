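# Shared synthetic corpora, built once per test run and cached.

corpus_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(corpus_cache[[key]])) corpus_cache[[key]] <- builder()
  corpus_cache[[key]]
}

# Standard errorful training corpus: mixed strands, 5/3/3% error rates.
std_corpus <- function() cached("std", function() {
  set.seed(101)
  spec <- fixture_spec(n_genes = 40, minus_strand_prob = 0.3)
  ref <- make_reference(spec)
  rd <- make_reads_with_truth(spec, ref, 1500)
  prof <- characterize(rd$transcriptome_alignments,
                       transcriptome = ref$transcriptome,
                       unaligned_lengths = rd$unaligned_lengths)
  list(spec = spec, ref = ref, rd = rd, prof = prof)
})

# Error-free IR corpus over its own reference (full-length reads).
ir_corpus <- function() cached("ir", function() {
  set.seed(102)
  spec <- fixture_spec(n_genes = 40, minus_strand_prob = 0.4,
                       mis_rate = 0, ins_rate = 0, del_rate = 0,
                       ir_chain = c(0.05, 0.02, 0.6), ratio_shape = NULL,
                       unaligned_fraction = 0)
  ref <- make_reference(spec)
  rd <- make_reads_with_truth(spec, ref, 4000)
  list(spec = spec, ref = ref, rd = rd)
})

# Homopolymer corpus: plus-strand genes with planted runs, hp-only reads.
hp_corpus <- function() cached("hp", function() {
  set.seed(103)
  spec <- fixture_spec(n_genes = 40, minus_strand_prob = 0,
                       plant_homopolymers = TRUE,
                       mis_rate = 0, ins_rate = 0, del_rate = 0,
                       unaligned_fraction = 0)
  ref <- make_reference(spec)
  reads <- make_hp_reads(spec, ref, 1500)
  list(spec = spec, ref = ref, reads = reads)
})

# Simulate from a profile stripped of the homopolymer model, so the truth
# rows define exact transcript-space alignments (truth_to_alignments).
hpless_sim <- function(co, n, seed, ...) {
  prof <- co$prof
  prof$homopolymer_model <- NULL
  simulate_reads(prof, co$ref$transcriptome, n, seed = seed, ...)
}

# One-gene annotation with a single intron, for hand-built IR cases:
# exon [0,100), intron [100, 100+intron_len), exon [.,.+100) on chr1.
one_intron_annotation <- function(intron_len = 500L, strand = "+") {
  df <- data.frame(
    transcript_id = "tx1", gene_id = "g1", chrom = "chr1", strand = strand,
    start = c(0L, 100L + intron_len), end = c(100L, 200L + intron_len),
    stringsAsFactors = FALSE)
  nanotxsim:::build_annotation(df)
}

# Minimal alignment-record constructor for hand-built cases.
aln <- function(qid, tid, walk, target_start = 0L, strand = "+",
                query_length = NULL, query_start = 0L, kind = "transcriptome",
                is_primary = TRUE, score = NA_real_) {
  qlen_core <- nanotxsim:::walk_query_len(walk)
  if (is.null(query_length)) query_length <- query_start + qlen_core
  nanotxsim:::new_alignment(
    query_id = qid, query_length = query_length, target_id = tid,
    target_kind = kind, strand = strand, query_start = query_start,
    query_end = query_start + qlen_core, target_start = target_start,
    target_end = target_start + nanotxsim:::walk_target_len(walk),
    walk = walk, is_primary = is_primary, score = score)
}

wk <- function(...) {
  v <- c(...)
  ops <- c("M" = 1L, "X" = 2L, "I" = 3L, "D" = 4L, "N" = 5L)
  nanotxsim:::make_walk(ops[names(v)], unname(v))
}
# Brute-force likelihood oracle for <= 3 transcripts: iteratively refined
# grid search over the abundance simplex, independent of the EM code path.
grid_oracle <- function(classes, counts, tx) {
  K <- length(tx)
  ll <- function(tau) {
    sum(counts * log(vapply(classes, function(cl) {
      sum(tau[match(cl, tx)])
    }, numeric(1))))
  }
  if (K == 1L) return(stats::setNames(1, tx))
  lo <- rep(1e-9, K - 1L); hi <- rep(1 - 1e-9, K - 1L)
  for (round in 1:6) {
    gr <- lapply(seq_len(K - 1L), function(k) seq(lo[k], hi[k], length.out = 40))
    grid <- as.matrix(expand.grid(gr))
    ok <- rowSums(grid) < 1
    grid <- grid[ok, , drop = FALSE]
    vals <- apply(grid, 1, function(g) ll(c(g, 1 - sum(g))))
    best <- grid[which.max(vals), ]
    step <- vapply(gr, function(g) diff(g[1:2]), numeric(1))
    lo <- pmax(1e-9, best - step); hi <- pmin(1 - 1e-9, best + step)
  }
  stats::setNames(c(best, 1 - sum(best)), tx)
}

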