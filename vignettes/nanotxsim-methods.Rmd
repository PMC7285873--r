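---
title: "Models and design of the nanotxsim read simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the nanotxsim read simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nanotxsim` is a two-stage simulator for Oxford Nanopore transcriptome
reads: a characterization stage learns statistical models from alignments
of training reads, and a simulation stage draws reads from a reference
transcriptome under those models, with complete per-read ground truth.
This vignette describes each model, its assumptions and tunable
parameters, the synthetic corpus generator used for validation, and the
design choices made where the methodology left the details open.

## Read anatomy and the length model

A nanopore transcriptome read is modelled as
`[head flank][aligned core][tail flank]`, where the core derives from a
contiguous slice of the source molecule and the flanks are unalignable
sequence (adapter remnants, low-quality ends). Because library preparation
and pore dwell artefacts truncate molecules in a length-dependent way, the
core is modelled *relative* to the source: the aligned ratio
r = (aligned span)/(molecule length), r in (0, 1].

The joint law of (log10 molecule length, r) is a 2-D Gaussian KDE over the
training pairs with a diagonal Scott's-rule bandwidth matrix
(sd * n^(-1/6) per dimension). We store the training points themselves and
sample by smoothed bootstrap: to draw r conditional on a molecule length
L, training points are resampled with Gaussian kernel weights in the
length dimension and jittered in the ratio dimension. Marginalized over
the training set this reproduces the fitted joint exactly, costs O(1) per
draw after caching the weight vectors on a fine grid (resolution
bandwidth/20, far below the kernel scale), and avoids the grid-inversion
machinery a conditional-CDF approach would need. Draws are rejected until
r in (0, 1] and the rounded aligned length is >= 1; after 1000 fruitless
rounds (pathological only) sampling falls back to empirical resampling
with a warning. Ratios above 1 in training (alignment artefacts) are
clipped to 1 with a warning: a read cannot be longer than its source
molecule.

Flank lengths are heavy-tailed and non-negative, so their joint KDE lives
on the log1p scale; unaligned-read lengths on the log10 scale. Fitting
refuses training sets of fewer than 30 aligned reads.

Where the aligned slice sits on the molecule is not identifiable from the
ratio alone. The default is 3'-anchored (`start_mode = "anchor3"`),
reflecting direct-RNA chemistry, which sequences from the 3' end and
truncates 5'; `"uniform"` is available for cDNA-like libraries. This is a
modelling assumption, not a fitted quantity.

The strand ratio — the fraction of reads in the annotated sense
orientation — is the binomial proportion of `+`-strand primary
transcriptome alignments. Antisense reads are produced by
reverse-complementing the finished sense read, so all ground-truth
coordinates live in sense/template space with an orientation flag: one
coordinate system, one source of truth.

## The base-call error model

An aligned read is an alternating sequence of match stretches and error
events (runs of mismatch, insertion or deletion). Four components:

* **Rates** per aligned reference base (mismatch, insertion, deletion),
  computed from the edit walks of primary alignments; unaligned reads are
  excluded.
* **Error lengths**: mismatch run lengths follow a
  zero-truncated-Poisson/Geometric mixture; insertion and deletion lengths
  Weibull/Geometric mixtures. The continuous Weibull is discretized onto
  {1, 2, ...} by CDF differences over [l - 0.5, l + 0.5); the geometric
  lives on {1, 2, ...}. Mixtures are fit by EM on the tabulated lengths
  with 5 random restarts (best log-likelihood kept); the Weibull M-step is
  a short Nelder-Mead on log-parameters (a generalized EM step), the
  truncated-Poisson M-step solves lambda/(1 - exp(-lambda)) = mean by
  uniroot. Types with fewer than 10 events fall back to a geometric MLE;
  all-ones degenerate sets to Geometric(p = 1) with a warning.
* **Match stretches** (inter-error distances, including the zero stretch
  between abutting errors) are a KDE on the log1p scale.
* **Type sequence**: a first-order Markov chain over {mis, ins, del},
  estimated as row-normalized bigram counts of consecutive errors with
  add-one smoothing, plus an initial distribution from first-error types.
  Splice (N) operations close a segment without emitting an error, so
  transitions never span exon junctions.

Simulation alternates match-stretch draws and error draws until the
requested reference length is consumed; the final event is truncated to
fit, and consecutive insertions are merged. Substituted bases are uniform
over the three alternatives and inserted bases uniform over {A,C,G,T}:
base context is deliberately not modelled, which keeps every event
independently replayable. Mismatch runs substitute independently per base.

## Intron retention

Retention is modelled per read as a first-order Markov chain over the
transcript's ordered introns with states {spliced, retained}:
P(first retained), P(retained | previous spliced),
P(retained | previous retained). Detection uses the genome alignment of a
read whose transcript is assigned by its best transcriptome alignment: an
intron is *retained* when aligned (M/X) blocks cover at least 90% of its
span and no N operation traverses it; *spliced* when an N gap spans it;
*uncovered* (and excluded) when outside the read's genomic span. The 90%
coverage threshold tolerates a few bases of edge wobble while excluding
splice-junction overhangs; it is exposed as `min_coverage`. Uncovered
introns break transition chains rather than being imputed. Rows whose
conditioning state has fewer than 5 observations are add-one smoothed.

At simulation time the sampled pattern expands the template *before*
length sampling: a retained intron physically lengthens the molecule, so
the aligned-ratio model must see the expanded length. Minus-strand
transcripts insert the reverse-complemented genomic intron sequence, and
template identity is preserved exactly: an all-spliced pattern reproduces
the spliced transcript byte-for-byte.

## Homopolymer lengths

Base callers mis-estimate the length of single-base runs, mostly
contracting them through deletions. Per base b in {A,C,G,T}, the read-run
length given a reference run of length L is Normal(mean_b(L), sd_b(L)):
mean_b is a continuous two-segment linear regression whose integer
breakpoint is grid-searched to minimize SSE, and sd_b an ordinary
least-squares fit of per-L standard deviations, clamped at 0.1. Runs
shorter than `min_len` (default 5, exposed as `--hp-min-len`) are left to
the generic error model. Draws are rounded and clamped at 0 (a run can be
deleted entirely). Bases with fewer than 30 observations fall back to an
identity mean with SD 0.5, with a warning.

During simulation, homopolymer modification runs *before* the generic
error layout, and the modified run intervals are masked from it (the
layout is sampled over the unmasked length and forced-match segments are
spliced in at the mask positions). The elevated deletion rate inside
homopolymers is therefore carried solely by this model and never double
counted. When measuring read-side run lengths from alignments, insertions
strictly inside a run extend it; if the record carries the read sequence
only insertions of the run's base are counted, otherwise all interior
insertions are (interior insertions in real homopolymers are almost
always the run base).

## Expression quantification

Reads are assigned RSEM-style: every alignment scoring at least 0.8 of
the read's best (matching bases for PAF, AS for SAM/BAM) defines the
read's compatibility set — the aligner is expected to be run retaining
all secondaries (minimap2 `-p0`); the 0.8 cutoff then discards
secondaries too poor to be credible origins and is exposed as
`min_score_frac`. EM over equivalence classes starts from uniform
abundances and stops when no abundance moves by more than 1e-6 (cap 100
iterations); the observed-data log-likelihood is non-decreasing and the
procedure is deterministic. TPM is *count-based*: one long read is
treated as evidence for one molecule, with no effective-length divisor,
because a long read identifies its source molecule rather than sampling
it proportionally to length. This differs from short-read TPM and is the
main interpretive caveat when comparing against short-read estimates.

Profile comparison (`expression_r2`) is the R² of a least-squares fit on
log10(TPM + 1) over transcripts where either profile is non-zero.

## The synthetic corpus generator

`fixture_spec()` / `make_reference()` / `make_reads_with_truth()` generate
genomes, transcriptomes, GTF annotations and reads under fully known
parameters, together with their *exact* alignments — no aligner runs in
any test. The generator's sampling code is implementationally independent
of the simulator, so closed-loop recovery tests (characterize the
generator's reads, compare fitted against generating parameters) are
genuine cross-checks.

Defaults describe a realistic small ONT RNA-seq experiment: 2-6 exons per
gene of 100-400 nt with 80-400 nt introns; log-normal expression
(sdlog 1.2); mismatch/insertion/deletion rates of 5/3/3% with the mixture
shapes above; aligned ratio Beta(5, 2); log-normal flanks (~12 nt); 85%
sense reads; 5% unaligned reads of ~300 nt; IR chain
(0.05, 0.02, 0.6); homopolymer law mean 0.9 L, SD 0.05 L + 0.3.

Two generator-side constraints keep the truth exact:

* Fixture match stretches are >= 1 nt. If two same-type error events
  abutted, they would merge into a single run in any alignment
  representation, making the generating type chain unidentifiable — the
  merged process, not the chain, is what alignments can see. Keeping
  stretches positive makes chain recovery well-posed. (Extraction of
  zero stretches from real alignments is still implemented and tested.)
* IR corpora are error-free with full-length reads: criterion-grade IR
  recovery requires exact genomic alignments, and emulating a splice-aware
  aligner's behaviour on errorful reads would test the emulation, not the
  model. Error recovery and IR recovery therefore use separate corpora.

What the generator does not emulate: positional biases beyond the aligned
ratio, base-context-dependent errors, quality scores, adapter sequence,
poly(A) tails, and aligner noise (soft-clip jitter, mis-assignment between
paralogs). Passing closed-loop tests therefore demonstrates correct
implementation of the stated models, not that the models capture every
property of real nanopore data.

## Determinism and parallelism

Reads are generated in fixed-size blocks (default 2500) whose RNG streams
derive deterministically from the master seed and the block index; worker
processes (`n_workers`) each process whole blocks and results are merged
in block order. Output is therefore byte-identical for any worker count,
and the unaligned/aligned category of each read is a function of its
global index alone.

## Numerical choices and degenerate inputs

* KDE bandwidths: Scott's rule, floored at 1e-9; constant training sets
  get an effectively zero bandwidth and reproduce themselves.
* Layout sampling is batch-vectorized (type chains stepped across all
  pending reads at once) with an extension loop for reads that exhaust the
  initial event budget; termination is guaranteed because every iteration
  either consumes reference or is bounded by the extension cap.
* Truth coordinates: template space, 0-based half-open, with homopolymer
  rows in pre-modification slice coordinates and error rows in
  post-modification coordinates; replay applies rows right-to-left so no
  offset bookkeeping is needed.
* GTF/GFF coordinates convert to 0-based half-open at the file boundary
  and back on write; all internal coordinates share one convention.
* Plain-M CIGARs are resolved to =/X via the MD tag or a provided
  reference; without either, parsing stops and asks for `--eqx`-style
  alignment, because the match/mismatch distinction is load-bearing for
  the error model.
* Transcripts with zero exons are skipped with a warning; unsorted exons
  are sorted with a warning; empty compatibility matrices, zero-length
  sequences, and out-of-range fractions in stored profiles are errors.

## Validation scale

The test suite validates each model by parameter recovery at sizes chosen
to give clear statistical resolution on a single CPU: error rates and
mixtures from 1e4 reads (~1e6 aligned bases, rates recovered to ±0.3
percentage points, mixture means to 5%, chain entries to 3 SE); the IR
chain from 2e4 full-length reads (3 SE); the expression loop from 5e4
simulated reads over 500 transcripts (log-TPM R² >= 0.95); homopolymer
regressions from ~1.4e4 observations (5% on means for L <= 20);
length/flank/unaligned laws by two-sample KS at 1e4 draws (alpha = 0.01);
ground-truth replay on 1e4 fully featured reads (100% byte-exact);
byte-identical output under 1 vs 4 workers. `scripts/acceptance.R` reruns
the same loops end-to-end and writes the recovered quantities as JSON.

## Known limitations

* Quality strings are not simulated (FASTA output only).
* No base-context (k-mer) substitution model.
* Count-based TPM only in the default path; length-normalization is a
  deliberate non-default because long reads evidence molecules, not bases.
* Per-intron identity effects (some introns intrinsically retention-prone)
  are averaged into the two-state chain.
* Homopolymer regressions extrapolate linearly beyond the training range;
  runs longer than ~20 nt are rare in training data and their simulated
  lengths are correspondingly less constrained.
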