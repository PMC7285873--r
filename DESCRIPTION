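Package: nanotxsim
Title: Characterization and Simulation of Nanopore RNA-Seq Reads
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-stage simulator for Oxford Nanopore Technologies (ONT)
    transcriptome sequencing reads. The characterization stage learns
    statistical models from alignments of real (or synthetic) nanopore
    RNA-seq reads: a two-dimensional kernel density model of read length
    relative to source transcript length, mixture models and a Markov
    chain for base-call error modes, a first-order Markov chain over
    intron retention states, per-base homopolymer length regressions,
    an expectation-maximization transcript abundance estimator, and the
    sense/antisense strand ratio. The simulation stage draws reads from
    a reference transcriptome under those models and reports complete
    per-read ground truth, sufficient to reconstruct every simulated
    read byte-exactly. Includes a deterministic synthetic-corpus
    generator so every model can be validated by closed-loop parameter
    recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    parallel,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
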