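# Small shared helpers: sequence manipulation, seed derivation, checks.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper used throughout the simulator;
#' accepts the {A,C,G,T,N} alphabet.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- chartr("ACGTN", "TGCAN", x)
  vapply(out, function(s) rawToChar(rev(charToRaw(s))), character(1),
         USE.NAMES = FALSE)
}

# Random DNA of given lengths (vectorized); one string per element of `lens`.
random_dna <- function(lens) {
  total <- sum(lens)
  if (total == 0L) return(rep("", length(lens)))
  bases <- sample(DNA_BASES, total, replace = TRUE)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  out <- character(length(lens))
  nz <- lens > 0L
  out[nz] <- vapply(which(nz), function(i) {
    paste(bases[starts[i]:ends[i]], collapse = "")
  }, character(1))
  out
}

# Deterministic derivation of sub-stream seeds from a master seed.
# Keeps results below 2^31 so they remain valid R integers.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 16807 + 12345) %% 2147483587)
}

# data.frame constructor without the checking overhead of data.frame();
# callers guarantee equal-length columns.
fast_df <- function(...) {
  x <- list(...)
  structure(x, class = "data.frame",
            row.names = .set_row_names(length(x[[1]])))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x)

# Substitute each base by one of the three alternatives, uniformly.
# `bases` is a character vector of single bases; returns same-length vector.
substitute_bases <- function(bases) {
  n <- length(bases)
  if (n == 0L) return(character(0))
  idx <- match(bases, DNA_BASES)
  idx[is.na(idx)] <- sample.int(4L, sum(is.na(idx)), replace = TRUE)  # N treated as random
  shift <- sample.int(3L, n, replace = TRUE)
  DNA_BASES[((idx - 1L + shift) %% 4L) + 1L]
}
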