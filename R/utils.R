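#' Random DNA sequence
#'
#' Uniform over A/C/G/T (50% GC), the neutral background used for intergenic
#' and intronic sequence in the simulator.
#'
#' @param n Length in nucleotides.
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# deterministic per-stage seed derived from a single run seed; kept < 2^31
substream_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + 9973 * stage) %% (.Machine$integer.max - 1L)) + 1L
}

# a, b, ..., z, aa, ab, ... labels for probes/segments
letter_tags <- function(n) {
  if (n <= 26) return(letters[seq_len(n)])
  first <- rep(c("", letters), each = 26)[seq_len(n)]
  paste0(first, rep(letters, length.out = n))
}

# tiny FNV-1a text hash used to stamp output files with their configuration
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "|")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-base substitution errors at a fixed rate; substitutes to a different base
mutate_bases <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit) > 0) {
    for (i in hit) {
      alt <- setdiff(c("A", "C", "G", "T"), chars[i])
      chars[i] <- alt[sample.int(3L, 1L)]
    }
  }
  paste(chars, collapse = "")
}
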