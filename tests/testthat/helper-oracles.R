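# Independent brute-force oracles. These deliberately avoid the package's DP
# kernels: scores come from exhaustive enumeration of complete alignments,
# chains from subset enumeration, window scans from direct Hamming counts.

# exhaustive optimal global alignment score under the affine convention
# (gap run of length L costs gap_open + L * gap_extend)
oracle_global_score <- function(a, b, smat, gap_open, gap_ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i > na && j > nb) {
      if (score > best) best <<- score
      return(invisible(NULL))
    }
    if (i <= na && j <= nb)
      rec(i + 1L, j + 1L, score + smat[av[i], bv[j]], 0L)
    if (i <= na) # a[i] over a gap (gap in b)
      rec(i + 1L, j, score - gap_ext - if (last == 2L) 0 else gap_open, 2L)
    if (j <= nb) # gap in a over b[j]
      rec(i, j + 1L, score - gap_ext - if (last == 1L) 0 else gap_open, 1L)
  }
  rec(1L, 1L, 0, 0L)
  best
}

# exhaustive best local block score: max over all non-empty substring pairs
oracle_local_score <- function(a, b, smat, gap_open, gap_ext) {
  na <- nchar(a); nb <- nchar(b)
  best <- 0
  for (i1 in seq_len(na)) for (i2 in i1:na) {
    sa <- substr(a, i1, i2)
    for (j1 in seq_len(nb)) for (j2 in j1:nb) {
      s <- oracle_global_score(sa, substr(b, j1, j2), smat, gap_open, gap_ext)
      if (s > best) best <- s
    }
  }
  best
}

# brute-force discriminating-window scan for gap-free equal-length pairs
oracle_discriminating_offsets <- function(seq_a, seq_b, probe_length,
                                          min_mismatches, step = 1L) {
  ca <- strsplit(seq_a, "")[[1]]
  cb <- strsplit(seq_b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  offsets <- seq(0L, length(ca) - probe_length, by = step)
  keep <- vapply(offsets, function(o) {
    idx <- (o + 1L):(o + probe_length)
    sum(ca[idx] != cb[idx]) >= min_mismatches
  }, logical(1))
  offsets[keep]
}

# exhaustive enumeration of maximal chains over a block table: every subset
# whose position-sorted blocks are pairwise-consecutively compatible, kept
# only if no compatible superset exists
oracle_maximal_chains <- function(blocks) {
  n <- nrow(blocks)
  compat <- function(i, j) { # j follows i
    if (blocks$strand[i] != blocks$strand[j]) return(FALSE)
    if (blocks$start[j] <= blocks$end[i]) return(FALSE)
    if (blocks$strand[i] == "+") blocks$exon[j] > blocks$exon[i]
    else blocks$exon[j] < blocks$exon[i]
  }
  is_chain <- function(idx) {
    idx <- idx[order(blocks$start[idx])]
    if (length(idx) <= 1) return(TRUE)
    all(vapply(seq_len(length(idx) - 1L),
               function(k) compat(idx[k], idx[k + 1L]), logical(1)))
  }
  subsets <- list()
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (is_chain(idx)) subsets[[length(subsets) + 1L]] <- sort(idx)
  }
  maximal <- Filter(function(s) {
    !any(vapply(subsets, function(t)
      length(t) > length(s) && all(s %in% t), logical(1)))
  }, subsets)
  unique(maximal)
}

# analytic expected full-containment hit count for a probe occupying
# transcript positions [s, s + plen - 1] under uniform read starts
oracle_probe_expectation <- function(s, plen, rlen, tx_len, n_reads) {
  lo <- max(1L, s + plen - rlen)
  hi <- min(tx_len - rlen + 1L, s)
  windows <- max(0L, hi - lo + 1L)
  n_reads * windows / (tx_len - rlen + 1L)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# per-site substitution at a fixed rate (test-side divergence generator)
mutate_bases_for_test <- function(seq, rate) {
  L <- nchar(seq)
  pos <- which(runif(L) < rate)
  if (length(pos) == 0) return(seq)
  substitute_at(seq, pos)
}

# substitute k positions of a sequence (guaranteed different base)
substitute_at <- function(seq, positions, alphabet = c("A", "C", "G", "T")) {
  chars <- strsplit(seq, "")[[1]]
  for (p in positions) {
    chars[p] <- sample(setdiff(alphabet, chars[p]), 1)
  }
  paste(chars, collapse = "")
}
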