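test_that("global alignment handles identity and single substitutions", {
  aln <- global_align("ACGTACGT", "ACGTACGT")
  expect_equal(aln$identities, 8L)
  expect_equal(aln$aligned_length, 8L)
  expect_false(grepl("-", aln$aligned_a, fixed = TRUE))

  aln2 <- global_align("ACGT", "ACGA")
  expect_equal(aln2$identities, 3L)
  expect_equal(aln2$aligned_length, 4L)
  expect_equal(aln2$score, 1 * 3 - 3)

  expect_error(global_align("ACGT", "MKLV"), "mixed alphabets")
  expect_error(global_align("", "ACGT"), "non-empty")
})

test_that("global aligner equals exhaustive enumeration on short pairs", {
  set.seed(55)
  sc <- scoring_scheme("dna")
  for (i in 1:40) {
    a <- random_seq(sample(1:6, 1))
    b <- random_seq(sample(1:6, 1))
    got <- global_align(a, b, sc)$score
    want <- oracle_global_score(a, b, sc$matrix, sc$gap_open, sc$gap_extend)
    expect_equal(got, want, label = paste(a, "vs", b))
  }
})

test_that("global score is symmetric and identities are exact under swap", {
  set.seed(56)
  for (i in 1:10) {
    a <- random_seq(sample(5:40, 1))
    b <- random_seq(sample(5:40, 1))
    f <- global_align(a, b)
    r <- global_align(b, a)
    expect_equal(f$score, r$score)
    expect_equal(f$identities, r$identities)
  }
})

test_that("percent identity reproduces the published rounding conventions", {
  set.seed(57)
  ref <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 193,
                      replace = TRUE), collapse = "")
  # twenty differences over 193 aligned residues: 173/193 -> 89.6
  other <- substitute_at(ref, sample(193, 20),
                         alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  idr <- percent_identity(global_align(ref, other, scoring_scheme("protein")))
  expect_equal(idr$matched_span, 193L)
  expect_equal(idr$differences, 20L)
  expect_equal(idr$percent_identity, 89.6)

  # a single substitution: 192/193 -> 99.5
  one <- substitute_at(ref, 100,
                       alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  idr1 <- percent_identity(global_align(ref, one, scoring_scheme("protein")))
  expect_equal(idr1$percent_identity, 99.5)
  expect_equal(idr1$differences, 1L)

  self <- percent_identity(global_align(ref, ref, scoring_scheme("protein")))
  expect_equal(self$percent_identity, 100)
  expect_equal(self$differences, 0L)
})

test_that("local best block finds embedded queries and respects thresholds", {
  set.seed(58)
  query <- random_seq(100)
  target <- paste0(random_seq(700), query, random_seq(700))
  r <- local_best_block(query, target)
  expect_false(r$no_match)
  expect_equal(r$percent_identity, 100)
  expect_equal(r$matched_span, 100L)
  expect_equal(substr(target, r$start_target, r$end_target), query)

  # diverged copy: identity near 85% within binomial 3 sigma
  div <- mutate_bases_for_test(query, 0.15)
  target2 <- paste0(random_seq(500), div, random_seq(500))
  r2 <- local_best_block(query, target2)
  expect_false(r2$no_match)
  sd3 <- 3 * 100 * sqrt(0.85 * 0.15 / 100)
  expect_lt(abs(r2$percent_identity - 85), sd3 + 2)
})

test_that("random query/target pairs virtually never match at the defaults", {
  set.seed(59)
  n_match <- 0L
  for (i in 1:60) {
    r <- local_best_block(random_seq(100), random_seq(2000))
    if (!r$no_match) n_match <- n_match + 1L
  }
  expect_lte(n_match, 1L)
})

test_that("local best block agrees with exhaustive substring enumeration", {
  set.seed(60)
  sc <- scoring_scheme("dna")
  for (i in 1:6) {
    a <- random_seq(6)
    b <- random_seq(sample(6:7, 1))
    got <- local_best_block(a, b, sc, min_score = 0, min_span = 0)
    want <- oracle_local_score(a, b, sc$matrix, sc$gap_open, sc$gap_extend)
    expect_equal(got$score, want, label = paste(a, "vs", b))
  }
})

test_that("exon identity table renders published cell conventions", {
  set.seed(61)
  ref <- list(exon1 = random_seq(107), exon2 = random_seq(94),
              exon3 = random_seq(124))
  species <- list(
    self = ref,
    diverged = lapply(ref, mutate_bases_for_test, rate = 0.05),
    missing = list(ref$exon1, NA, mutate_bases_for_test(ref$exon3, 0.05))
  )
  tab <- exon_identity_table(ref, species)
  expect_identical(tab$species, c("self", "diverged", "missing"))
  expect_identical(unname(unlist(tab[1, -1])), rep("100.0", 3))
  expect_identical(tab$exon2[3], "no exon")
  # diverged cells within 3 sigma of 95
  for (j in 2:4) {
    v <- as.numeric(sub(" .*", "", tab[2, j]))
    L <- nchar(ref[[j - 1]])
    expect_lt(abs(v - 95), 3 * 100 * sqrt(0.95 * 0.05 / L) + 2)
  }
})

test_that("protein identity table lists small difference sets positionally", {
  set.seed(62)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ref <- paste(sample(aa, 199, replace = TRUE), collapse = "")
  mutated <- substitute_at(ref, c(7, 42, 176, 198), alphabet = aa)
  tab <- protein_identity_table(ref, list(self = ref, anole_like = mutated))
  expect_equal(tab$percent_identity[1], 100)
  expect_equal(tab$n_differences[1], 0L)
  expect_equal(tab$percent_identity[2], 98.0)
  expect_equal(tab$n_differences[2], 4L)
  expect_match(tab$differences[2], "7>")
  expect_match(tab$differences[2], "198>")
  expect_error(protein_identity_table(ref, list(bad = "")), "empty protein")
})

test_that("difference count equals Hamming distance for gap-free alignments", {
  set.seed(63)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ref <- paste(sample(aa, 120, replace = TRUE), collapse = "")
  k <- 9
  other <- substitute_at(ref, sample(120, k), alphabet = aa)
  idr <- percent_identity(global_align(ref, other, scoring_scheme("protein")))
  hamming <- sum(strsplit(ref, "")[[1]] != strsplit(other, "")[[1]])
  expect_equal(idr$differences, hamming)
})

test_that("neighbor-joining reproduces the closed-form 3-taxon solution", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tree <- nj_guide_tree(d)
  # with 3 taxa every pair is Q-equivalent; whichever pair (i, j) is joined,
  # its branch lengths must equal the closed form (d_ij + d_ik - d_jk) / 2
  i <- tree$merges[[1]]$left[1]
  j <- tree$merges[[1]]$right[1]
  k <- setdiff(1:3, c(i, j))
  v <- unname(tree$edge_lengths[[1]])
  expect_equal(v[1], (d[i, j] + d[i, k] - d[j, k]) / 2)
  expect_equal(v[2], (d[i, j] + d[j, k] - d[i, k]) / 2)
})

test_that("NJ join order matches ape::nj topology on random matrices", {
  set.seed(64)
  n <- 6
  pts <- matrix(runif(n * 4), n)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
  tree <- nj_guide_tree(d)
  ape_tree <- ape::nj(as.dist(d))
  ape_splits <- ape::prop.part(ape_tree)
  labs <- attr(ape_splits, "labels")
  ape_sets <- lapply(ape_splits, function(s) sort(labs[s]))
  # every internal cluster our joins produce must be an ape bipartition side
  for (k in seq_len(length(tree$merges) - 1)) {
    members <- sort(unlist(tree$merges[[k]][c("left", "right")]))
    clust <- sort(rownames(d)[members])
    comp <- sort(setdiff(rownames(d), clust))
    ok <- any(vapply(ape_sets, function(s)
      identical(s, clust) || identical(s, comp), logical(1)))
    expect_true(ok, label = paste("cluster", paste(clust, collapse = ",")))
  }
})

test_that("progressive MSA reduces to pairwise and respects construction", {
  set.seed(65)
  a <- random_seq(40); b <- random_seq(40)
  two <- progressive_msa(c(s1 = a, s2 = b))
  ref <- global_align(a, b)
  expect_identical(unname(two["s1"]), ref$aligned_a)
  expect_identical(unname(two["s2"]), ref$aligned_b)

  # identical sequences: gap-free block
  same <- progressive_msa(setNames(rep(a, 4), paste0("s", 1:4)))
  expect_false(any(grepl("-", same, fixed = TRUE)))
  expect_equal(unique(nchar(same)), 40L)

  # single sequence returned unchanged
  one <- progressive_msa(c(only = a))
  expect_identical(unname(one), a)

  # planted single deletion among five related sequences is recovered as
  # one contiguous gap run in that row
  base <- random_seq(80)
  fam <- c(f1 = base,
           f2 = mutate_bases_for_test(base, 0.02),
           f3 = mutate_bases_for_test(base, 0.02),
           f4 = paste0(substr(base, 1, 39), substr(base, 50, 80)),
           f5 = mutate_bases_for_test(base, 0.02))
  msa <- progressive_msa(fam)
  expect_equal(length(unique(nchar(msa))), 1L)
  gaps <- gregexpr("-+", msa["f4"])[[1]]
  expect_equal(length(gaps), 1L)
  expect_equal(attr(gaps, "match.length"), 10L)
  # de-gapping recovers the inputs
  expect_identical(unname(gsub("-", "", msa["f4"], fixed = TRUE)),
                   unname(fam["f4"]))
  expect_false(any(grepl("-", msa[c("f1", "f2", "f3", "f5")], fixed = TRUE)))
})

test_that("global scores agree with an independent aligner implementation", {
  set.seed(66)
  sc <- scoring_scheme("dna")
  mat <- sc$matrix[1:4, 1:4] # ACGT only
  for (i in 1:20) {
    a <- random_seq(sample(20:60, 1))
    b <- random_seq(sample(20:60, 1))
    got <- global_align(a, b, sc)$score
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = mat,
      gapOpening = sc$gap_open, gapExtension = sc$gap_extend,
      scoreOnly = TRUE)
    expect_equal(got, ref, label = paste(a, "vs", b))
  }
})
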