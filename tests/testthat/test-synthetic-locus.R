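test_that("simulated gene embeds the configured structure", {
  cfg <- zebrafish_like_config(seed = 11)
  sim <- simulate_gene(cfg)
  truth <- sim$truth
  ml <- model_lengths(truth$gene_model)
  expect_equal(ml$gene_length, 6404L)
  expect_equal(ml$mrna_length, 1114L)
  expect_equal(ml$cds_length, 597L)
  expect_equal(nchar(sim$genome), cfg$chromosome_length)

  # spliced transcript equals the concatenated exons and the stored truth
  tx <- splice_transcript(sim$genome, truth$gene_model)
  expect_identical(tx, truth$transcripts[[1]])
  expect_identical(tx, paste(truth$exon_sequences, collapse = ""))
  expect_equal(nchar(tx), sum(cfg$exon_lengths))

  # introns are GT..AG
  coords <- truth$exon_coordinates
  for (i in seq_len(nrow(coords) - 1)) {
    intron <- substr(sim$genome, coords$end[i] + 1, coords$start[i + 1] - 1)
    expect_identical(substr(intron, 1, 2), "GT")
    expect_identical(substr(intron, nchar(intron) - 1, nchar(intron)), "AG")
  }

  # CDS starts with ATG, ends with a stop, no internal stop
  cds <- substr(tx, cfg$utr5_length + 1, cfg$utr5_length + ml$cds_length)
  prot <- translate_cds(cds)
  expect_equal(prot$length, 198L)

  # planted hexamer sits cleavage_offset nt upstream of the cleavage site
  hex <- substr(sim$genome, truth$hexamer_position, truth$hexamer_position + 5)
  expect_identical(hex, cfg$polya_hexamer)
  expect_equal(truth$cleavage_position - (truth$hexamer_position + 5L),
               cfg$cleavage_offset)
})

test_that("single-exon degenerate gene reduces to its exon", {
  cfg <- simulation_config(seed = 3, exon_lengths = 99L,
                           intron_lengths = integer(0),
                           utr5_length = 18L, utr3_length = 30L,
                           cleavage_offset = 10L, n_reads = 50L,
                           read_length = 50L)
  sim <- simulate_gene(cfg)
  ml <- model_lengths(sim$truth$gene_model)
  expect_equal(ml$gene_length, 99L)
  expect_equal(ml$mrna_length, 99L)
  expect_identical(splice_transcript(sim$genome, sim$truth$gene_model),
                   sim$truth$transcripts[[1]])
})

test_that("a fixed seed reproduces genome, truth and reads bit-identically", {
  cfg <- zebrafish_like_config(seed = 21)
  a <- simulate_gene(cfg)
  b <- simulate_gene(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth$exon_coordinates, b$truth$exon_coordinates)
  ra <- simulate_reads(a$genome, a$truth, cfg)
  rb <- simulate_reads(b$genome, b$truth, cfg)
  expect_identical(ra$sequence, rb$sequence)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(exon_lengths = c(100, 200),
                                 intron_lengths = c(50, 60)),
               "intron count")
  expect_error(simulation_config(error_rate = 1.5), "error_rate")
  expect_error(simulation_config(isoform_weights = c(0.5, 0.4)),
               "sum to 1")
  # CDS not a multiple of 3 after UTR partition
  expect_error(simulation_config(utr5_length = 17), "multiple of 3")
})

test_that("error-free single-isoform reads are exact transcript substrings", {
  cfg <- zebrafish_like_config(seed = 5, error_rate = 0,
                               polya_tail_rate = 0, n_reads = 200L)
  sim <- simulate_gene(cfg)
  reads <- simulate_reads(sim$genome, sim$truth, cfg)
  tx <- sim$truth$transcripts[[1]]
  ok <- vapply(seq_len(nrow(reads)), function(i) {
    substr(tx, reads$start[i], reads$start[i] + cfg$read_length - 1L) ==
      reads$sequence[i]
  }, logical(1))
  expect_true(all(ok))
})

test_that("isoform weight zero yields no reads from that isoform", {
  cfg <- zebrafish_like_config(seed = 9, isoform_weights = c(1, 0),
                               isoform_exon_sets = list(1:6, c(1:4, 6)),
                               n_reads = 300L)
  sim <- simulate_gene(cfg)
  reads <- simulate_reads(sim$genome, sim$truth, cfg)
  expect_true(all(reads$isoform == 1L))
})

test_that("read errors converge to the configured per-base rate", {
  cfg <- zebrafish_like_config(seed = 13, error_rate = 0.01,
                               polya_tail_rate = 0, five_prime_decay = 0,
                               n_reads = 2000L)
  sim <- simulate_gene(cfg)
  reads <- simulate_reads(sim$genome, sim$truth, cfg)
  tx <- sim$truth$transcripts[[1]]
  mism <- vapply(seq_len(nrow(reads)), function(i) {
    ref <- substr(tx, reads$start[i], reads$start[i] + cfg$read_length - 1L)
    sum(strsplit(ref, "")[[1]] != strsplit(reads$sequence[i], "")[[1]])
  }, numeric(1))
  n_bases <- nrow(reads) * cfg$read_length
  expected <- n_bases * cfg$error_rate
  sd3 <- 3 * sqrt(n_bases * cfg$error_rate * (1 - cfg$error_rate))
  expect_lt(abs(sum(mism) - expected), sd3)
})

test_that("tailed reads span the cleavage junction with a >= 5 nt A-run", {
  cfg <- zebrafish_like_config(seed = 17, error_rate = 0,
                               polya_tail_rate = 0.4, n_reads = 400L)
  sim <- simulate_gene(cfg)
  reads <- simulate_reads(sim$genome, sim$truth, cfg)
  tailed <- reads[reads$tail_length > 0, ]
  expect_gt(nrow(tailed), 0)
  expect_true(all(tailed$tail_length >= 5))
  tx_len <- nchar(sim$truth$transcripts[[1]])
  core_end <- tailed$start + (cfg$read_length - tailed$tail_length) - 1L
  expect_true(all(core_end == tx_len))
  # observed tailed fraction near the configured rate
  expect_lt(abs(mean(reads$tail_length > 0) - cfg$polya_tail_rate), 0.1)
})

test_that("read_length longer than the shortest isoform errors", {
  cfg <- zebrafish_like_config(seed = 2, read_length = 2000L)
  sim <- simulate_gene(cfg)
  expect_error(simulate_reads(sim$genome, sim$truth, cfg), "shortest isoform")
})

test_that("retrocopy planting inserts the transcript intact and shifts truth", {
  cfg <- zebrafish_like_config(seed = 31)
  sim <- simulate_gene(cfg)
  tx <- sim$truth$transcripts[[1]]
  ins <- sim$truth$cleavage_position + 2000L

  # divergence zero: inserted copy identical to the transcript
  p0 <- plant_retrocopy(sim$genome, sim$truth, divergence = 0,
                        insertion_point = ins)
  expect_identical(substr(p0$genome, p0$truth$retrocopy_span[1],
                          p0$truth$retrocopy_span[2]), tx)
  expect_equal(nchar(p0$genome), nchar(sim$genome) + nchar(tx))
  # parent coordinates unchanged for an insertion downstream of the gene
  expect_equal(p0$truth$tss_position, sim$truth$tss_position)

  # insertion upstream shifts parent coordinates by the copy length
  up <- plant_retrocopy(sim$genome, sim$truth, divergence = 0,
                        insertion_point = 100L)
  expect_equal(up$truth$tss_position, sim$truth$tss_position + nchar(tx))
  expect_identical(splice_transcript(up$genome, up$truth$gene_model), tx)

  # divergence 0.1: substitutions within binomial 3 sigma of 0.1 * L
  p1 <- plant_retrocopy(sim$genome, sim$truth, divergence = 0.1,
                        insertion_point = ins)
  copy <- substr(p1$genome, p1$truth$retrocopy_span[1],
                 p1$truth$retrocopy_span[2])
  nsub <- sum(strsplit(copy, "")[[1]] != strsplit(tx, "")[[1]])
  L <- nchar(tx)
  expect_lt(abs(nsub - 0.1 * L), 3 * sqrt(L * 0.1 * 0.9))

  # insertion inside the parent span is rejected
  expect_error(plant_retrocopy(sim$genome, sim$truth, 0,
                               sim$truth$tss_position + 10L),
               "inside the parent gene")
})

test_that("simulated neighborhood preserves configured order and orientation", {
  cfg <- zebrafish_like_config(seed = 41)
  nb <- simulate_neighborhood(cfg)
  expect_identical(nb$locus_map$genes$name, c("Ik", "Hars", "Hars2", "Zmat2"))
  expect_identical(nb$locus_map$genes$strand, c("+", "-", "-", "+"))
  expect_true(all(diff(nb$locus_map$genes$start) > 0))
  expect_equal(nchar(nb$genome), cfg$chromosome_length)

  # empty neighbor list errors
  cfg2 <- cfg
  cfg2$neighbor_genes <- cfg$neighbor_genes[0, ]
  expect_error(simulate_neighborhood(cfg2), "non-empty")

  # strand flip changes exactly one gene's orientation
  cfg3 <- zebrafish_like_config(seed = 41)
  cfg3$neighbor_genes$strand[3] <- "+"
  nb3 <- simulate_neighborhood(cfg3)
  expect_identical(nb3$locus_map$genes$name, nb$locus_map$genes$name)
  expect_identical(which(nb3$locus_map$genes$strand !=
                           nb$locus_map$genes$strand), 3L)

  # over-long request errors
  cfg4 <- cfg
  cfg4$neighbor_genes$length <- rep(8000L, 4)
  expect_error(simulate_neighborhood(cfg4), "exceed")
})
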