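test_that("count_probe_hits counts containment with bounded mismatches", {
  set.seed(11)
  probe <- random_seq(60)
  flank <- function() random_seq(20)
  exact <- vapply(1:10, function(i) paste0(flank(), probe, flank()),
                  character(1))
  prof <- count_probe_hits(data.frame(id = "p1", tag = "a", sequence = probe,
                                      stringsAsFactors = FALSE), exact)
  expect_equal(prof$hit_count, 10L)

  # three mismatches exceed the default tolerance of two
  bad <- substitute_at(probe, c(10, 30, 50))
  prof_bad <- count_probe_hits(probe, paste0(flank(), bad, flank()))
  expect_equal(prof_bad$hit_count, 0L)
  two <- substitute_at(probe, c(10, 30))
  prof_two <- count_probe_hits(probe, paste0(flank(), two, flank()))
  expect_equal(prof_two$hit_count, 1L)

  # reverse-complement containment counts too
  prof_rc <- count_probe_hits(probe, revcomp(paste0(flank(), probe, flank())))
  expect_equal(prof_rc$hit_count, 1L)

  expect_warning(zero <- count_probe_hits(probe, character(0)), "empty read")
  expect_equal(zero$hit_count, 0L)
})

test_that("hit counts are monotone non-increasing in mismatch stringency", {
  cfg <- zebrafish_like_config(seed = 23, error_rate = 0.01,
                               polya_tail_rate = 0, n_reads = 400L)
  sim <- simulate_gene(cfg)
  reads <- simulate_reads(sim$genome, sim$truth, cfg)
  probes <- tile_probes(sim$truth$transcripts[[1]], 60)
  h2 <- count_probe_hits(probes, reads, max_mismatches = 2)$hit_count
  h1 <- count_probe_hits(probes, reads, max_mismatches = 1)$hit_count
  h0 <- count_probe_hits(probes, reads, max_mismatches = 0)$hit_count
  expect_true(all(h1 <= h2))
  expect_true(all(h0 <= h1))
})

test_that("tiled-probe hit counts follow the analytic coverage expectation", {
  cfg <- zebrafish_like_config(seed = 29, error_rate = 0, polya_tail_rate = 0,
                               five_prime_decay = 0, n_reads = 10000L)
  sim <- simulate_gene(cfg)
  reads <- simulate_reads(sim$genome, sim$truth, cfg)
  tx <- sim$truth$transcripts[[1]]
  probes <- tile_probes(tx, 60)
  prof <- count_probe_hits(probes, reads)
  for (i in seq_len(nrow(probes))) {
    expected <- oracle_probe_expectation(probes$offset[i] + 1L, 60L,
                                         cfg$read_length, nchar(tx),
                                         cfg$n_reads)
    expect_lt(abs(prof$hit_count[i] - expected),
              3 * sqrt(expected) + 1e-9,
              label = sprintf("probe %d: obs %d vs exp %.1f",
                              i, prof$hit_count[i], expected))
  }
})

test_that("call_five_prime applies the longest-clone rule", {
  set.seed(31)
  region <- random_seq(200)
  reads <- substring(region, c(10, 5, 23), c(10, 5, 23) + 59)
  bc <- call_five_prime(region, reads, atg_position = 40)
  expect_equal(bc$position, 5L)
  expect_equal(bc$support_reads, 1L)
  expect_identical(bc$confidence, "low")     # single-read support
  expect_identical(bc$method, "longest-clone")
  expect_equal(bc$utr_length, 35L)

  two <- c(reads, substr(region, 5, 64))
  bc2 <- call_five_prime(region, two)
  expect_identical(bc2$confidence, "normal")

  expect_error(call_five_prime(region, character(0)), "no expression evidence")
  expect_error(call_five_prime(region, random_seq(60)),
               "no expression evidence")
})

test_that("5' recovery is within 2 nt of truth at mapping depth", {
  for (seed in c(101, 102, 103)) {
    r <- recover_ends(zebrafish_like_config(seed))
    expect_lte(abs(r$utr5 - 18L), 2L)
  }
  r <- recover_ends(chicken_like_config(104))
  expect_lte(abs(r$utr5 - 89L), 2L)
})

test_that("scan_polya_signals finds accepted hexamers in order", {
  seq1 <- paste0(strrep("C", 20), "AATAAA", strrep("G", 20))
  hits <- scan_polya_signals(seq1)
  expect_equal(nrow(hits), 1L)
  expect_identical(hits$hexamer, "AATAAA")
  expect_equal(hits$start, 21L)

  # chicken-style variant signal is in the accepted set
  seq2 <- paste0(strrep("C", 10), "ATTTTA", strrep("C", 10))
  expect_identical(scan_polya_signals(seq2)$hexamer, "ATTTTA")

  # poly-purine window with no accepted hexamer
  expect_equal(nrow(scan_polya_signals(strrep("GA", 30))), 0L)

  # multiple signals reported 5' to 3'
  seq3 <- paste0("ATTAAA", strrep("C", 30), "AATAAA", strrep("C", 10))
  multi <- scan_polya_signals(seq3)
  expect_identical(multi$hexamer, c("ATTAAA", "AATAAA"))
  expect_true(all(diff(multi$start) > 0))

  expect_error(scan_polya_signals("ACGT", window = c(1, 10)), "window")
})

test_that("call_three_prime recovers planted cleavage offsets exactly", {
  r12 <- recover_ends(zebrafish_like_config(201))
  expect_identical(r12$cleavage_method, "polyA-site")
  expect_equal(r12$cleavage, r12$cleavage_truth)
  expect_equal(r12$offset, 12L)
  expect_identical(r12$hexamer, "ATTAAA")

  r8 <- recover_ends(chicken_like_config(202))
  expect_equal(r8$cleavage, r8$cleavage_truth)
  expect_equal(r8$offset, 8L)
  expect_identical(r8$hexamer, "ATTTTA")
})

test_that("without tailed reads the 3' call degrades to coverage terminus", {
  r <- recover_ends(zebrafish_like_config(203, polya_tail_rate = 0,
                                          five_prime_decay = 0))
  expect_identical(r$cleavage_method, "coverage-terminus")
  expect_lte(r$cleavage, r$cleavage_truth)
})

test_that("exon_usage supports exactly the expressed exons", {
  # single isoform lacking exon 5: exon 5 unsupported, all others supported
  cfg <- zebrafish_like_config(301, error_rate = 0, polya_tail_rate = 0,
                               five_prime_decay = 0, n_reads = 800L,
                               isoform_weights = 1,
                               isoform_exon_sets = list(c(1, 2, 3, 4, 6)))
  sim <- simulate_gene(cfg)
  reads <- simulate_reads(sim$genome, sim$truth, cfg)
  usage <- exon_usage(sim$truth$gene_model, reads,
                      transcript = paste(sim$truth$exon_sequences,
                                         collapse = ""))
  expect_identical(usage$exons$supported, c(rep(TRUE, 4), FALSE, TRUE))
  # junctions flanking exon 5 carry no support
  expect_equal(usage$junctions$junction_support[4], 0L)
  expect_equal(usage$junctions$junction_support[5], 0L)
  expect_gt(usage$junctions$junction_support[1], 0L)

  # frog-style mixture: all configured exons supported
  cfg2 <- zebrafish_like_config(302, error_rate = 0, polya_tail_rate = 0,
                                five_prime_decay = 0, n_reads = 900L,
                                isoform_weights = c(0.5, 0.3, 0.2),
                                isoform_exon_sets = list(1:6, c(1:4, 6),
                                                         c(1, 2, 3, 6)))
  sim2 <- simulate_gene(cfg2)
  reads2 <- simulate_reads(sim2$genome, sim2$truth, cfg2)
  usage2 <- exon_usage(sim2$truth$gene_model, reads2,
                       transcript = paste(sim2$truth$exon_sequences,
                                          collapse = ""))
  expect_true(all(usage2$exons$supported))
})

test_that("paralog_expression_ratio computes percent means", {
  p1 <- structure(data.frame(probe_id = "a", tag = "a", hit_count = 200L),
                  class = c("hit_profile", "data.frame"))
  p2 <- structure(data.frame(probe_id = "a", tag = "a", hit_count = 5L),
                  class = c("hit_profile", "data.frame"))
  expect_equal(paralog_expression_ratio(p1, p2), 2.5)
  expect_equal(paralog_expression_ratio(p1, p1), 100)
  zero <- p2; zero$hit_count <- 0L
  expect_warning(r <- paralog_expression_ratio(zero, p1), "undefined")
  expect_true(is.na(r))
  expect_error(paralog_expression_ratio(p1, rbind(p2, p2)), "equal numbers")
})

test_that("paralog abundance is recovered from discriminating probes", {
  cfg <- zebrafish_like_config(401, error_rate = 0.001, polya_tail_rate = 0,
                               five_prime_decay = 0, n_reads = 20000L)
  sim <- simulate_gene(cfg)
  set.seed(4011)
  tx1 <- sim$truth$transcripts[[1]]
  tx2 <- mutate_bases_for_test(tx1, 0.10)
  reads <- simulate_reads(sim$genome, sim$truth, cfg,
                          transcripts = c(tx1, tx2), weights = c(0.8, 0.2))
  # discriminating windows from exon 2 of each paralog
  e2 <- c(37L, 127L) # transcript coordinates of exon 2 (36 + 91)
  exon2_a <- substr(tx1, e2[1], e2[2])
  exon2_b <- substr(tx2, e2[1], e2[2])
  dp <- discriminating_probes(exon2_a, exon2_b, probe_length = 60,
                              min_mismatches = 3)
  expect_gt(nrow(dp), 0)
  probes_b <- substring(exon2_b, dp$offset + 1L, dp$offset + 60L)
  prof_a <- count_probe_hits(dp$sequence, reads)
  prof_b <- count_probe_hits(probes_b, reads)
  ratio <- paralog_expression_ratio(prof_a, prof_b)
  # binomial 3 sigma on the two mean counts (delta method)
  m1 <- mean(prof_a$hit_count); m2 <- mean(prof_b$hit_count)
  # overlapping step-1 windows are near-fully correlated: use a single
  # window's binomial sigma
  sd3 <- 3 * 100 * (m2 / m1) * sqrt(1 / m2 + 1 / m1)
  expect_lt(abs(ratio - 25), max(sd3, 2))
})
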