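# Shared simulation conditions. The zebrafish-like default gene comes from
# simulation_config(); the chicken-like variant plants an ATTTTA signal with
# an 8-nt cleavage offset. End-mapping libraries are 600 reads (~50x) with a
# 5'-informative start distribution (decay 0.02/nt).

config_with <- function(base, seed, ...) {
  args <- c(list(seed = seed), list(...))
  for (nm in names(base)) if (!nm %in% names(args)) args[[nm]] <- base[[nm]]
  do.call(simulation_config, args)
}

zebrafish_like_config <- function(seed, ...) {
  config_with(list(n_reads = 600L, five_prime_decay = 0.02), seed, ...)
}

chicken_like_config <- function(seed, ...) {
  config_with(list(
    exon_lengths = c(107L, 94L, 124L, 74L, 146L, 1903L),
    intron_lengths = c(2807L, 558L, 1345L, 2338L, 1532L),
    utr5_length = 89L, utr3_length = 1759L,
    polya_hexamer = "ATTTTA", cleavage_offset = 8L,
    n_reads = 600L, five_prime_decay = 0.02), seed, ...)
}

# simulate a gene + library and call both ends; returns recovered quantities
recover_ends <- function(cfg) {
  sim <- simulate_gene(cfg)
  reads <- simulate_reads(sim$genome, sim$truth, cfg)
  coords <- sim$truth$exon_coordinates
  n <- nrow(coords)
  flank <- 200L
  r5_start <- max(1L, coords$start[1] - flank)
  region5 <- substr(sim$genome, r5_start, coords$end[1])
  atg <- coords$start[1] - r5_start + 1L + cfg$utr5_length
  bc5 <- call_five_prime(region5, reads, atg_position = atg)
  region3 <- substr(sim$genome, coords$start[n], coords$end[n])
  down <- substr(sim$genome, coords$end[n] + 1L,
                 min(nchar(sim$genome), coords$end[n] + 60L))
  c3 <- call_three_prime(region3, reads, downstream = down)
  true_cleavage_region <- coords$end[n] - coords$start[n] + 1L
  list(utr5 = bc5$utr_length,
       five_confidence = bc5$confidence,
       cleavage = c3$boundary$position,
       cleavage_truth = true_cleavage_region,
       cleavage_method = c3$boundary$method,
       offset = if (!is.null(c3$polya)) c3$polya$offset else NA_integer_,
       hexamer = if (!is.null(c3$polya)) c3$polya$hexamer else NA_character_)
}
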