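#' Accepted poly(A) signal hexamers
#'
#' The canonical AATAAA plus the two variants observed at the study loci
#' (ATTAAA, ATTTTA). Extensible wherever a `hexamers` argument is taken.
#' @export
POLYA_HEXAMERS <- c("AATAAA", "ATTAAA", "ATTTTA")

#' Simulation configuration
#'
#' Parameters of the synthetic locus and read generator. Defaults emulate the
#' zebrafish-like study gene: 6 exons of 36/91/124/74/146/643 nt, introns of
#' 978/503/85/1040/2684 nt, an 18-nt 5' UTR and 499-nt 3' UTR (a 1114-nt mRNA
#' encoding a 198-residue protein within a 6404-bp gene), an ATTAAA poly(A)
#' signal whose 3' end lies 12 nt upstream of the cleavage site, and 100-nt
#' reads.
#'
#' @param seed Integer seed; every stage derives its own substream from it.
#' @param chromosome_length Chromosome segment length (nt).
#' @param exon_lengths,intron_lengths Exon/intron lengths (nt); introns must
#'   number one fewer than exons.
#' @param utr5_length,utr3_length UTR lengths on the terminal exons (nt).
#' @param polya_hexamer Planted poly(A) signal (6-mer).
#' @param cleavage_offset Distance (nt) from the hexamer's 3' end to the
#'   cleavage (poly(A) addition) site.
#' @param n_reads Library size.
#' @param read_length Read length (nt).
#' @param error_rate Per-base substitution error probability.
#' @param polya_tail_rate Fraction of reads that are 3'-terminal, spanning the
#'   cleavage junction with a non-genomic A-run of 5-20 nt appended (the
#'   oligo-dT-primed component of the library).
#' @param five_prime_decay Per-nt decay of the read-start distribution from the
#'   transcript 5' end: start `s` has weight `(1 - decay)^(s-1)`. 0 (the
#'   default) gives uniform starts; a positive value emulates 5'-informative
#'   (capped/longest-clone) capture.
#' @param isoform_weights Sampling weights of the isoforms (must sum to 1).
#' @param isoform_exon_sets List of integer vectors; exon indices retained by
#'   each isoform (default: one isoform with all exons).
#' @param paralog_divergence Per-site substitution probability used when
#'   planting a diverged copy.
#' @param neighbor_genes `data.frame(name, strand, length)` of neighbor genes
#'   for [simulate_neighborhood()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              chromosome_length = 20000L,
                              exon_lengths = c(36L, 91L, 124L, 74L, 146L, 643L),
                              intron_lengths = c(978L, 503L, 85L, 1040L, 2684L),
                              utr5_length = 18L,
                              utr3_length = 499L,
                              polya_hexamer = "ATTAAA",
                              cleavage_offset = 12L,
                              n_reads = 100000L,
                              read_length = 100L,
                              error_rate = 0.001,
                              polya_tail_rate = 0.3,
                              five_prime_decay = 0,
                              isoform_weights = 1,
                              isoform_exon_sets = NULL,
                              paralog_divergence = 0.05,
                              neighbor_genes = data.frame(
                                name = c("Ik", "Hars", "Hars2", "Zmat2"),
                                strand = c("+", "-", "-", "+"),
                                length = c(1500L, 2000L, 1800L, 6404L),
                                stringsAsFactors = FALSE)) {
  cfg <- list(seed = as.integer(seed),
              chromosome_length = as.integer(chromosome_length),
              exon_lengths = as.integer(exon_lengths),
              intron_lengths = as.integer(intron_lengths),
              utr5_length = as.integer(utr5_length),
              utr3_length = as.integer(utr3_length),
              polya_hexamer = toupper(polya_hexamer),
              cleavage_offset = as.integer(cleavage_offset),
              n_reads = as.integer(n_reads),
              read_length = as.integer(read_length),
              error_rate = error_rate,
              polya_tail_rate = polya_tail_rate,
              five_prime_decay = five_prime_decay,
              isoform_weights = isoform_weights,
              isoform_exon_sets = isoform_exon_sets,
              paralog_divergence = paralog_divergence,
              neighbor_genes = neighbor_genes)
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  n <- length(cfg$exon_lengths)
  if (length(cfg$intron_lengths) != n - 1)
    stop("intron count must equal exon count - 1")
  if (any(cfg$exon_lengths <= 0) || any(cfg$intron_lengths <= 0))
    stop("all exon and intron lengths must be positive")
  if (nchar(cfg$polya_hexamer) != 6)
    stop("polya_hexamer must be a 6-mer")
  if (cfg$cleavage_offset < 0) stop("cleavage_offset must be >= 0")
  if (cfg$error_rate < 0 || cfg$error_rate > 1)
    stop("error_rate must be in [0, 1]")
  if (cfg$paralog_divergence < 0 || cfg$paralog_divergence > 1)
    stop("paralog_divergence must be in [0, 1]")
  if (abs(sum(cfg$isoform_weights) - 1) > 1e-8)
    stop("isoform_weights must sum to 1")
  if (!is.null(cfg$isoform_exon_sets) &&
      length(cfg$isoform_exon_sets) != length(cfg$isoform_weights))
    stop("isoform_exon_sets must match isoform_weights in length")
  if (cfg$utr5_length >= cfg$exon_lengths[1])
    stop("utr5_length must be shorter than exon 1")
  if (cfg$utr3_length >= cfg$exon_lengths[n] && n > 1)
    stop("utr3_length must be shorter than the last exon")
  if (cfg$cleavage_offset + 6 > cfg$utr3_length)
    stop("cleavage_offset + 6 must fit within the 3' UTR")
  cds <- sum(cfg$exon_lengths) - cfg$utr5_length - cfg$utr3_length
  if (cds < 6 || cds %% 3 != 0)
    stop("CDS length after UTR partition (", cds,
         ") must be >= 6 and a multiple of 3")
  invisible(cfg)
}

# sample n non-stop codons
sample_codons <- function(n) {
  if (n == 0) return(character(0))
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  sample(codons, n, replace = TRUE)
}

# replace any accepted hexamer occurring in `seq` (other than the interval
# [keep_start, keep_end]) by mutating its 3rd base
scrub_hexamers <- function(seq, keep_start = 0L, keep_end = 0L,
                           hexamers = POLYA_HEXAMERS) {
  repeat {
    found <- FALSE
    for (h in hexamers) {
      p <- 1L
      while ((m <- regexpr(h, substr(seq, p, nchar(seq)), fixed = TRUE)) > 0) {
        pos <- p + as.integer(m) - 1L
        if (!(pos >= keep_start && pos + 5L <= keep_end)) {
          mid <- pos + 2L
          cur <- substr(seq, mid, mid)
          substr(seq, mid, mid) <- if (cur == "C") "G" else "C"
          found <- TRUE
        }
        p <- pos + 1L
      }
    }
    if (!found) break
  }
  seq
}

#' Simulate a genome segment carrying a multi-exon gene
#'
#' Embeds a forward-strand gene with GT..AG introns in a random (50% GC)
#' chromosome segment. The spliced transcript is `5'UTR + CDS + 3'UTR`; the CDS
#' starts with ATG, ends with a stop codon and carries no internal stop. The
#' configured poly(A) hexamer is planted so its 3' end lies `cleavage_offset`
#' nt upstream of the cleavage position (the genomic 3' end of the last exon);
#' the 3'-end search window is scrubbed of any other accepted hexamer, and the
#' transcript's final base and the base just downstream of the cleavage site
#' are forced non-A so the cleavage position is unambiguous. Reverse-strand
#' loci are obtained by reverse-complementing the finished segment.
#'
#' @param config A [simulation_config()].
#' @return A list with `genome` (character string) and `truth`, an object of
#'   class `ground_truth` holding the `gene_model`, `tss_position`,
#'   `cleavage_position`, `hexamer_position` (genomic start of the hexamer),
#'   `isoform_models`, `transcripts` (mature sequence per isoform) and empty
#'   `retrocopy_span`/`paralog_span`.
#' @export
simulate_gene <- function(config) {
  validate_config(config)
  set.seed(substream_seed(config$seed, 1L))
  exl <- config$exon_lengths
  n <- length(exl)
  mrna_len <- sum(exl)
  cds_len <- mrna_len - config$utr5_length - config$utr3_length

  utr5 <- random_dna(config$utr5_length)
  cds <- paste0("ATG",
                paste(sample_codons(cds_len / 3 - 2), collapse = ""),
                sample(c("TAA", "TGA", "TAG"), 1))
  utr3 <- random_dna(config$utr3_length)

  transcript <- paste0(utr5, cds, utr3)
  # plant hexamer: 3' end `cleavage_offset` nt upstream of transcript end
  hex_end_t <- mrna_len - config$cleavage_offset
  hex_start_t <- hex_end_t - 5L
  substr(transcript, hex_start_t, hex_end_t) <- config$polya_hexamer
  # scrub competing hexamers from the 3' search window, keep planted one
  win_start <- max(1L, mrna_len - 60L)
  win <- substr(transcript, win_start, mrna_len)
  win <- scrub_hexamers(win, keep_start = hex_start_t - win_start + 1L,
                        keep_end = hex_end_t - win_start + 1L,
                        hexamers = unique(c(POLYA_HEXAMERS, config$polya_hexamer)))
  substr(transcript, win_start, mrna_len) <- win
  # unambiguous cleavage: final transcript base non-A
  if (substr(transcript, mrna_len, mrna_len) == "A")
    substr(transcript, mrna_len, mrna_len) <- "C"

  # cut transcript back into exons
  bounds <- cumsum(exl)
  exon_seqs <- substring(transcript, c(1L, head(bounds, -1L) + 1L), bounds)
  introns <- vapply(config$intron_lengths, function(L) {
    paste0("GT", random_dna(L - 4L), "AG")
  }, character(1))

  gene_seq <- paste0(exon_seqs[1],
                     paste0(vapply(seq_along(introns), function(i)
                       paste0(introns[i], exon_seqs[i + 1]), character(1)),
                       collapse = ""))
  gene_len <- nchar(gene_seq)
  margin <- 500L
  if (gene_len + 2L * margin > config$chromosome_length)
    stop("chromosome_length too short for the configured gene")
  gstart <- sample(margin:(config$chromosome_length - gene_len - margin), 1)
  flank5 <- random_dna(gstart - 1L)
  flank3 <- random_dna(config$chromosome_length - gstart + 1L - gene_len)
  # base right after the cleavage site forced non-A
  if (substr(flank3, 1, 1) == "A") substr(flank3, 1, 1) <- "G"
  genome <- paste0(flank5, gene_seq, flank3)

  model <- assemble_model(exl, config$intron_lengths,
                          utr5 = config$utr5_length, utr3 = config$utr3_length,
                          name = "sim_gene", strand = "+",
                          genomic_start = gstart)

  sets <- config$isoform_exon_sets %||% list(seq_len(n))
  isoform_models <- lapply(seq_along(sets), function(k) {
    keep <- sort(unique(as.integer(sets[[k]])))
    if (identical(keep, seq_len(n))) return(model)
    sub_exl <- exl[keep]
    # introns between retained exons span everything skipped
    coords <- exon_coordinates(model)
    sub_intr <- vapply(seq_len(length(keep) - 1L), function(i) {
      as.integer(coords$start[keep[i + 1L]] - coords$end[keep[i]] - 1L)
    }, integer(1))
    m <- assemble_model(sub_exl, sub_intr,
                        utr5 = min(config$utr5_length, sub_exl[1] - 1L),
                        utr3 = min(config$utr3_length,
                                   sub_exl[length(sub_exl)] - 1L),
                        name = paste0("sim_gene_iso", k), strand = "+",
                        genomic_start = as.integer(coords$start[keep[1]]))
    m
  })
  transcripts <- vapply(seq_along(sets), function(k) {
    keep <- sort(unique(as.integer(sets[[k]])))
    paste(exon_seqs[keep], collapse = "")
  }, character(1))

  coords <- exon_coordinates(model)
  truth <- structure(list(
    gene_model = model,
    exon_coordinates = coords,
    exon_sequences = exon_seqs,
    tss_position = gstart,
    cleavage_position = gstart + gene_len - 1L,
    hexamer_position = gstart + gene_len - 1L -
      (config$cleavage_offset + 5L),
    hexamer = config$polya_hexamer,
    cleavage_offset = config$cleavage_offset,
    isoform_models = isoform_models,
    transcripts = transcripts,
    retrocopy_span = NULL,
    paralog_span = NULL,
    config = config
  ), class = "ground_truth")
  list(genome = genome, truth = truth)
}

#' Simulate an RNA-seq-like read library
#'
#' Reads are substrings of the mature isoform sequences (chosen by
#' `isoform_weights`), with per-base substitution errors. A `polya_tail_rate`
#' fraction of reads is drawn from the polyadenylated molecule; those reaching
#' past the transcript 3' end carry a non-genomic A-run (>= 5 nt). Read starts
#' are uniform, optionally decaying from the 5' end (`five_prime_decay`) to
#' emulate 5'-informative capture.
#'
#' @param genome Genome string (unused directly; retained in the signature for
#'   pipeline symmetry and future spliced-alignment extensions).
#' @param truth `ground_truth` from [simulate_gene()].
#' @param config The [simulation_config()].
#' @param transcripts Optional named character vector overriding the truth's
#'   mature sequences (e.g. to add a paralog transcript).
#' @param weights Optional sampling weights matching `transcripts`.
#' @return An object of class `read_set`: data.frame with `id`, `sequence`,
#'   `isoform`, `start` (transcript coordinate) and `tail_length`; attribute
#'   `library_name`.
#' @export
simulate_reads <- function(genome, truth, config,
                           transcripts = NULL, weights = NULL) {
  set.seed(substream_seed(config$seed, 2L))
  tx <- transcripts %||% truth$transcripts
  w <- weights %||% config$isoform_weights
  if (length(w) != length(tx)) stop("weights must match transcripts")
  if (config$n_reads <= 0) stop("n_reads must be positive")
  R <- config$read_length
  lens <- nchar(tx)
  if (R > min(lens))
    stop("read_length (", R, ") exceeds the shortest isoform (", min(lens), ")")

  iso <- sample.int(length(tx), config$n_reads, replace = TRUE, prob = w)
  tailed <- runif(config$n_reads) < config$polya_tail_rate
  tail_draw <- sample(5:20, config$n_reads, replace = TRUE)

  start_probs <- lapply(lens, function(L) {
    S <- L - R + 1L
    if (config$five_prime_decay > 0) {
      p <- (1 - config$five_prime_decay)^(seq_len(S) - 1)
      p / sum(p)
    } else NULL
  })

  seqs <- character(config$n_reads)
  starts <- integer(config$n_reads)
  tlen <- integer(config$n_reads)
  for (i in seq_len(config$n_reads)) {
    k <- iso[i]
    L <- lens[k]
    if (tailed[i]) {
      # 3'-anchored read spanning the cleavage junction (oligo-dT-primed
      # component): transcript suffix plus a non-genomic A-run of 5-20 nt
      a <- min(tail_draw[i], R - 30L)
      s <- L - (R - a) + 1L
      rd <- paste0(substr(tx[k], s, L), strrep("A", a))
      tlen[i] <- a
    } else {
      S <- L - R + 1L
      s <- if (is.null(start_probs[[k]])) sample.int(S, 1L)
           else sample.int(S, 1L, prob = start_probs[[k]])
      rd <- substr(tx[k], s, s + R - 1L)
      tlen[i] <- 0L
    }
    starts[i] <- s
    seqs[i] <- if (config$error_rate > 0) mutate_bases(rd, config$error_rate) else rd
  }
  structure(
    data.frame(id = sprintf("read%06d", seq_len(config$n_reads)),
               sequence = seqs, isoform = iso, start = starts,
               tail_length = tlen, stringsAsFactors = FALSE),
    library_name = paste0("simlib_seed", config$seed),
    class = c("read_set", "data.frame")
  )
}

#' Plant an intronless retrocopy of the gene
#'
#' Inserts the (optionally diverged) mature transcript sequence intact at
#' `insertion_point`, emulating a processed mRNA retro-transposed back into the
#' genome as a DNA copy. All ground-truth coordinates at or beyond the
#' insertion point are shifted by the insert length.
#'
#' @param genome Genome string.
#' @param truth `ground_truth` from [simulate_gene()].
#' @param divergence Per-site substitution probability applied to the copy.
#' @param insertion_point 1-based genomic position at which the copy begins;
#'   must lie outside the parent gene span.
#' @param seed Integer seed for the divergence draw.
#' @return A list with updated `genome` and `truth` (the latter gains
#'   `retrocopy_span` and `retrocopy_sequence`).
#' @export
plant_retrocopy <- function(genome, truth, divergence, insertion_point,
                            seed = truth$config$seed) {
  set.seed(substream_seed(seed, 3L))
  gene_start <- truth$tss_position
  gene_end <- truth$cleavage_position
  if (insertion_point >= gene_start && insertion_point <= gene_end + 1L)
    stop("insertion_point lies inside the parent gene span")
  if (insertion_point < 1L || insertion_point > nchar(genome) + 1L)
    stop("insertion_point outside the genome")
  copy <- if (divergence > 0) mutate_bases(truth$transcripts[[1]], divergence)
          else truth$transcripts[[1]]
  L <- nchar(copy)
  genome2 <- paste0(substr(genome, 1L, insertion_point - 1L), copy,
                    substr(genome, insertion_point, nchar(genome)))
  shift <- function(p) ifelse(p >= insertion_point, p + L, p)
  truth$tss_position <- shift(truth$tss_position)
  truth$cleavage_position <- shift(truth$cleavage_position)
  truth$hexamer_position <- shift(truth$hexamer_position)
  truth$exon_coordinates$start <- shift(truth$exon_coordinates$start)
  truth$exon_coordinates$end <- shift(truth$exon_coordinates$end)
  if (!is.na(truth$gene_model$genomic_start))
    truth$gene_model$genomic_start <- shift(truth$gene_model$genomic_start)
  truth$isoform_models <- lapply(truth$isoform_models, function(m) {
    if (!is.na(m$genomic_start)) m$genomic_start <- shift(m$genomic_start)
    m
  })
  truth$retrocopy_span <- c(insertion_point, insertion_point + L - 1L)
  truth$retrocopy_sequence <- copy
  list(genome = genome2, truth = truth)
}

#' Simulate a neighborhood of ordered, oriented genes
#'
#' Places the configured neighbor genes left to right along a random
#' chromosome segment with random intergenic gaps, and returns the genome plus
#' the corresponding locus map.
#'
#' @param config A [simulation_config()]; uses `neighbor_genes`,
#'   `chromosome_length` and `seed`.
#' @param gap_range Intergenic gap range (nt), drawn uniformly.
#' @param species Species label for the locus map.
#' @param anchor Anchor gene name (defaults to `"Zmat2"` when present,
#'   otherwise the first gene).
#' @return A list with `genome` and `locus_map` (see [locus_map()]).
#' @export
simulate_neighborhood <- function(config, gap_range = c(200L, 1000L),
                                  species = "simulated", anchor = NULL) {
  set.seed(substream_seed(config$seed, 4L))
  genes <- config$neighbor_genes
  if (is.null(genes) || nrow(genes) == 0)
    stop("neighbor_genes must be non-empty")
  gaps <- sample(gap_range[1]:gap_range[2], nrow(genes) + 1L, replace = TRUE)
  total <- sum(genes$length) + sum(gaps)
  if (total > config$chromosome_length)
    stop("requested genes and gaps (", total,
         " nt) exceed chromosome_length (", config$chromosome_length, ")")
  starts <- integer(nrow(genes))
  pos <- gaps[1] + 1L
  for (i in seq_len(nrow(genes))) {
    starts[i] <- pos
    pos <- pos + genes$length[i] + gaps[i + 1L]
  }
  genome <- random_dna(config$chromosome_length)
  map <- locus_map(species = species,
                   anchor = anchor %||%
                     (if ("Zmat2" %in% genes$name) "Zmat2" else genes$name[1]),
                   genes = data.frame(name = genes$name,
                                      strand = genes$strand,
                                      start = starts,
                                      end = starts + genes$length - 1L,
                                      stringsAsFactors = FALSE))
  list(genome = genome, locus_map = map)
}
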