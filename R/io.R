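#' Read and write FASTA
#'
#' Thin wrappers around Biostrings keeping plain named character vectors as
#' the working representation.
#'
#' @param x Named character vector of sequences.
#' @param path File path.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(x, path) {
  set <- Biostrings::BStringSet(x)
  names(set) <- names(x) %||% paste0("seq", seq_along(x))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  setNames(as.character(set), names(set))
}

#' Write a read set as FASTQ
#'
#' Phred+33 with a uniform Q30 quality string.
#'
#' @param reads A `read_set` or named character vector.
#' @param path File path.
#' @export
write_fastq <- function(reads, path) {
  seqs <- read_sequences(reads)
  ids <- if (is.data.frame(reads)) reads$id else
    names(reads) %||% paste0("read", seq_along(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  qual <- vapply(nchar(seqs), function(n) strrep("?", n), character(1))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}

#' Read FASTQ with line-numbered validation
#'
#' Validates the 4-line record structure first so malformed files produce a
#' parse error naming the offending line, then parses with Biostrings.
#'
#' @param path File path.
#' @return A `read_set` data.frame with `id` and `sequence`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4 != 0)
    stop("truncated FASTQ: ", path, " has ", n,
         " lines (not a multiple of 4); record starting at line ",
         4 * (n %/% 4) + 1, " is incomplete")
  for (k in seq_len(n %/% 4)) {
    h <- 4 * (k - 1) + 1
    if (!startsWith(lines[h], "@"))
      stop("FASTQ parse error at line ", h, ": header must start with '@'")
    if (!startsWith(lines[h + 2], "+"))
      stop("FASTQ parse error at line ", h + 2,
           ": separator must start with '+'")
    if (nchar(lines[h + 1]) != nchar(lines[h + 3]))
      stop("FASTQ parse error at line ", h + 3,
           ": quality length differs from sequence length")
  }
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  structure(
    data.frame(id = names(set), sequence = as.character(set),
               stringsAsFactors = FALSE),
    library_name = basename(path),
    class = c("read_set", "data.frame")
  )
}

#' Convert a gene model to genomic feature ranges
#'
#' Produces the `gene`/`mRNA`/`exon`/`CDS` feature set (1-based, closed
#' intervals) for GFF3 export.
#'
#' @param model A `gene_model` with genomic coordinates.
#' @param seqname Sequence (chromosome) name.
#' @return A `GRanges` with `type`, `ID` and `Parent` columns.
#' @export
gene_model_to_granges <- function(model, seqname = "chr") {
  coords <- exon_coordinates(model)
  ml <- model_lengths(model)
  gene_start <- min(coords$start)
  gene_end <- max(coords$end)

  # CDS spans: coding part of each exon, honoring transcription order
  cds <- coords
  ex <- model$exons
  for (i in seq_len(nrow(ex))) {
    if (model$strand == "+") {
      cds$start[i] <- coords$start[i] + ex$utr5[i]
      cds$end[i] <- coords$end[i] - ex$utr3[i]
    } else {
      cds$start[i] <- coords$start[i] + ex$utr3[i]
      cds$end[i] <- coords$end[i] - ex$utr5[i]
    }
  }
  cds <- cds[ex$coding > 0, , drop = FALSE]

  n_ex <- nrow(coords)
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(
      start = c(gene_start, gene_start, coords$start, cds$start),
      end = c(gene_end, gene_end, coords$end, cds$end)),
    strand = model$strand)
  gr$type <- c("gene", "mRNA", rep("exon", n_ex), rep("CDS", nrow(cds)))
  # CDS phase: codon offset carried over from preceding coding exons
  coding <- ex$coding[ex$coding > 0]
  phase <- (3L - c(0L, cumsum(coding)[-length(coding)]) %% 3L) %% 3L
  gr$phase <- c(rep(NA_integer_, 2L + n_ex), phase)
  gr$ID <- c(model$name, paste0(model$name, ".t1"),
             paste0(model$name, ".exon", coords$index),
             paste0(model$name, ".cds", cds$index))
  gr$Parent <- c(NA, model$name,
                 rep(paste0(model$name, ".t1"), n_ex + nrow(cds)))
  S4Vectors::metadata(gr)$mrna_length <- ml$mrna_length
  gr
}

#' Rebuild a gene model from feature ranges
#'
#' Inverse of [gene_model_to_granges()] for a single-gene, single-transcript
#' feature set.
#'
#' @param gr A `GRanges` with `type` column holding gene/exon/CDS features.
#' @param name Gene name override (default: the gene feature's ID).
#' @return A `gene_model`.
#' @export
granges_to_gene_model <- function(gr, name = NULL) {
  type <- gr$type
  strand <- as.character(BiocGenerics::strand(gr))[1]
  exons <- gr[type == "exon"]
  cds <- gr[type == "CDS"]
  if (length(exons) == 0) stop("no exon features found")
  ord <- order(BiocGenerics::start(exons))
  if (strand == "-") ord <- rev(ord)
  ex_start <- BiocGenerics::start(exons)[ord]
  ex_end <- BiocGenerics::end(exons)[ord]
  lens <- ex_end - ex_start + 1L
  n <- length(lens)
  introns <- if (n > 1) {
    if (strand == "+") ex_start[-1] - ex_end[-n] - 1L
    else ex_start[-n] - ex_end[-1] - 1L # transcription order on '-'
  } else integer(0)

  utr5 <- 0L; utr3 <- 0L
  if (length(cds) > 0) {
    cds_lo <- min(BiocGenerics::start(cds))
    cds_hi <- max(BiocGenerics::end(cds))
    if (strand == "+") {
      utr5 <- cds_lo - ex_start[1]
      utr3 <- ex_end[n] - cds_hi
    } else {
      utr5 <- ex_end[1] - cds_hi
      utr3 <- cds_lo - ex_start[n]
    }
  }
  gname <- name %||% {
    g <- gr[type == "gene"]
    if (length(g) > 0 && !is.null(g$ID)) g$ID[1] else "gene"
  }
  assemble_model(lens, introns, utr5 = utr5, utr3 = utr3, name = gname,
                 strand = strand,
                 genomic_start = min(BiocGenerics::start(exons)))
}

#' Write/read gene models as GFF3
#'
#' GFF3 uses 1-based, closed intervals.
#'
#' @param model A `gene_model`.
#' @param path File path.
#' @param seqname Chromosome name.
#' @export
write_gff3 <- function(model, path, seqname = "chr") {
  gr <- gene_model_to_granges(model, seqname)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  granges_to_gene_model(gr)
}

#' Write probes as BED (plus FASTA)
#'
#' BED uses 0-based, half-open intervals; probe offsets are already 0-based so
#' they map directly to BED starts.
#'
#' @param probes A `probe_set`.
#' @param path BED file path.
#' @param seqname Chromosome name.
#' @param region_offset 0-based genomic offset of the probes' source region.
#' @export
write_probes_bed <- function(probes, path, seqname = "chr",
                             region_offset = 0L) {
  df <- data.frame(chrom = seqname,
                   start = probes$offset + region_offset,
                   end = probes$offset + region_offset +
                     nchar(probes$sequence),
                   name = probes$id,
                   stringsAsFactors = FALSE)
  writeLines(sprintf("%s\t%d\t%d\t%s", df$chrom, df$start, df$end, df$name),
             path)
  invisible(path)
}

#' @rdname write_probes_bed
#' @export
read_probes_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L, # back to 0-based
             end = BiocGenerics::end(gr),
             name = gr$name,
             stringsAsFactors = FALSE)
}

#' Coordinate conversions between BED and GFF conventions
#'
#' BED is 0-based half-open; GFF is 1-based closed. These two helpers are the
#' single place the off-by-one lives.
#'
#' @param start0,end0 BED start/end.
#' @param start1,end1 GFF start/end.
#' @return A list with converted `start` and `end`.
#' @export
bed_to_gff_coords <- function(start0, end0) {
  list(start = start0 + 1L, end = end0)
}

#' @rdname bed_to_gff_coords
#' @export
gff_to_bed_coords <- function(start1, end1) {
  list(start = start1 - 1L, end = end1)
}

#' Write a TSV with a provenance header
#'
#' Every pipeline table carries its seed and configuration hash as `#` comment
#' lines, so any stage can be re-run and byte-compared.
#'
#' @param df Data.frame to write.
#' @param path File path.
#' @param seed Run seed.
#' @param config_hash Configuration hash string.
#' @export
write_tsv_stamped <- function(df, path, seed = NA, config_hash = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%s config=%s", seed, config_hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_stamped
#' @export
read_tsv_stamped <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
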