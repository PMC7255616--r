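#' Assemble an exon/intron/UTR gene model
#'
#' Builds a gene model from exon and intron lengths plus the UTR annotation of
#' the terminal exons. Interior exons are fully coding; exon 1 carries the 5'
#' UTR and the last exon the 3' UTR. Models whose total coding length is not a
#' multiple of 3 are representable (the audit must be able to hold inconsistent
#' published rows) but are marked non-translatable.
#'
#' @param exon_lengths Integer vector of exon lengths (nt), 5' to 3'.
#' @param intron_lengths Integer vector of intron lengths; must be one shorter
#'   than `exon_lengths` (empty for a single-exon gene).
#' @param utr5 Length (nt) of the 5' UTR on exon 1.
#' @param utr3 Length (nt) of the 3' UTR on the last exon.
#' @param name Gene name.
#' @param strand `"+"` or `"-"`.
#' @param genomic_start Optional 1-based genomic coordinate of the gene's first
#'   base (leftmost base for `+`; the model's exon order is transcription
#'   order).
#' @return An object of class `gene_model`: a list with `name`, `exons` (a
#'   data.frame with `index`, `length`, `utr5`, `coding`, `utr3`), `introns`,
#'   `strand`, `genomic_start` and `translatable`.
#' @export
assemble_model <- function(exon_lengths, intron_lengths = integer(0),
                           utr5 = 0, utr3 = 0, name = "gene",
                           strand = "+", genomic_start = NA_integer_) {
  exon_lengths <- as.integer(exon_lengths)
  intron_lengths <- as.integer(intron_lengths)
  n <- length(exon_lengths)
  if (n < 1) stop("at least one exon is required")
  if (length(intron_lengths) != n - 1)
    stop("intron count must equal exon count - 1 (got ", length(intron_lengths),
         " introns for ", n, " exons)")
  if (any(exon_lengths <= 0) || any(intron_lengths <= 0))
    stop("exon and intron lengths must be positive")
  if (utr5 < 0 || utr3 < 0) stop("UTR lengths must be non-negative")
  if (utr5 >= exon_lengths[1])
    stop("5' UTR (", utr5, ") must be shorter than exon 1 (", exon_lengths[1], ")")
  if (utr3 >= exon_lengths[n] && n > 1)
    stop("3' UTR (", utr3, ") must be shorter than the last exon")
  if (n == 1 && utr5 + utr3 >= exon_lengths[1])
    stop("UTRs exceed the single exon length")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")

  exons <- data.frame(
    index = seq_len(n),
    length = exon_lengths,
    utr5 = c(utr5, rep(0L, n - 1)),
    utr3 = c(rep(0L, n - 1), utr3),
    stringsAsFactors = FALSE
  )
  exons$coding <- exons$length - exons$utr5 - exons$utr3
  exons <- exons[, c("index", "length", "utr5", "coding", "utr3")]
  cds <- sum(exons$coding)
  structure(
    list(name = name, exons = exons, introns = intron_lengths,
         strand = strand, genomic_start = genomic_start,
         translatable = cds %% 3 == 0 && cds >= 6),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  ml <- model_lengths(x)
  cat(sprintf("gene_model '%s' (%s): %d exon(s), gene %d bp, mRNA %d nt, CDS %d nt%s\n",
              x$name, x$strand, nrow(x$exons), ml$gene_length, ml$mrna_length,
              ml$cds_length,
              if (x$translatable) "" else " [non-translatable]"))
  invisible(x)
}

#' Gene, mRNA and CDS lengths of a model
#'
#' `gene_length` is the sum of exon plus intron lengths, `mrna_length` the sum
#' of exon lengths (the processed transcript), and `cds_length` the sum of
#' coding segments (including the stop codon).
#'
#' @param model A `gene_model`.
#' @return A list with `gene_length`, `mrna_length` and `cds_length`.
#' @export
model_lengths <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  list(
    gene_length = sum(model$exons$length) + sum(model$introns),
    mrna_length = sum(model$exons$length),
    cds_length = sum(model$exons$coding)
  )
}

# 1-based genomic [start, end] per exon, in transcription order. For "-"
# strand models genomic_start is still the leftmost base of the gene; exon 1
# is then the rightmost exon.
exon_coordinates <- function(model) {
  if (is.na(model$genomic_start)) stop("model has no genomic coordinates")
  lens <- model$exons$length
  intr <- c(model$introns, 0L)
  starts <- model$genomic_start +
    cumsum(c(0L, head(lens + intr, -1L)))
  coords <- data.frame(index = model$exons$index,
                       start = starts, end = starts + lens - 1L)
  if (model$strand == "-") {
    # mirror so exon 1 (transcription order) is the rightmost block
    gene_len <- sum(lens) + sum(model$introns)
    gstart <- model$genomic_start
    gend <- gstart + gene_len - 1L
    coords$new_start <- gstart + (gend - coords$end)
    coords$new_end <- gstart + (gend - coords$start)
    coords$start <- coords$new_start
    coords$end <- coords$new_end
    coords$new_start <- coords$new_end <- NULL
  }
  coords
}

#' Splice a mature transcript out of a genome
#'
#' Concatenates the model's exon sequences in transcription order;
#' reverse-complements for minus-strand models.
#'
#' @param genome Genome sequence (single character string).
#' @param model A `gene_model` with `genomic_start` set.
#' @return The mature (spliced) transcript as a character string.
#' @export
splice_transcript <- function(genome, model) {
  stopifnot(inherits(model, "gene_model"))
  coords <- exon_coordinates(model)
  if (any(coords$start < 1) || any(coords$end > nchar(genome)))
    stop("exon coordinates out of genome bounds")
  pieces <- substring(genome, coords$start, coords$end)
  if (model$strand == "-") pieces <- revcomp(pieces)
  paste(pieces, collapse = "")
}

#' Translate a coding sequence
#'
#' Translates a CDS with the standard genetic code and audits it: the sequence
#' must begin with ATG (unless `allow_non_atg_start`, for proteins annotated
#' without an amino-terminal methionine), have length divisible by 3, end in a
#' stop codon, and contain no internal stop. The reported protein length is
#' `codon_count - 1` (the stop codon is excluded).
#'
#' @param cds_sequence CDS as a character string (A/C/G/T).
#' @param allow_non_atg_start Permit a non-ATG first codon.
#' @return An object of class `protein_record`: list with `sequence`, `length`
#'   and `codon_count`.
#' @export
translate_cds <- function(cds_sequence, allow_non_atg_start = FALSE) {
  n <- nchar(cds_sequence)
  if (n %% 3 != 0)
    stop("CDS length (", n, ") is not a multiple of 3")
  if (!allow_non_atg_start && toupper(substr(cds_sequence, 1, 3)) != "ATG")
    stop("CDS does not begin with ATG")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(toupper(cds_sequence)),
    no.init.codon = TRUE
  ))
  codons <- n / 3
  if (substr(aa, codons, codons) != "*")
    stop("CDS lacks a terminal stop codon")
  body <- substr(aa, 1, codons - 1)
  if (grepl("*", body, fixed = TRUE))
    stop("CDS contains an internal stop codon at codon ",
         regexpr("*", body, fixed = TRUE)[1])
  structure(list(sequence = body, length = nchar(body), codon_count = codons),
            class = "protein_record")
}

#' Audit a model against reported totals
#'
#' Recomputes gene and mRNA lengths from the model and compares them with the
#' published totals. A discrepancy is a finding, not an error: the report rows
#' flag it but the call succeeds.
#'
#' @param model A `gene_model`.
#' @param reported_gene_length Published total gene length (bp), or `NA`.
#' @param reported_mrna_length Published mRNA length (nt), or `NA`.
#' @return A data.frame with `quantity`, `computed`, `reported`, `pass`.
#' @export
validate_reported_totals <- function(model, reported_gene_length = NA,
                                     reported_mrna_length = NA) {
  ml <- model_lengths(model)
  out <- data.frame(
    quantity = c("gene_length", "mrna_length"),
    computed = c(ml$gene_length, ml$mrna_length),
    reported = c(reported_gene_length, reported_mrna_length),
    stringsAsFactors = FALSE
  )
  out$pass <- !is.na(out$reported) & out$computed == out$reported
  out$pass[is.na(out$reported)] <- NA
  out
}

#' Audit the published gene-structure rows
#'
#' Runs [validate_reported_totals()] over every fully characterized row of
#' [zmat2_gene_rows()], returning one audit row per species with the computed
#' total, the printed total, and a flag where they disagree.
#'
#' @param rows A data.frame shaped like [zmat2_gene_rows()].
#' @return A data.frame with `species`, `computed_total_bp`,
#'   `reported_total_bp`, `computed_mrna_nt`, `reported_mrna_nt`,
#'   `total_flagged`, `mrna_flagged`.
#' @export
audit_gene_table <- function(rows = zmat2_gene_rows()) {
  exon_cols <- grep("^exon", names(rows), value = TRUE)
  intron_cols <- grep("^intron", names(rows), value = TRUE)
  res <- lapply(seq_len(nrow(rows)), function(i) {
    ex <- as.numeric(rows[i, exon_cols])
    intr <- as.numeric(rows[i, intron_cols])
    if (anyNA(ex) || anyNA(intr)) {
      return(data.frame(species = rows$species[i],
                        computed_total_bp = NA_real_,
                        reported_total_bp = rows$reported_total_bp[i],
                        computed_mrna_nt = NA_real_,
                        reported_mrna_nt = rows$reported_mrna_nt[i],
                        total_flagged = NA, mrna_flagged = NA,
                        stringsAsFactors = FALSE))
    }
    model <- assemble_model(ex, intr, utr5 = 0, utr3 = 0,
                            name = rows$species[i])
    ml <- model_lengths(model)
    # lower-bound totals (">" rows) and partial rows (more exons than the
    # table prints) cannot be audited by summation
    exempt <- isTRUE(rows$total_is_lower_bound[i]) ||
      isTRUE(rows$partial_row[i])
    data.frame(
      species = rows$species[i],
      computed_total_bp = ml$gene_length,
      reported_total_bp = rows$reported_total_bp[i],
      computed_mrna_nt = ml$mrna_length,
      reported_mrna_nt = rows$reported_mrna_nt[i],
      total_flagged = !exempt && !is.na(rows$reported_total_bp[i]) &&
        ml$gene_length != rows$reported_total_bp[i],
      mrna_flagged = !is.na(rows$reported_mrna_nt[i]) &&
        ml$mrna_length != rows$reported_mrna_nt[i],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Summarize a model as an exon/intron length table row
#'
#' Produces the alternating exon/intron length layout used in the published
#' structure tables, ending with the total gene length.
#'
#' @param model A `gene_model`.
#' @return A one-row data.frame `exon1, intron1, exon2, ..., total`.
#' @export
model_structure_row <- function(model) {
  lens <- model$exons$length
  intr <- model$introns
  n <- length(lens)
  vals <- integer(0)
  nms <- character(0)
  for (i in seq_len(n)) {
    vals <- c(vals, lens[i])
    nms <- c(nms, paste0("exon", i))
    if (i < n) {
      vals <- c(vals, intr[i])
      nms <- c(nms, paste0("intron", i))
    }
  }
  out <- as.data.frame(as.list(c(vals, sum(vals))))
  names(out) <- c(nms, "total")
  out
}
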