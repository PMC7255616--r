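#' Count read support per probe
#'
#' A read is counted for a probe when the full probe lies within the read (on
#' either strand) with at most `max_mismatches` mismatches over the probe; each
#' read is counted at most once per probe. Matching uses an exact k-mer seed
#' (word size 11) followed by mismatch-bounded verification, the regime
#' appropriate for near-identical sequences.
#'
#' @param probes A `probe_set` (see [tile_probes()]) or character vector.
#' @param reads A `read_set` (see [simulate_reads()]) or character vector.
#' @param max_mismatches Mismatch tolerance over the probe.
#' @param both_strands Test the reverse complement of each read as well.
#' @param seed_length Exact seed length.
#' @return An object of class `hit_profile`: data.frame with `probe_id`, `tag`
#'   and `hit_count`; attribute `library_name`.
#' @export
count_probe_hits <- function(probes, reads, max_mismatches = 2L,
                             both_strands = TRUE, seed_length = 11L) {
  pseq <- if (is.data.frame(probes)) probes$sequence else as.character(probes)
  pid <- if (is.data.frame(probes)) probes$id else paste0("probe-", seq_along(pseq))
  ptag <- if (is.data.frame(probes) && "tag" %in% names(probes)) probes$tag
          else letter_tags(length(pseq))
  rseq <- read_sequences(reads)
  if (length(rseq) == 0) {
    warning("empty read set: all-zero hit profile")
    counts <- integer(length(pseq))
  } else {
    counts <- count_hits_cpp(pseq, rseq, as.integer(max_mismatches),
                             as.integer(seed_length), both_strands)
  }
  structure(
    data.frame(probe_id = pid, tag = ptag, hit_count = counts,
               stringsAsFactors = FALSE),
    library_name = attr(reads, "library_name") %||% "library",
    class = c("hit_profile", "data.frame")
  )
}

read_sequences <- function(reads) {
  if (is.data.frame(reads)) reads$sequence else as.character(reads)
}

#' Place reads on a region by ungapped matching
#'
#' Best ungapped placement of each read on a region sequence: an exact k-mer
#' seed fixes the offset; the full overlap between read and region under that
#' offset (clipped at region edges) must carry at most `max_mismatches`
#' mismatches and at least `min_overlap` columns.
#'
#' @inheritParams count_probe_hits
#' @param region_sequence Region as a character string.
#' @param min_overlap Minimum overlap (nt).
#' @return A data.frame with one row per matched read: `read` (index), `start`,
#'   `end` (1-based region coordinates), `read_start`, `read_end`,
#'   `mismatches`, `strand`.
#' @export
match_reads <- function(region_sequence, reads, max_mismatches = 2L,
                        min_overlap = 16L, both_strands = TRUE,
                        seed_length = 11L) {
  rseq <- read_sequences(reads)
  if (length(rseq) == 0)
    return(data.frame(read = integer(0), start = integer(0), end = integer(0),
                      read_start = integer(0), read_end = integer(0),
                      mismatches = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  match_reads_cpp(rseq, region_sequence, as.integer(max_mismatches),
                  as.integer(seed_length), as.integer(min_overlap),
                  both_strands)
}

boundary_call <- function(position, side, support_reads, method,
                          confidence = "normal", utr_length = NA_integer_) {
  structure(list(position = position, side = side,
                 support_reads = support_reads, method = method,
                 confidence = confidence, utr_length = utr_length),
            class = "boundary_call")
}

#' @export
print.boundary_call <- function(x, ...) {
  cat(sprintf("%s boundary at %d (%s; %d read(s); confidence %s)%s\n",
              x$side, x$position, x$method, x$support_reads, x$confidence,
              if (!is.na(x$utr_length))
                sprintf("; UTR >= %d nt", x$utr_length) else ""))
  invisible(x)
}

#' Call the transcript 5' end (longest-clone rule)
#'
#' The 5' boundary is the 5'-most region coordinate covered by any matched
#' read. The call carries lower-bound ("at least") semantics: more reads can
#' only move it further 5'. A call supported by a single read is flagged
#' low-confidence.
#'
#' @param region_sequence Region covering the candidate 5' end (upstream flank
#'   plus first exon).
#' @param reads A `read_set` or character vector of read sequences.
#' @param probes Optional `hit_profile` over 5' probes; if supplied, at least
#'   one probe must have non-zero hits.
#' @param atg_position Optional 1-based region coordinate of the start codon;
#'   when given, the call carries the derived (lower-bound) 5' UTR length.
#' @param max_mismatches Mismatch tolerance for read placement.
#' @return A `boundary_call` with side `"5'"`.
#' @export
call_five_prime <- function(region_sequence, reads, probes = NULL,
                            atg_position = NA_integer_, max_mismatches = 2L) {
  if (!is.null(probes) && all(probes$hit_count == 0))
    stop("no expression evidence: all probe hit counts are zero")
  m <- match_reads(region_sequence, reads, max_mismatches = max_mismatches)
  if (nrow(m) == 0) stop("no expression evidence: no reads match the region")
  pos <- min(m$start)
  support <- sum(m$start == pos)
  boundary_call(position = pos, side = "5'", support_reads = support,
                method = "longest-clone",
                confidence = if (support < 2) "low" else "normal",
                utr_length = if (!is.na(atg_position))
                  as.integer(atg_position - pos) else NA_integer_)
}

#' Scan a window for poly(A) signal hexamers
#'
#' Reports every occurrence of an accepted hexamer within the window, 5' to 3'.
#'
#' @param sequence Sequence to scan.
#' @param window Integer `c(start, end)` (1-based, inclusive) restricting the
#'   scan; default the whole sequence.
#' @param hexamers Accepted signal set.
#' @return A data.frame with `hexamer`, `start`, `end` (1-based coordinates in
#'   `sequence`).
#' @export
scan_polya_signals <- function(sequence, window = NULL,
                               hexamers = POLYA_HEXAMERS) {
  L <- nchar(sequence)
  if (is.null(window)) window <- c(1L, L)
  if (window[1] < 1L || window[2] > L || window[1] > window[2])
    stop("window outside sequence")
  sub <- substr(sequence, window[1], window[2])
  hits <- do.call(rbind, lapply(hexamers, function(h) {
    pos <- gregexpr(h, sub, fixed = TRUE)[[1]]
    if (pos[1] == -1) return(NULL)
    data.frame(hexamer = h, start = as.integer(pos) + window[1] - 1L,
               stringsAsFactors = FALSE)
  }))
  if (is.null(hits))
    return(data.frame(hexamer = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  hits$end <- hits$start + 5L
  hits[order(hits$start), , drop = FALSE]
}

polya_site <- function(hexamer, hexamer_start, cleavage_position) {
  structure(list(hexamer = hexamer,
                 hexamer_position = hexamer_start,
                 cleavage_position = cleavage_position,
                 offset = cleavage_position - (hexamer_start + 5L)),
            class = "polya_site")
}

#' @export
print.polya_site <- function(x, ...) {
  cat(sprintf("poly(A) site: %s at %d, cleavage at %d (offset %d nt)\n",
              x$hexamer, x$hexamer_position, x$cleavage_position, x$offset))
  invisible(x)
}

#' Call the transcript 3' end and poly(A) site
#'
#' The cleavage position is the 3'-most region coordinate at which reads
#' transition to non-genomic A-runs: each read's trailing A-run (>= 5 nt) is
#' stripped, the core is placed on the region, and the match end is re-extended
#' through genomic As (tail As are indistinguishable from templated As) as long
#' as at least 5 non-genomic As remain. If no A-tailed read is found the call
#' falls back to the 3'-most covered coordinate at low confidence. A poly(A)
#' site is reported when an accepted hexamer lies within `search_window` nt
#' upstream of the cleavage position (closest hexamer chosen).
#'
#' @param region_sequence Region covering the terminal exon.
#' @param reads A `read_set` or character vector.
#' @param probes Optional `hit_profile` over 3' probes; if supplied, at least
#'   one probe must have non-zero hits.
#' @param downstream Genomic sequence immediately 3' of the region, used only
#'   for the genomic-A re-extension check.
#' @param search_window Hexamer search window (nt) upstream of the cleavage
#'   candidate.
#' @param hexamers Accepted signal set.
#' @param max_mismatches Mismatch tolerance for read placement.
#' @return A list with `boundary` (a `boundary_call`, side `"3'"`) and `polya`
#'   (a `polya_site`, or `NULL` when no accepted hexamer lies in the window).
#' @export
call_three_prime <- function(region_sequence, reads, probes = NULL,
                             downstream = "", search_window = 40L,
                             hexamers = POLYA_HEXAMERS, max_mismatches = 2L) {
  if (!is.null(probes) && all(probes$hit_count == 0))
    stop("no terminal-exon coverage: all probe hit counts are zero")
  rseq <- read_sequences(reads)
  L <- nchar(region_sequence)
  extended <- paste0(region_sequence, downstream)

  tail_len <- vapply(rseq, function(s) {
    m <- regexpr("A+$", s)
    if (m > 0) attr(m, "match.length") else 0L
  }, integer(1), USE.NAMES = FALSE)

  candidates <- integer(0)
  tailed_idx <- which(tail_len >= 5L)
  if (length(tailed_idx) > 0) {
    cores <- substr(rseq[tailed_idx], 1L,
                    nchar(rseq[tailed_idx]) - tail_len[tailed_idx])
    long_enough <- nchar(cores) >= 16L
    cores <- cores[long_enough]
    tl <- tail_len[tailed_idx][long_enough]
    if (length(cores) > 0) {
      m <- match_reads(region_sequence, cores,
                       max_mismatches = max_mismatches, both_strands = FALSE)
      if (nrow(m) > 0) {
        for (r in seq_len(nrow(m))) {
          # the placement must reach the core's 3' end
          if (m$read_end[r] != nchar(cores[m$read[r]])) next
          e <- m$end[r]
          remaining <- tl[m$read[r]]
          # A's that continue to match the genome are genomic: re-extend
          # through them; only the unmatched remainder is a candidate tail
          while (remaining > 0L && e < nchar(extended) &&
                 substr(extended, e + 1L, e + 1L) == "A") {
            e <- e + 1L
            remaining <- remaining - 1L
          }
          if (remaining >= 5L) candidates <- c(candidates, e)
        }
      }
    }
  }

  if (length(candidates) > 0) {
    cleavage <- max(candidates)
    bc <- boundary_call(position = cleavage, side = "3'",
                        support_reads = sum(candidates == cleavage),
                        method = "polyA-site", confidence = "normal")
  } else {
    m <- match_reads(region_sequence, reads, max_mismatches = max_mismatches)
    if (nrow(m) == 0) stop("no terminal-exon coverage: no reads match")
    cleavage <- max(m$end)
    bc <- boundary_call(position = cleavage, side = "3'",
                        support_reads = sum(m$end == cleavage),
                        method = "coverage-terminus", confidence = "low")
  }

  win_start <- max(1L, cleavage - search_window - 5L)
  sig <- scan_polya_signals(region_sequence, window = c(win_start, min(cleavage, L)),
                            hexamers = hexamers)
  sig <- sig[sig$end <= cleavage, , drop = FALSE]
  ps <- NULL
  if (nrow(sig) > 0) {
    best <- sig[which.max(sig$end), ]
    ps <- polya_site(best$hexamer, best$start, cleavage)
  }
  list(boundary = bc, polya = ps)
}

#' Per-exon read support and junction evidence
#'
#' Places reads on the model's spliced transcript and reports, per exon,
#' whether any read matches within it, and per junction, the number of reads
#' spanning at least `junction_flank` nt on each side.
#'
#' @param model A `gene_model`.
#' @param reads A `read_set` or character vector.
#' @param transcript The model's spliced transcript; computed from `genome`
#'   when omitted.
#' @param genome Genome string (used only when `transcript` is missing).
#' @param max_mismatches Mismatch tolerance.
#' @param junction_flank Minimum read span (nt) on each side of a junction.
#' @return A list with `exons` (data.frame `exon`, `supported`,
#'   `reads_in_exon`) and `junctions` (data.frame `junction`, `upstream_exon`,
#'   `downstream_exon`, `junction_support`).
#' @export
exon_usage <- function(model, reads, transcript = NULL, genome = NULL,
                       max_mismatches = 2L, junction_flank = 8L) {
  stopifnot(inherits(model, "gene_model"))
  if (is.null(transcript)) {
    if (is.null(genome)) stop("supply either `transcript` or `genome`")
    transcript <- splice_transcript(genome, model)
  }
  lens <- model$exons$length
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1L) + 1L)
  L <- nchar(transcript)
  rseq <- read_sequences(reads)
  rlen_max <- if (length(rseq)) max(nchar(rseq)) else 0L

  # per-exon support: reads placed on the exon's own sequence so that
  # junction-spanning reads from other isoforms are clipped, not rejected
  n_in <- integer(length(lens))
  for (i in seq_along(lens)) {
    region <- substr(transcript, starts[i], ends[i])
    ov <- min(16L, lens[i])
    m <- match_reads(region, reads, max_mismatches = max_mismatches,
                     min_overlap = ov)
    n_in[i] <- nrow(m)
  }

  # per-junction support: reads placed on a window around the splice point of
  # THIS model's transcript, spanning >= junction_flank nt on each side
  jn <- integer(max(length(lens) - 1L, 0L))
  if (length(lens) > 1 && rlen_max > 0) {
    for (i in seq_len(length(lens) - 1L)) {
      b <- ends[i] # junction lies between positions b and b + 1
      w0 <- max(1L, b - rlen_max + 1L)
      w1 <- min(L, b + rlen_max)
      region <- substr(transcript, w0, w1)
      jb <- b - w0 + 1L
      m <- match_reads(region, reads, max_mismatches = max_mismatches)
      jn[i] <- sum(m$start <= jb - junction_flank + 1L &
                   m$end >= jb + junction_flank)
    }
  }
  supported <- n_in > 0
  if (length(lens) > 1) {
    adj <- c(jn, 0L) > 0 | c(0L, jn) > 0
    supported <- supported | adj
  }
  list(
    exons = data.frame(exon = seq_along(lens), supported = supported,
                       reads_in_exon = n_in, stringsAsFactors = FALSE),
    junctions = if (length(lens) > 1)
      data.frame(junction = seq_len(length(lens) - 1L),
                 upstream_exon = seq_len(length(lens) - 1L),
                 downstream_exon = seq_len(length(lens) - 1L) + 1L,
                 junction_support = jn, stringsAsFactors = FALSE)
    else
      data.frame(junction = integer(0), upstream_exon = integer(0),
                 downstream_exon = integer(0), junction_support = integer(0))
  )
}

#' Relative expression of a paralog from discriminating probes
#'
#' Ratio (percent) of the mean per-probe hit count of gene 2 to that of gene 1,
#' computed over discriminating probes of equal number and comparable length.
#'
#' @param profile_1,profile_2 `hit_profile`s built from discriminating probes.
#' @return The ratio in percent (numeric). `NA` with a warning when the
#'   denominator (gene 1 mean) is zero.
#' @export
paralog_expression_ratio <- function(profile_1, profile_2) {
  if (nrow(profile_1) != nrow(profile_2))
    stop("profiles must be built from equal numbers of discriminating probes")
  m1 <- mean(profile_1$hit_count)
  m2 <- mean(profile_2$hit_count)
  if (m1 == 0) {
    warning("gene 1 mean hit count is zero: ratio undefined")
    return(NA_real_)
  }
  100 * m2 / m1
}
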