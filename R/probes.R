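#' Tile fixed-length probes across a region
#'
#' Produces the tiled genomic probes (default 60 bp, abutting) used to
#' interrogate read libraries, labeled a, b, c, ... in 5' to 3' order.
#'
#' @param region_sequence Region as a character string.
#' @param probe_length Probe length (nt), default 60.
#' @param step Tiling step (nt); default `probe_length` (abutting windows).
#' @param source Name of the source region, stored on each probe.
#' @return A data.frame of class `probe_set` with `id`, `source`, `offset`
#'   (0-based position in the region), `sequence` and `tag`.
#' @export
tile_probes <- function(region_sequence, probe_length = 60L, step = probe_length,
                        source = "region") {
  if (step < 1L) stop("step must be >= 1")
  L <- nchar(region_sequence)
  if (L < probe_length) {
    warning("region (", L, " nt) shorter than probe_length (", probe_length,
            "); no probes produced")
    return(empty_probe_set(source))
  }
  offsets <- seq(0L, L - probe_length, by = step)
  tags <- letter_tags(length(offsets))
  structure(
    data.frame(id = paste0(source, "-", tags),
               source = source,
               offset = as.integer(offsets),
               sequence = substring(region_sequence, offsets + 1L,
                                    offsets + probe_length),
               tag = tags,
               stringsAsFactors = FALSE),
    class = c("probe_set", "data.frame")
  )
}

empty_probe_set <- function(source = "region") {
  structure(
    data.frame(id = character(0), source = character(0), offset = integer(0),
               sequence = character(0), tag = character(0),
               stringsAsFactors = FALSE),
    class = c("probe_set", "data.frame")
  )
}

#' Paralog-discriminating probe windows
#'
#' Globally aligns two sequences and returns every `probe_length` window of
#' `seq_a` whose aligned counterpart in `seq_b` differs at `min_mismatches` or
#' more positions (gap columns count as differences). With the default
#' mismatch-bounded read matching (<= 2 mismatches), windows differing at >= 3
#' positions are paralog-specific.
#'
#' @param seq_a,seq_b Sequences to discriminate between.
#' @param probe_length Window length (nt).
#' @param min_mismatches Minimum aligned differences within the window.
#' @param step Window step, default 1.
#' @return A `probe_set` of windows of `seq_a` (offsets are 0-based positions
#'   in `seq_a`), with an extra `mismatches` column.
#' @export
discriminating_probes <- function(seq_a, seq_b, probe_length = 60L,
                                  min_mismatches = 3L, step = 1L) {
  La <- nchar(seq_a)
  if (La < probe_length) {
    warning("seq_a shorter than probe_length; no probes produced")
    return(empty_probe_set("seq_a"))
  }
  aln <- global_align(seq_a, seq_b)
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  # per-position (in seq_a) difference indicator; columns where a has a gap
  # are charged to the following a-position
  a_pos <- cumsum(ca != "-")
  diff_col <- ca != cb
  subst <- diff_col & ca != "-"
  mism_at <- tabulate(a_pos[subst], nbins = La)
  # gaps in a (insertions in b) charged to the preceding a-position
  gap_pos <- a_pos[diff_col & ca == "-"]
  ins_at <- tabulate(pmax(gap_pos, 1L), nbins = La)

  offsets <- seq(0L, La - probe_length, by = step)
  mm <- vapply(offsets, function(o) {
    idx <- (o + 1L):(o + probe_length)
    sum(mism_at[idx]) + sum(ins_at[idx])
  }, numeric(1))
  keep <- mm >= min_mismatches
  if (!any(keep)) return(empty_probe_set("seq_a"))
  offs <- offsets[keep]
  tags <- letter_tags(length(offsets))[keep]
  out <- data.frame(id = paste0("seq_a-", tags),
                    source = "seq_a",
                    offset = as.integer(offs),
                    sequence = substring(seq_a, offs + 1L, offs + probe_length),
                    tag = tags,
                    mismatches = as.integer(mm[keep]),
                    stringsAsFactors = FALSE)
  structure(out, class = c("probe_set", "data.frame"))
}
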