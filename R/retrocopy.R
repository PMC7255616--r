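#' Scan a genome for exon-homologous blocks
#'
#' Best local alignment block per exon per strand, outside an excluded parent
#' span (masked with N so the parent never matches), filtered on score, span
#' and identity.
#'
#' @param exon_sequences List/character vector of exon sequences (order gives
#'   the exon index).
#' @param genome Genome string.
#' @param exclude_span Optional `c(start, end)` (1-based, inclusive) to mask;
#'   `NULL` disables exclusion.
#' @param min_identity Minimum fractional identity of a block.
#' @param min_span,min_score Block thresholds (see [local_best_block()]).
#' @param scoring Optional [scoring_scheme()].
#' @return A data.frame of `homology_block`s: `exon`, `start`, `end`, `strand`,
#'   `identity` (percent), `span`, `score`, sorted by genomic position.
#' @export
exon_homology_scan <- function(exon_sequences, genome, exclude_span = NULL,
                               min_identity = 0.75, min_span = 30,
                               min_score = 30, scoring = NULL) {
  scoring <- scoring %||% scoring_scheme("dna")
  if (!is.null(exclude_span)) {
    stopifnot(length(exclude_span) == 2, exclude_span[1] <= exclude_span[2])
    mask <- strrep("N", exclude_span[2] - exclude_span[1] + 1L)
    substr(genome, exclude_span[1], exclude_span[2]) <- mask
  }
  rows <- list()
  for (i in seq_along(exon_sequences)) {
    ex <- toupper(exon_sequences[[i]])
    for (strand in c("+", "-")) {
      q <- if (strand == "+") ex else revcomp(ex)
      r <- local_best_block(q, genome, scoring = scoring,
                            min_score = min_score, min_span = min_span)
      if (r$no_match) next
      if (r$percent_identity / 100 < min_identity) next
      rows[[length(rows) + 1L]] <- data.frame(
        exon = i, start = r$start_target, end = r$end_target,
        strand = strand, identity = r$percent_identity,
        span = r$matched_span, score = r$score, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(exon = integer(0), start = integer(0), end = integer(0),
                      strand = character(0), identity = numeric(0),
                      span = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

# b can follow a in a chain: same strand, strictly downstream, exon index
# strictly increasing (+) or strictly decreasing (-)
block_follows <- function(a, b) {
  if (a$strand != b$strand) return(FALSE)
  if (b$start <= a$end) return(FALSE)
  if (a$strand == "+") b$exon > a$exon else b$exon < a$exon
}

#' Chain homology blocks into candidate gene copies
#'
#' Enumerates every maximal chain of co-linear same-strand blocks (exon indices
#' strictly increasing left-to-right on `+`, strictly decreasing on `-`),
#' recording inter-block gaps. A chain is `intronless` when every gap is at
#' most `gap_threshold` nt — retrocopy-like adjacency, orders of magnitude
#' below parent intron lengths.
#'
#' @param blocks Data.frame from [exon_homology_scan()] (sorted by position).
#' @param gap_threshold Maximum inter-block gap (nt) for an intronless chain.
#' @param exon_lengths Optional parent exon lengths; when given, the allowed
#'   gap between blocks of exons i and j additionally includes the summed
#'   length of the skipped exons i+1..j-1 — an undetected short exon still
#'   occupies its sequence within an intronless copy.
#' @return A list of chains, each a list with `blocks` (data.frame rows),
#'   `gaps`, `max_gap`, `intronless`, `strand`, `n_exons`; sorted by decreasing
#'   block count.
#' @export
chain_blocks <- function(blocks, gap_threshold = 50L, exon_lengths = NULL) {
  n <- nrow(blocks)
  if (n == 0) return(list())
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  rows <- split(blocks, seq_len(n))
  succ <- lapply(seq_len(n), function(i) {
    js <- setdiff(seq_len(n), seq_len(i))
    js[vapply(js, function(j) block_follows(rows[[i]], rows[[j]]), logical(1))]
  })
  has_pred <- rep(FALSE, n)
  for (i in seq_len(n)) has_pred[succ[[i]]] <- TRUE

  chains <- list()
  walk <- function(path) {
    nxt <- succ[[path[length(path)]]]
    if (length(nxt) == 0) {
      chains[[length(chains) + 1L]] <<- path
    } else {
      for (j in nxt) walk(c(path, j))
    }
  }
  for (i in which(!has_pred)) walk(i)

  # keep maximal chains only: a path that skips an insertable block is a
  # strict subset of some longer path
  chains <- unique(lapply(chains, sort))
  keep <- vapply(seq_along(chains), function(i) {
    !any(vapply(seq_along(chains), function(j) {
      j != i && length(chains[[j]]) > length(chains[[i]]) &&
        all(chains[[i]] %in% chains[[j]])
    }, logical(1)))
  }, logical(1))
  chains <- chains[keep]

  out <- lapply(chains, function(idx) {
    b <- blocks[idx, , drop = FALSE]
    gaps <- if (nrow(b) > 1) b$start[-1] - b$end[-nrow(b)] - 1L else integer(0)
    allowed <- rep(gap_threshold, length(gaps))
    if (!is.null(exon_lengths) && nrow(b) > 1) {
      for (g in seq_along(gaps)) {
        lo <- min(b$exon[g], b$exon[g + 1L])
        hi <- max(b$exon[g], b$exon[g + 1L])
        if (hi - lo > 1L)
          allowed[g] <- allowed[g] + sum(exon_lengths[(lo + 1L):(hi - 1L)])
      }
    }
    list(blocks = b, gaps = gaps,
         max_gap = if (length(gaps)) max(gaps) else 0L,
         intronless = all(gaps <= allowed),
         strand = b$strand[1], n_exons = length(unique(b$exon)))
  })
  out[order(vapply(out, function(x) -x$n_exons, numeric(1)))]
}

#' Classify a chained candidate copy
#'
#' An intronless chain covering at least `min_exons` exons is a retrocopy —
#' labeled `"retrocopy"` when expression evidence exists and
#' `"processed-pseudogene"` when silent. A chain with intron-scale gaps that
#' retains the full exon complement is a `"tandem-duplicate"`; anything
#' covering fewer than `min_exons` exons is a `"fragment"`.
#'
#' @param chain One chain from [chain_blocks()].
#' @param expression_hits Optional `hit_profile` from discriminating probes
#'   specific to the candidate copy; `NULL` means no expression evidence was
#'   collected.
#' @param expression_ratio Optional percent ratio from
#'   [paralog_expression_ratio()].
#' @param n_parent_exons Exon count of the parent gene.
#' @param min_exons Minimum exon coverage for a retrocopy call (tolerates
#'   decayed terminal exons).
#' @return An object of class `retrocopy_call`: list with `blocks`,
#'   `intronless`, `max_gap_observed`, `expressed`, `expression_ratio`,
#'   `classification`, `span`.
#' @export
classify_retrocopy <- function(chain, expression_hits = NULL,
                               expression_ratio = NA_real_,
                               n_parent_exons, min_exons = 4L) {
  if (is.null(chain) || nrow(chain$blocks) == 0) stop("empty chain")
  expressed <- !is.null(expression_hits) && sum(expression_hits$hit_count) > 0
  classification <- if (chain$n_exons < min_exons) {
    "fragment"
  } else if (chain$intronless) {
    if (expressed) "retrocopy" else "processed-pseudogene"
  } else if (chain$n_exons == n_parent_exons) {
    "tandem-duplicate"
  } else {
    "fragment"
  }
  structure(
    list(blocks = chain$blocks, intronless = chain$intronless,
         max_gap_observed = chain$max_gap,
         expressed = expressed,
         expression_ratio = if (expressed) expression_ratio else NA_real_,
         classification = classification,
         span = c(min(chain$blocks$start), max(chain$blocks$end))),
    class = "retrocopy_call"
  )
}

#' @export
print.retrocopy_call <- function(x, ...) {
  cat(sprintf("%s: %d block(s) over [%d, %d], max gap %d nt%s%s\n",
              x$classification, nrow(x$blocks), x$span[1], x$span[2],
              x$max_gap_observed,
              if (x$expressed) ", expressed" else ", silent",
              if (!is.na(x$expression_ratio))
                sprintf(" (%.1f%% of parent)", x$expression_ratio) else ""))
  invisible(x)
}

#' One-call retrocopy detector
#'
#' Scans a genome for intronless co-linear copies of a parent gene's exons,
#' chains the blocks, and classifies the best chain. Returns `NULL` when no
#' homology blocks are found outside the parent span.
#'
#' @param genome Genome string.
#' @param exon_sequences Parent exon sequences in order.
#' @param parent_span `c(start, end)` of the parent gene (excluded from the
#'   scan).
#' @param gap_threshold Intronless gap threshold (nt).
#' @param ... Passed to [exon_homology_scan()].
#' @inheritParams classify_retrocopy
#' @return A `retrocopy_call` or `NULL`.
#' @export
detect_retrocopy <- function(genome, exon_sequences, parent_span,
                             gap_threshold = 50L, expression_hits = NULL,
                             expression_ratio = NA_real_, ...) {
  blocks <- exon_homology_scan(exon_sequences, genome,
                               exclude_span = parent_span, ...)
  if (nrow(blocks) == 0) return(NULL)
  chains <- chain_blocks(blocks, gap_threshold = gap_threshold,
                         exon_lengths = nchar(unlist(exon_sequences)))
  if (length(chains) == 0) return(NULL)
  classify_retrocopy(chains[[1]], expression_hits = expression_hits,
                     expression_ratio = expression_ratio,
                     n_parent_exons = length(exon_sequences))
}
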