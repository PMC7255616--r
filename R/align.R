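#' Scoring schemes for pairwise alignment
#'
#' DNA scoring mirrors megablast-style parameters (match +1, mismatch -3, gap
#' open 5, gap extend 2); protein scoring uses BLOSUM62 with gap open 10 and
#' gap extend 0.5. A gap run of length L costs `gap_open + L * gap_extend`.
#'
#' @param type `"dna"` or `"protein"`.
#' @param match,mismatch DNA match/mismatch scores (ignored for protein).
#' @param gap_open,gap_extend Gap penalties (positive numbers).
#' @return A list with `matrix` (named scoring matrix), `gap_open`,
#'   `gap_extend` and `type`.
#' @export
scoring_scheme <- function(type = c("dna", "protein"), match = 1,
                           mismatch = -3, gap_open = NULL, gap_extend = NULL) {
  type <- match.arg(type)
  if (type == "dna") {
    alpha <- c("A", "C", "G", "T", "N")
    smat <- matrix(mismatch, 5, 5, dimnames = list(alpha, alpha))
    diag(smat) <- match
    smat["N", ] <- mismatch
    smat[, "N"] <- mismatch
    list(matrix = smat, gap_open = gap_open %||% 5,
         gap_extend = gap_extend %||% 2, type = "dna")
  } else {
    smat <- get_blosum62()
    list(matrix = smat, gap_open = gap_open %||% 10,
         gap_extend = gap_extend %||% 0.5, type = "protein")
  }
}

get_blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62
  storage.mode(m) <- "double"
  m
}

guess_type <- function(x) {
  if (grepl("^[ACGTN]+$", toupper(x))) "dna" else "protein"
}

check_alphabets <- function(a, b) {
  ta <- guess_type(a); tb <- guess_type(b)
  if (ta != tb)
    stop("mixed alphabets: one sequence looks like ", ta,
         ", the other like ", tb)
  ta
}

#' Optimal global alignment (Needleman-Wunsch with affine gaps)
#'
#' Deterministic traceback: match/mismatch is preferred over a gap, and a gap
#' in `a` over a gap in `b`.
#'
#' @param a,b Sequences (both DNA or both protein; mixed alphabets error).
#' @param scoring A [scoring_scheme()]; inferred from the alphabet when `NULL`.
#' @return An object of class `pairwise_alignment`: list with `aligned_a`,
#'   `aligned_b`, `score`, `identities`, `aligned_length`, `mode`.
#' @export
global_align <- function(a, b, scoring = NULL) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("sequences must be non-empty")
  a <- toupper(a); b <- toupper(b)
  type <- check_alphabets(a, b)
  scoring <- scoring %||% scoring_scheme(type)
  res <- gotoh_global_cpp(a, b, scoring$matrix, scoring$gap_open,
                          scoring$gap_extend)
  structure(c(res, list(mode = "global")), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("%s alignment: score %.1f, %d/%d identities\n",
              x$mode, x$score, x$identities, x$aligned_length))
  w <- 60L
  for (o in seq(1L, x$aligned_length, by = w)) {
    cat(substr(x$aligned_a, o, min(o + w - 1L, x$aligned_length)), "\n")
    cat(substr(x$aligned_b, o, min(o + w - 1L, x$aligned_length)), "\n\n")
  }
  invisible(x)
}

#' Percent identity of an alignment
#'
#' `100 * identities / aligned_length`, rounded to one decimal, with the
#' difference count (`aligned_length - identities`).
#'
#' @param alignment A `pairwise_alignment`.
#' @return An object of class `identity_result`: list with `percent_identity`,
#'   `matched_span`, `differences`, `no_match` (FALSE here).
#' @export
percent_identity <- function(alignment) {
  if (alignment$aligned_length == 0) stop("zero-length alignment")
  structure(
    list(percent_identity = round(100 * alignment$identities /
                                    alignment$aligned_length, 1),
         matched_span = alignment$aligned_length,
         differences = alignment$aligned_length - alignment$identities,
         no_match = FALSE),
    class = "identity_result"
  )
}

#' @export
print.identity_result <- function(x, ...) {
  if (x$no_match) cat("no match\n")
  else cat(sprintf("%.1f%% identity over %d columns (%d differences)\n",
                   x$percent_identity, x$matched_span, x$differences))
  invisible(x)
}

#' Best local alignment block (Smith-Waterman with affine gaps)
#'
#' Finds the highest-scoring local block of `query` in `target` and reports its
#' identity and span, the "percent (span bp)" convention of partial-exon
#' comparisons. The block is located with a linear-memory forward/backward
#' score pass; the block substrings are then aligned with full traceback.
#' `no_match` is set when the block score falls below `min_score` or its span
#' below `min_span` — the operational stand-in for a database e-value in a
#' single-pair setting (defaults calibrated so random 100-nt queries against
#' random 2-kb targets virtually never match).
#'
#' @param query,target Sequences.
#' @param scoring A [scoring_scheme()]; inferred when `NULL`.
#' @param min_score,min_span No-match thresholds.
#' @return An `identity_result` with additional fields `score`, `start_query`,
#'   `end_query`, `start_target`, `end_target`, `aligned_a`, `aligned_b`.
#' @export
local_best_block <- function(query, target, scoring = NULL,
                             min_score = 30, min_span = 30) {
  if (nchar(query) == 0 || nchar(target) == 0)
    stop("sequences must be non-empty")
  query <- toupper(query); target <- toupper(target)
  type <- check_alphabets(query, target)
  scoring <- scoring %||% scoring_scheme(type)

  fwd <- sw_score_cpp(query, target, scoring$matrix, scoring$gap_open,
                      scoring$gap_extend)
  no_match <- structure(
    list(percent_identity = NA_real_, matched_span = NA_integer_,
         differences = NA_integer_, no_match = TRUE, score = fwd$score),
    class = "identity_result")
  if (fwd$score < min_score) return(no_match)

  # locate block start by aligning the reversed prefixes ending at the best cell
  qa <- substr(query, 1, fwd$end_a)
  tb <- substr(target, 1, fwd$end_b)
  rev1 <- paste(rev(strsplit(qa, "")[[1]]), collapse = "")
  rev2 <- paste(rev(strsplit(tb, "")[[1]]), collapse = "")
  bwd <- sw_score_cpp(rev1, rev2, scoring$matrix, scoring$gap_open,
                      scoring$gap_extend)
  sq <- fwd$end_a - bwd$end_a + 1L
  st <- fwd$end_b - bwd$end_b + 1L

  blk <- gotoh_global_cpp(substr(query, sq, fwd$end_a),
                          substr(target, st, fwd$end_b),
                          scoring$matrix, scoring$gap_open, scoring$gap_extend)
  if (blk$aligned_length < min_span) return(no_match)
  structure(
    list(percent_identity = round(100 * blk$identities / blk$aligned_length, 1),
         matched_span = blk$aligned_length,
         differences = blk$aligned_length - blk$identities,
         no_match = FALSE,
         score = fwd$score,
         start_query = sq, end_query = fwd$end_a,
         start_target = st, end_target = fwd$end_b,
         aligned_a = blk$aligned_a, aligned_b = blk$aligned_b),
    class = "identity_result"
  )
}

#' Exon-by-exon identity table
#'
#' Compares each species' exon sequences against the reference exons,
#' rendering each cell as the published tables do: a bare percent when the
#' matched block covers the full reference exon, `"percent (span bp)"` for a
#' partial block, `"no match"` below threshold, and `"no exon"` where the
#' species lacks the exon.
#'
#' @param reference_exons Named or ordered list/character vector of reference
#'   exon sequences.
#' @param species_exons Named list (one entry per species) of exon lists; use
#'   `NA`/`NULL` entries for missing exons.
#' @param mode `"local"` (best block, the default) or `"global"`.
#' @param scoring Optional [scoring_scheme()].
#' @param min_score,min_span No-match thresholds for local mode.
#' @return A data.frame of formatted cells (rows = species, columns =
#'   reference exons); the raw `identity_result`s are in attribute `"results"`.
#' @export
exon_identity_table <- function(reference_exons, species_exons,
                                mode = c("local", "global"), scoring = NULL,
                                min_score = 30, min_span = 30) {
  mode <- match.arg(mode)
  nex <- length(reference_exons)
  exon_names <- names(reference_exons) %||% paste0("exon", seq_len(nex))
  if (is.null(names(reference_exons))) names(reference_exons) <- exon_names
  results <- list()
  rows <- lapply(names(species_exons), function(sp) {
    cells <- character(nex)
    for (i in seq_len(nex)) {
      other <- species_exons[[sp]][[i]]
      if (is.null(other) || length(other) == 0 ||
          (length(other) == 1 && is.na(other))) {
        cells[i] <- "no exon"
        next
      }
      if (mode == "local") {
        r <- local_best_block(other, reference_exons[[i]], scoring = scoring,
                              min_score = min_score, min_span = min_span)
        results[[paste(sp, exon_names[i])]] <<- r
        if (r$no_match) {
          cells[i] <- "no match"
        } else if (r$matched_span >= nchar(reference_exons[[i]])) {
          cells[i] <- sprintf("%.1f", r$percent_identity)
        } else {
          cells[i] <- sprintf("%.1f (%d bp)", r$percent_identity,
                              r$matched_span)
        }
      } else {
        r <- percent_identity(global_align(other, reference_exons[[i]],
                                           scoring = scoring))
        results[[paste(sp, exon_names[i])]] <<- r
        cells[i] <- sprintf("%.1f", r$percent_identity)
      }
    }
    cells
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- exon_names
  out <- cbind(data.frame(species = names(species_exons),
                          stringsAsFactors = FALSE), out)
  attr(out, "results") <- results
  out
}

#' Protein identity table
#'
#' Globally aligns each protein to the reference and reports length, percent
#' identity (one decimal) and the number of differences; for small difference
#' counts the differences are listed positionally (reference coordinates) in
#' `"X7>A; ..."` form.
#'
#' @param reference_protein Reference protein sequence.
#' @param others Named list/character vector of protein sequences.
#' @param max_listed List positions only when the difference count is at most
#'   this many.
#' @return A data.frame with `species`, `length`, `percent_identity`,
#'   `n_differences`, `differences`.
#' @export
protein_identity_table <- function(reference_protein, others, max_listed = 6L) {
  if (nchar(reference_protein) == 0) stop("empty reference protein")
  rows <- lapply(names(others) %||% paste0("seq", seq_along(others)),
                 function(nm) {
    p <- others[[nm]]
    if (is.null(p) || nchar(p) == 0) stop("empty protein for ", nm)
    aln <- global_align(reference_protein, p, scoring_scheme("protein"))
    idr <- percent_identity(aln)
    diffs <- ""
    if (idr$differences <= max_listed && idr$differences > 0) {
      ca <- strsplit(aln$aligned_a, "")[[1]]
      cb <- strsplit(aln$aligned_b, "")[[1]]
      ref_pos <- cumsum(ca != "-")
      idx <- which(ca != cb)
      diffs <- paste(vapply(idx, function(i) {
        sprintf("%s%d>%s", ifelse(ca[i] == "-", "-", ca[i]),
                ref_pos[i], ifelse(cb[i] == "-", "-", cb[i]))
      }, character(1)), collapse = "; ")
    }
    data.frame(species = nm, length = nchar(p),
               percent_identity = idr$percent_identity,
               n_differences = idr$differences,
               differences = diffs, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Neighbor-joining guide tree
#'
#' Standard neighbor joining on a distance matrix, recording the join order
#' (used as the progressive-alignment guide) and branch lengths.
#'
#' @param d A symmetric distance matrix (or `dist`) with labels.
#' @return A list with `merges` (list of joins: each has `left`, `right`
#'   cluster member indices) and `edge_lengths`.
#' @export
nj_guide_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least two sequences")
  labels <- rownames(d) %||% paste0("s", seq_len(n))
  active <- seq_len(n)
  members <- as.list(seq_len(n)) # tip indices per active cluster
  merges <- list()
  edge_lengths <- list()
  D <- d
  while (length(active) > 2) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    vi <- 0.5 * Dm[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- Dm[i, j] - vi
    ai <- active[i]; aj <- active[j]
    # new cluster takes slot ai
    new_d <- 0.5 * (D[ai, active] + D[aj, active] - D[ai, aj])
    D[ai, active] <- new_d
    D[active, ai] <- new_d
    D[ai, ai] <- 0
    merges[[length(merges) + 1L]] <- list(left = members[[ai]],
                                          right = members[[aj]])
    edge_lengths[[length(edge_lengths) + 1L]] <- c(vi, vj)
    members[[ai]] <- c(members[[ai]], members[[aj]])
    active <- setdiff(active, aj)
  }
  if (length(active) == 2) {
    ai <- active[1]; aj <- active[2]
    merges[[length(merges) + 1L]] <- list(left = members[[ai]],
                                          right = members[[aj]])
    edge_lengths[[length(edge_lengths) + 1L]] <-
      c(D[ai, aj] / 2, D[ai, aj] / 2)
  }
  list(merges = merges, edge_lengths = edge_lengths, labels = labels)
}

# fractional-identity distance matrix from pairwise global alignments
identity_distance_matrix <- function(seqs, scoring = NULL) {
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- global_align(seqs[[i]], seqs[[j]], scoring)
      d[i, j] <- d[j, i] <- 1 - aln$identities / aln$aligned_length
    }
  }
  d
}

# profile-profile global alignment: columns scored by the mean pairwise
# substitution score; gap characters score -gap_extend against residues
align_profiles <- function(profA, profB, smat, gap_open, gap_ext) {
  La <- nchar(profA[1]); Lb <- nchar(profB[1])
  A <- do.call(rbind, strsplit(profA, ""))
  B <- do.call(rbind, strsplit(profB, ""))
  col_score <- function(i, j) {
    sa <- A[, i]; sb <- B[, j]
    tot <- 0; k <- 0
    for (x in sa) for (y in sb) {
      k <- k + 1
      tot <- tot + if (x == "-" || y == "-") {
        if (x == "-" && y == "-") 0 else -gap_ext
      } else smat[x, y]
    }
    tot / k
  }
  S <- matrix(0, La, Lb)
  for (i in seq_len(La)) for (j in seq_len(Lb)) S[i, j] <- col_score(i, j)

  NEG <- -1e18
  M <- matrix(NEG, La + 1, Lb + 1); X <- M; Y <- M
  TM <- matrix(0L, La + 1, Lb + 1); TX <- TM; TY <- TM
  M[1, 1] <- 0
  for (i in seq_len(La)) { X[i + 1, 1] <- -(gap_open + gap_ext * i); TX[i + 1, 1] <- ifelse(i == 1, 0L, 2L) }
  for (j in seq_len(Lb)) { Y[1, j + 1] <- -(gap_open + gap_ext * j); TY[1, j + 1] <- ifelse(j == 1, 0L, 1L) }
  for (i in seq_len(La)) {
    for (j in seq_len(Lb)) {
      cands <- c(M[i, j], Y[i, j], X[i, j])
      k <- which.max(cands)
      M[i + 1, j + 1] <- cands[k] + S[i, j]; TM[i + 1, j + 1] <- k - 1L
      cands <- c(M[i, j + 1] - gap_open - gap_ext,
                 Y[i, j + 1] - gap_open - gap_ext,
                 X[i, j + 1] - gap_ext)
      k <- which.max(cands)
      X[i + 1, j + 1] <- cands[k]; TX[i + 1, j + 1] <- k - 1L
      cands <- c(M[i + 1, j] - gap_open - gap_ext,
                 Y[i + 1, j] - gap_ext,
                 X[i + 1, j] - gap_open - gap_ext)
      k <- which.max(cands)
      Y[i + 1, j + 1] <- cands[k]; TY[i + 1, j + 1] <- k - 1L
    }
  }
  i <- La; j <- Lb
  state <- which.max(c(M[i + 1, j + 1], Y[i + 1, j + 1], X[i + 1, j + 1])) - 1L
  pa <- integer(0); pb <- integer(0) # 0 marks gap column
  while (i > 0 || j > 0) {
    if (state == 0L) {
      nb <- TM[i + 1, j + 1]; pa <- c(i, pa); pb <- c(j, pb)
      i <- i - 1; j <- j - 1; state <- nb
    } else if (state == 2L) {
      nb <- TX[i + 1, j + 1]; pa <- c(i, pa); pb <- c(0L, pb)
      i <- i - 1; state <- nb
    } else {
      nb <- TY[i + 1, j + 1]; pa <- c(0L, pa); pb <- c(j, pb)
      j <- j - 1; state <- nb
    }
  }
  outA <- vapply(seq_len(nrow(A)), function(r)
    paste(ifelse(pa == 0L, "-", A[r, pmax(pa, 1L)]), collapse = ""),
    character(1))
  outB <- vapply(seq_len(nrow(B)), function(r)
    paste(ifelse(pb == 0L, "-", B[r, pmax(pb, 1L)]), collapse = ""),
    character(1))
  c(outA, outB)
}

#' Progressive multiple sequence alignment
#'
#' Pairwise global alignments give a fractional-identity distance matrix; a
#' neighbor-joining guide tree orders profile-profile merges. A single
#' sequence is returned unchanged; two sequences reduce to [global_align()].
#'
#' @param sequences Named character vector (>= 1 sequence, all DNA or all
#'   protein).
#' @param scoring Optional [scoring_scheme()].
#' @return A named character vector of aligned (gapped) sequences, all equal
#'   length.
#' @export
progressive_msa <- function(sequences, scoring = NULL) {
  seqs <- as.list(sequences)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (length(seqs) == 1) return(setNames(toupper(unlist(seqs)), names(seqs)))
  seqs <- lapply(seqs, toupper)
  type <- guess_type(seqs[[1]])
  scoring <- scoring %||% scoring_scheme(type)
  if (length(seqs) == 2) {
    aln <- global_align(seqs[[1]], seqs[[2]], scoring)
    return(setNames(c(aln$aligned_a, aln$aligned_b), names(seqs)))
  }
  d <- identity_distance_matrix(seqs, scoring)
  guide <- nj_guide_tree(d)
  profiles <- lapply(seq_along(seqs), function(i)
    setNames(seqs[i], names(seqs)[i]))
  cluster_of <- seq_along(seqs)
  for (mg in guide$merges) {
    ca <- cluster_of[mg$left[1]]
    cb <- cluster_of[mg$right[1]]
    pa <- unlist(profiles[[ca]])
    pb <- unlist(profiles[[cb]])
    merged <- align_profiles(pa, pb, scoring$matrix, scoring$gap_open,
                             scoring$gap_extend)
    names(merged) <- c(names(pa), names(pb))
    profiles[[ca]] <- merged
    cluster_of[cluster_of == cb] <- ca
  }
  final <- unlist(profiles[[cluster_of[1]]])
  final[names(seqs)]
}
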