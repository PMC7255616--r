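#' Locus map constructor
#'
#' An ordered, oriented list of genes around an anchor gene — the unit of
#' microsynteny comparison.
#'
#' @param species Species label.
#' @param anchor Anchor gene name (must be present in `genes`).
#' @param genes Data.frame with `name`, `strand` and either `start`/`end`
#'   coordinates or a pre-established order.
#' @return An object of class `locus_map`.
#' @export
locus_map <- function(species, anchor, genes) {
  stopifnot(all(c("name", "strand") %in% names(genes)))
  if (!anchor %in% genes$name)
    stop("anchor '", anchor, "' not present in the gene list")
  if (all(c("start", "end") %in% names(genes))) {
    genes <- genes[order(genes$start), , drop = FALSE]
    if (nrow(genes) > 1 &&
        any(genes$start[-1] <= genes$end[-nrow(genes)]))
      stop("gene spans overlap within the locus map")
  }
  rownames(genes) <- NULL
  structure(list(species = species, anchor = anchor, genes = genes),
            class = "locus_map")
}

#' @export
print.locus_map <- function(x, ...) {
  cat(sprintf("locus map [%s], anchor %s:\n  %s\n", x$species, x$anchor,
              paste0(x$genes$name, "(", x$genes$strand, ")",
                     collapse = " - ")))
  invisible(x)
}

#' Build an anchored locus map from an annotation
#'
#' Selects genes whose spans intersect `anchor +/- window` and orders them by
#' coordinate. Orientation is anchor-normalized: when the anchor lies on the
#' minus strand the whole locus is mirrored (order reversed, strands flipped)
#' so the anchor reads `+`.
#'
#' @param annotation Data.frame with `name`, `strand`, `start`, `end` (or a
#'   `GRanges` with a `name` column).
#' @param anchor Anchor gene name.
#' @param window Window (nt) on each side of the anchor.
#' @param species Species label.
#' @return A `locus_map`.
#' @export
build_locus_map <- function(annotation, anchor, window, species = "unknown") {
  if (methods::is(annotation, "GRanges")) {
    annotation <- data.frame(
      name = annotation$name,
      strand = as.character(BiocGenerics::strand(annotation)),
      start = BiocGenerics::start(annotation),
      end = BiocGenerics::end(annotation),
      stringsAsFactors = FALSE)
  }
  if (window <= 0) stop("window must be positive")
  a <- annotation[annotation$name == anchor, , drop = FALSE]
  if (nrow(a) == 0) stop("anchor '", anchor, "' not found in the annotation")
  lo <- a$start[1] - window
  hi <- a$end[1] + window
  sel <- annotation[annotation$end >= lo & annotation$start <= hi, ,
                    drop = FALSE]
  sel <- sel[order(sel$start), , drop = FALSE]
  if (a$strand[1] == "-") {
    sel$strand <- ifelse(sel$strand == "+", "-", "+")
    c_max <- max(sel$end)
    new_start <- c_max - sel$end + 1L
    new_end <- c_max - sel$start + 1L
    sel$start <- new_start
    sel$end <- new_end
    sel <- sel[order(sel$start), , drop = FALSE]
  }
  locus_map(species = species, anchor = anchor, genes = sel)
}

canonical_names <- function(names, synonyms = NULL) {
  out <- tolower(names)
  if (!is.null(synonyms) && length(synonyms) > 0) {
    syn <- setNames(tolower(unname(synonyms)), tolower(names(synonyms)))
    hit <- out %in% names(syn)
    out[hit] <- syn[out[hit]]
  }
  out
}

#' Compare two locus maps
#'
#' Reports the shared gene set (names matched case-insensitively, optionally
#' through a synonym table collapsing paralog suffixes), whether the shared
#' genes occur in a congruent order (identical or whole-locus reversed),
#' orientation flips relative to the anchor, and the Jaccard fraction of
#' shared gene names.
#'
#' @param map_a,map_b `locus_map`s.
#' @param synonyms Named character vector mapping alternate names to canonical
#'   ones (e.g. `c(Lcp2a = "Lcp2")`).
#' @return An object of class `synteny_comparison`: list with `shared`,
#'   `order_congruent`, `orientation_flips`, `jaccard`.
#' @export
compare_loci <- function(map_a, map_b, synonyms = NULL) {
  stopifnot(inherits(map_a, "locus_map"), inherits(map_b, "locus_map"))
  na <- canonical_names(map_a$genes$name, synonyms)
  nb <- canonical_names(map_b$genes$name, synonyms)
  shared <- intersect(na, nb)
  union_n <- union(na, nb)
  jaccard <- if (length(union_n) == 0) 0 else length(shared) / length(union_n)

  order_congruent <- TRUE
  if (length(shared) > 1) {
    pa <- match(shared, na)
    pb <- match(shared, nb)
    ord <- order(pa)
    pb_in_a_order <- pb[ord]
    order_congruent <- all(diff(pb_in_a_order) > 0) ||
      all(diff(pb_in_a_order) < 0)
  }

  anchor_a <- canonical_names(map_a$anchor, synonyms)
  anchor_b <- canonical_names(map_b$anchor, synonyms)
  rel_strand <- function(genes, names_canon, anchor) {
    as <- genes$strand[match(anchor, names_canon)]
    ifelse(genes$strand == as, "same", "opposite")
  }
  flips <- character(0)
  if (anchor_a %in% na && anchor_b %in% nb) {
    ra <- rel_strand(map_a$genes, na, anchor_a)
    rb <- rel_strand(map_b$genes, nb, anchor_b)
    for (g in shared) {
      if (ra[match(g, na)] != rb[match(g, nb)]) {
        flips <- c(flips, map_a$genes$name[match(g, na)])
      }
    }
  }
  structure(list(shared = map_a$genes$name[match(shared, na)],
                 order_congruent = order_congruent,
                 orientation_flips = flips,
                 jaccard = jaccard),
            class = "synteny_comparison")
}

#' @export
print.synteny_comparison <- function(x, ...) {
  cat(sprintf("shared: %s\norder congruent: %s\norientation flips: %s\nJaccard: %.2f\n",
              paste(x$shared, collapse = ", "),
              x$order_congruent,
              if (length(x$orientation_flips))
                paste(x$orientation_flips, collapse = ", ") else "none",
              x$jaccard))
  invisible(x)
}
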