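---
title: "Characterizing a gene locus from annotation arithmetic and read evidence"
author: "locuskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a gene locus from annotation arithmetic and read evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locuskit)
```

## The problem

Comparative characterization of a single gene locus across species rests on a
handful of computations that are usually performed ad hoc: summing exon and
intron lengths into gene, mRNA and protein lengths; locating transcript 5' and
3' ends from RNA-seq read evidence when annotation lacks UTRs; detecting
poly(A) signals and cleavage sites; tabulating percent identity between
orthologous exons and proteins; recognizing intronless (retro-transposed)
gene copies; and comparing the gene order and orientation of the surrounding
locus. locuskit packages these steps as tested, reusable functions, together
with a synthetic-locus generator that provides ground truth for every one of
them. The worked organism setting is the vertebrate *Zmat2* gene — a compact,
6-exon spliceosomal-protein gene whose published structure tables provide
exact arithmetic test points — but every function is generic.

## Gene-model arithmetic and the published-row audit

A `gene_model` is an ordered list of exons with a UTR/coding partition on the
terminal exons (interior exons are fully coding), plus intron lengths. The
three derived lengths are

* gene length = sum of exons + introns,
* mRNA length = sum of exons,
* protein length = coding length / 3 − 1 (the stop codon is excluded).

The zebrafish-style reference model: exons 36/91/124/74/146/643 nt with
introns 978/503/85/1040/2684 nt, an 18-nt 5' UTR and 499-nt 3' UTR give a
6404-bp gene, a 1114-nt mRNA and a 597-nt CDS encoding 198 residues.

```{r arithmetic}
m <- assemble_model(c(36, 91, 124, 74, 146, 643),
                    c(978, 503, 85, 1040, 2684), utr5 = 18, utr3 = 499,
                    name = "zebrafish")
model_lengths(m)
```

`audit_gene_table()` recomputes every published structure row bundled in
`zmat2_gene_rows()` and flags rows whose printed total disagrees with the sum
of the printed parts. Three rows are internally inconsistent (chicken: printed
9159 bp vs computed 11028 bp, and printed mRNA 2452 nt vs computed 2448 nt;
tetraodon: 2337 vs 2449; duck: 8723 vs 8711). The audit reports both numbers
and does not guess intent; rows whose totals are printed as lower bounds
(">"), or whose gene has more exons than the row tabulates (tilapia), are
exempt from flagging since summation cannot audit them. Models whose coding
length fails divisibility by 3 (as the coelacanth row's printed UTR
annotations imply) are representable but marked non-translatable, so the audit
can hold inconsistent printed rows without rejecting them.

```{r audit}
audit <- audit_gene_table()
audit[which(audit$total_flagged | audit$mrna_flagged), 1:5]
```

## The synthetic locus generator

`simulate_gene()` embeds a forward-strand gene in a uniform-background (50%
GC) chromosome segment. Guarantees by construction: introns are GT..AG; the
CDS starts with ATG, ends with a stop and has no internal stop; the
configured poly(A) hexamer is planted with its 3' end exactly
`cleavage_offset` nt upstream of the cleavage position; the 3' search window
carries no competing accepted hexamer; and the transcript's final base and
the genomic base just downstream of the cleavage site are non-A, so the
cleavage position is unambiguous. Reverse-strand loci are obtained by
reverse-complementing the finished segment. Isoforms are defined as exon
subsets (`isoform_exon_sets`) sampled by `isoform_weights`.

`simulate_reads()` draws reads from the mature isoform sequences with
per-base substitution errors. Two deliberate departures from a plain uniform
model, both motivated by what end-mapping requires:

* **5' starts.** Under uniform starts, the expected 5'-most read start at
  20–50x depth sits 3–5 nt downstream of the true transcript start (order
  statistics of a few hundred uniform draws over ~1000 positions), so a
  ±2 nt recovery claim would be unattainable regardless of implementation.
  Libraries that inform 5' ends are 5'-enriched; the generator models this
  with a geometric decay of the start distribution (`five_prime_decay`,
  default 0 = uniform). End-mapping experiments in the tests and the
  acceptance script use decay 0.02/nt, i.e. a ~35-nt half-life, chosen from
  the order-statistics argument above.
* **3' tails.** `polya_tail_rate` is the fraction of reads that are
  3'-anchored: they span the cleavage junction and carry a non-genomic A-run
  of 5–20 nt (the oligo-dT-primed component of a library). Modeling tails as
  a property of uniformly placed reads instead would make visibly tailed
  reads ~0.5% of a library and exact cleavage recovery fragile at realistic
  depth. Uniform-coverage experiments (probe count calibration) set the rate
  to 0.

End-mapping experiments use 600 reads (~50x over the 1114-nt reference
transcript, read length 100 nt, error rate 0.1%): depth at which at least one
tailed junction read is present with probability ≈ 1 − 1e−5 per library.

What the generator does **not** model: library-prep sequence biases,
paired-end reads, indel errors, quality-score variation (FASTQ qualities are
a constant Q30), or genomic repeats. Passing tests therefore demonstrate
correctness of the computations under idealized read evidence, not robustness
to artifacts of real libraries.

## End mapping

`call_five_prime()` implements the longest-clone rule: the transcript 5'
boundary is the 5'-most region coordinate covered by any placed read. The
call is a lower bound ("at least" semantics) — more reads can only move it
further 5' — and single-read support is flagged low-confidence.

`call_three_prime()` strips each read's trailing A-run (≥ 5 nt), places the
core on the terminal-exon region, then re-extends the match end through
genomic As (tail As are indistinguishable from templated ones); a read is a
cleavage candidate only if ≥ 5 non-genomic As remain. The cleavage position
is the 3'-most candidate. When no tailed read exists the call degrades to the
3'-most covered coordinate at low confidence. The accepted hexamer set is
{AATAAA, ATTAAA, ATTTTA} — the canonical signal plus the two variants
reported at the study loci — and the closest accepted hexamer within 40 nt
upstream of the cleavage site is reported with its offset. The 40-nt window
is the typical signal-to-site spacing; the planted offsets recovered in the
tests are 8 and 12 nt.

Read placement everywhere uses an exact 11-mer seed followed by ungapped
mismatch-bounded verification (≤ 2 mismatches by default), the regime
appropriate for near-identical sequences; gap costs are irrelevant because
probes and reads are near-identical to their source by construction.
`count_probe_hits()` requires the full probe inside a read — this makes the
analytic coverage expectation exact (reads covering a 60-mer at uniform
depth) and is the counting convention behind per-probe bar graphs. Boundary
calling instead clips the overlap at region edges so junction-spanning reads
still anchor their within-region part.

## Probes

`tile_probes()` produces abutting 60-mers by default (step = probe length,
labels a, b, c, ...), configurable down to step 1; the published figures'
lettered segments are reproduced by the default. `discriminating_probes()`
globally aligns two paralogous sequences and returns windows differing at
≥ 3 aligned positions — with ≤ 2-mismatch read matching, 3 differences
guarantee paralog specificity. Window selection equals a brute-force scan
(tested exhaustively up to 500 nt).

## Alignment and identity tables

The aligners are affine-gap Gotoh dynamic programs (compiled): global
(Needleman–Wunsch) with deterministic tie-breaking (match/mismatch over gap,
gap in the first sequence over gap in the second), and best-local-block
(Smith–Waterman) reported as "percent (span bp)". DNA scoring is match +1 /
mismatch −3 / gap open 5 / extend 2; protein scoring is BLOSUM62 with open
10 / extend 0.5. A gap run of length L costs open + L·extend. Since no
database context exists, no e-values are computed; "no match" is
operationalized as block score < 30 or span < 30 nt, a threshold calibrated
on the random-sequence null (random 100-nt vs 2-kb pairs essentially never
match; a tested property). The large-target local search runs a linear-memory
score-only pass forward and backward to locate the block, then re-aligns the
block substrings with full traceback.

Percent identity is 100 × identities / aligned columns, rounded to one
decimal — the convention that renders 173/193 as 89.6 and 192/193 as 99.5.
Protein tables list small difference sets positionally in reference
coordinates ("T7>A").

`progressive_msa()` builds pairwise fractional-identity distances, a
neighbor-joining guide tree (verified against the closed-form 3-taxon
solution and an independent NJ implementation), and merges profiles with a
mean-pairwise-score profile aligner. It is a minimal progressive aligner: no
sequence weighting or iterative refinement.

## Retrocopy detection

`exon_homology_scan()` reports the best local block per exon per strand
outside the (masked) parent span, above identity/span/score thresholds.
`chain_blocks()` enumerates every maximal co-linear same-strand chain
(exon indices strictly increasing left-to-right, or decreasing on the minus
strand); chaining equals exhaustive maximal-chain enumeration on ≤ 10 blocks
(a tested property). A chain is intronless when every inter-block gap is at
most 50 nt — parent introns (85–23430 bp in the published rows) are orders of
magnitude above this — with one refinement: when parent exon lengths are
supplied, the allowed gap between blocks of exons i and j also includes the
summed length of skipped exons, because an undetected short exon (a 36-nt
exon 1 at 5–10% divergence routinely falls below the score threshold) still
occupies its sequence inside the copy. Classification: an intronless chain
covering ≥ 4 exons is a retrocopy — "retrocopy" when discriminating probes
register expression, "processed-pseudogene" when silent; a full-complement
chain with intron-scale gaps is a tandem duplicate; fewer than 4 exons is a
fragment. The ≥ 4-exon rule tolerates decayed terminal exons without
requiring a perfect copy.

## Synteny

A locus map is an ordered, oriented gene list around an anchor;
`build_locus_map()` normalizes orientation so the anchor reads `+`
(mirroring the locus when it does not). `compare_loci()` reports the shared
gene set (names matched case-insensitively through an optional synonym table,
e.g. Lcp2a ≡ Lcp2), order congruence on the shared subset (identical or
whole-locus reversed; insertions of non-shared genes do not break it),
orientation flips relative to the anchor, and the Jaccard fraction.
Distances are never compared — only content, order and orientation.

## Numerical and interface choices

* Internal sequence coordinates are 1-based closed (R convention); GFF3 is
  emitted 1-based closed and BED 0-based half-open, with the conversion
  centralized in `bed_to_gff_coords()`/`gff_to_bed_coords()`.
* All randomness in a pipeline run derives from one seed via fixed per-stage
  substreams; two runs with the same seed produce byte-identical tables.
  Output TSVs carry the seed and a configuration hash in a header comment.
* Problem sizes in the test-suite and acceptance script: 20-seed recovery
  loops for end mapping and retrocopy detection on 12–20-kb chromosome
  segments, paralog-ratio recovery at 1e5 reads, a 200-pair exhaustive-oracle
  panel for the global aligner (lengths ≤ 6; the alignment enumeration grows
  super-exponentially beyond that), and 30 random block sets for chaining.
* Non-ATG-start proteins (annotated without an amino-terminal methionine) are
  translated only under an explicit override flag.

## Limitations

Reads are matched against region and transcript sequences, never
spliced-aligned to the genome; counts are raw (no cross-library
normalization), as in the per-probe bar-graph convention; the progressive
aligner is a guide-tree profile merger, not a ClustalW-class tool; and the
retrocopy detector does not scan insertion flanks for poly(A) tracts or
target-site duplications, nor date insertions.
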