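---
title: "BAC tiling paths, dotplot structural comparison and MHC class I classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BAC tiling paths, dotplot structural comparison and MHC class I classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bactile)
```

## The problem

Physical maps of complex genomic regions -- the major histocompatibility
complex (MHC) is the canonical example -- are built from overlapping
large-insert clones (BACs, roughly 100-200 kb each).  Getting the map right
requires four analyses that this package automates as one tested pipeline:

1. **Pairwise overlap detection.**  Which clone ends share sequence, in
   which relative orientation, and where exactly do the overlaps begin and
   end?
2. **Tiling-path construction.**  Orient the clones consistently, order them
   into contigs from the overlap geometry, and call the gaps that separate
   contigs.
3. **Dotplot structural comparison.**  Compare clones with each other and
   with a reference chromosome to call indels, inversions, interspersed
   repeats, artefacts caused by runs of undefined nucleotides, and clone
   misassemblies such as a displaced terminal segment.
4. **MHC class I classification.**  Annotate predicted class I proteins
   (signal peptide, α1/α2/α3, transmembrane, cytoplasmic tail) and label
   each locus classical (Ia) or nonclassical (Ib).

The sheep MHC class I region is the motivating case: re-analysis of a
published 20-BAC clone set shows the region is not one contiguous map but
several contigs separated by gaps, contains an apparent large segmental
inversion relative to the reference chromosome, and carries a clone whose
first few hundred bases were misassembled from sequence that truly
originates tens of kilobases downstream.  Every one of those phenomena is a
first-class, testable object here.

## Overlap detection by exact-word anchoring

All sequence comparison in the package is built on one primitive: **exact
word matches** of a fixed length (default `word_length = 30`, the word size
used for Gepard-style dotplots of BAC sequences).  Words containing `N`
never match, so ambiguity runs cannot fake homology.  Maximal exact matches
(anchors) are found in both orientations by a hash join on words; on small
inputs the engine is tested for exact equality against a brute-force
all-words comparison.

Anchors are chained by dynamic programming into the highest-coverage
strictly collinear chain per orientation (reverse-orientation anchors are
pre-flipped into reverse-complement coordinates so chaining is always
monotone).  Chains break where the inter-anchor gap exceeds `max_gap`
(default 6,000 bp -- large enough to bridge multi-kb N-runs in a reference)
or the diagonal drifts by more than `max_diag_drift` (default 300 bp).

A chain becomes an **overlap call** only if it is *dovetail-compatible*:
after orientation normalisation it must reach the facing ends of both clones
within `end_slack` (default 500 bp).  Because no numeric thresholds for
"an overlap" exist in the original analyses (they were manual BLAST +
alignment-editor judgements), the defaults

* `min_overlap` = 1,000 bp,
* `min_identity` = 0.95,
* `end_slack` = 500 bp

are this package's own calibration, chosen to accept true dovetails between
clones of the same haplotype while rejecting internal repeat matches; all
are exposed in `overlap_params()`.  Chain boundaries are refined by greedy
ungapped extension that stops when identity in a trailing 50-bp window
drops below 0.8 -- a stated, reproducible stand-in for manual alignment
editing.

One deliberate asymmetry: a *non-matching terminal segment* of up to
`prefix_slack` (default 1,000 bp) does **not** veto an otherwise-dovetail
overlap.  It is annotated as a *suspect terminus* instead.  This is exactly
the signature of a terminal misassembly -- a clone whose first few hundred
bases belong elsewhere would otherwise break its junction and split the
contig.

## Tiling paths

Orientations are propagated by breadth-first traversal of a spanning forest
of the overlap graph (each component's seed clone is taken forward); any
non-tree edge that contradicts the propagation is logged as a conflict and
excluded, never fatal.  Offsets come from dovetail geometry: two clones
sharing an overlap satisfy `offset_b = offset_a + (a_start - b_start)` in
oriented coordinates, and all non-tree edges must agree within
`word_length - 1` bp.  Connected components become contigs; clones are
ordered by offset.

Without external information a tiling path is only defined up to a flip of
each whole contig, and contig order is arbitrary (the package uses
decreasing span, deterministically, and labels the order as arbitrary).
Projecting contigs onto a reference chromosome (`project_contigs()` +
`apply_reference_orientation()`) fixes both: contigs are re-ordered by
projected position and flipped where their internal direction opposes the
reference, yielding a consistent telomeric-to-centromeric map.  Gap sizes
are estimated only from reference projection (distance between projected
intervals); without a reference a gap's size is reported unknown.

## Dotplot structural-event calling

`dotplot_matrix()` computes the sparse set of word matches;
`diagonal_segments()` collapses them into maximal same-diagonal runs of at
least `min_segment_words` (default 5) words, merging across within-diagonal
gaps up to `max_diagonal_gap` (default 2,000 bp).  Substitutions thin a
diagonal but do not move it; only true indels shift it.  Event calling then
reads the geometry:

* **Indel**: consecutive main-chain segments whose diagonal offset changes
  by Δ ≠ 0; size `|Δ|`, signed so insertions in either sequence are
  distinguishable.
* **N-run artefact**: an indel whose spanned region is at least half
  undefined nucleotides -- small diagonal breaks frequently trace back to
  N-runs in a reference rather than to real variation, so these are
  reclassified rather than reported as biology.
* **Inversion**: reverse-orientation segments embedded between forward
  main-chain segments; size is the reverse span.
* **Interspersed repeat**: same-orientation segments overlapping in one
  axis at distinct offsets (parallel diagonals).
* **Unaligned terminus / displaced segment**: a terminal region of at least
  `min_terminus` (default 1,000 bp) with no main-chain alignment; if it is
  covered by off-chain segments aligning elsewhere it becomes a displaced
  segment with its displacement distance, the misassembly signature.

`self_consistency_scan()` applies the same logic to a clone against itself
with the trivial diagonal masked: a displaced prefix shows up as terminal
segments matching downstream, split displaced prefixes (interrupted by an
N-run) are grouped into one event, and internal duplications appear as
interspersed repeats.

The main chain is the maximum-word-count collinear chain of forward
segments.  All dotplot thresholds live in `dotplot_params()`; since the
word-match primitive cannot resolve boundaries finer than one word, every
truth-recovery claim in the tests carries a tolerance of
`word_length - 1 = 29` bp.

## Class I classification

The classification rule is the standard ruminant criterion: a locus with an
identifiable transmembrane (TM) and cytoplasmic domain is **nonclassical
(Ib)** if a `VPI`, `IPI` or `VLIK` motif occurs within the TM span (± 2
residues) *or* the cytoplasmic tail is truncated; otherwise it is
**classical (Ia)**.  A protein without a detectable TM or tail is
unclassified.  "Truncated" has no published residue cutoff; the package
uses `truncated_tail_max = 20` residues against canonical class I tails of
roughly 28-33, configurable in `class1_config()`.

The supporting annotations are deliberately simple, stated heuristics
rather than re-implementations of trained predictors:

* **Signal peptide**: within residues 1-35, a hydrophobic core (best
  7-residue window with mean Kyte-Doolittle hydropathy ≥ 1.5, extended
  while flanking residues stay above 1.5) preceded within 10 residues by a
  positively charged residue; cleavage at the first small residue
  (A/G/S/C) at least 3 positions past the core.
* **Transmembrane domain**: best 19-residue window with mean hydropathy
  ≥ 1.6 (ties resolve to the earlier window), extended while per-residue
  hydropathy stays positive.
* **Domain boundaries (α1/α2/α3 etc.)**: global alignment (BLOSUM62,
  affine gaps) of the query to the best-matching member of a bundled
  reference panel, with the panel's marked boundaries projected through
  alignment columns; a projected domain under 40% identity is flagged
  `weak_match`, and a best alignment under 20% identity yields an all-`NA`
  annotation.

The bundled panel (`inst/extdata/class1_reference_panel_synthetic.*`) is
**synthetic**: eight variants of the package's consensus class I scaffold
with marked boundaries.  It stands in for a curated alignment of real class
I loci, which users can supply via `load_class1_references()` -- the
projection machinery is identical either way.

## The synthetic-data generators

Every stage is validated against generators whose outputs carry complete
ground truth (`make_chromosome()`, `simulate_clone_set()`,
`inject_structural_event()`, `make_class1_proteins()`), all pure functions
of their parameters and a mandatory seed.

Design choices, made once:

* Background chromosome sequence is i.i.d. uniform over ACGT.  Repeat
  copies and loci are planted intervals; repeat copies diverge by per-site
  substitution (default 2%, so copies stay well above 85% pairwise
  identity).  This is sufficient to exercise anchoring, chaining and
  repeat/inversion geometry; it does not model coalescent structure,
  sequencing error, GC bias or real repeat families, so passing tests
  demonstrate algorithmic correctness on the stated signal model, not
  performance on real BAC data.
* Clone-level noise is per-site substitution at 0.5%, a realistic scale for
  re-assembled clones of one haplotype, keeping true overlap identity near
  0.99 against the 0.95 acceptance threshold.
* The canonical integration fixture (`simulate_tiling_fixture()`) mirrors
  the study design at reduced scale: 20 clones of 6 kb over a ~100-kb
  chromosome, 2-kb overlaps, 5 designated gaps of 2.5 kb (hence 6 contigs
  and 14 within-contig junctions), 13 of 20 clones reverse-complemented, a
  split displaced prefix (700 bp in two parts around a 44-bp N-run, origins
  2,000 and 2,900 bp downstream) at the start of clone 6, an 800-bp
  inversion inside clone 10, a 3-copy repeat family and planted N-runs.
  Clones 6 and 10 are pinned forward so the injected events are defined in
  map orientation.
* Synthetic class I proteins are built from a fixed consensus scaffold
  (24-aa signal, 90/92/92-aa α domains, 10-aa connecting peptide, 23-aa
  hydrophobic TM, polar tail).  Substitutions are restricted to α-domain
  interiors and drawn from polar residues, so planted features -- and only
  planted features -- determine the hydropathy profile.  Tail lengths are
  drawn from clearly separated classes (truncated 3-15, canonical 26-33
  residues), matching the bimodal pattern seen in real class I loci.  The
  generator's intended class applies the classifier's documented rule to
  the planted features, so panel-level agreement asserts implementation
  fidelity, not biological validity.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout, matching the convention of
  published overlap tables; BED export converts to 0-based half-open and
  the conversion is round-trip tested.
* IUPAC ambiguity codes other than N are converted to N on input (with a
  warning); downstream logic is strictly {A,C,G,T,N}.
* Equal-coverage forward and reverse chains resolve to forward and are
  flagged ambiguous.  Equal-scoring hydropathy windows resolve to the
  earlier window (window means are rounded to 9 decimals so exact ties are
  not broken by floating-point accumulation order).
* Empty inputs degrade gracefully: no anchors means no overlap; no hits
  means every clone is its own contig; an empty annotation set yields an
  empty map; orientation conflicts and branching clones are logged and
  excluded, never fatal.
* Identity over a chain is computed from anchors plus direct comparison of
  equal-length inter-anchor gaps; unequal gaps (indels) contribute their
  maximum length to the denominator and no matches.

## Problem sizes used by the shipped checks

The test suite and the acceptance script regenerate everything they
measure.  The suite runs the 20-clone fixture across 20 seeds, structural
events across 100 seeded replicates, the word-match oracle on 200 random
pairs up to 2 kb, and the classifier on 600 proteins (20 panels of 30)
with per-case monotonicity flips.  The acceptance script reports the same
quantities at 5 tiling seeds, 20 event replicates, 50 oracle pairs and 200
proteins.  These sizes are the package's chosen trade-off between
statistical coverage and a test run that stays pleasant to execute locally.

## Known limitations

* Overlap identity is anchor-based, not an optimal alignment; for highly
  diverged overlaps (below ~90% identity) anchors thin out and the
  dovetail test becomes conservative.
* Gap sizes exist only through reference projection; a diverged or
  misassembled reference biases them.
* The dotplot engine holds all word matches for a pair in memory; for two
  200-kb BACs that is unproblematic, but whole-chromosome self-comparisons
  at word length 8 are not the intended use.
* Domain annotation projects boundaries from the best single reference; it
  will not resolve domain losses that the panel does not represent.
* The classifier is a rule, not a model: it encodes the published motif /
  truncation criterion and inherits its ambiguities (a motif-bearing locus
  with a full-length tail is called Ib by rule, a case the source
  literature leaves undetermined).
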