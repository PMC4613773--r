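# bactile

Tools for building and auditing physical maps from large-insert (BAC) clone
sequences, motivated by the MHC class I region of the sheep genome — a
region where published maps disagree about contiguity, gene order and even
the orientation of whole clones.

`bactile` automates, as one reproducible pipeline, four analyses that are
usually done by hand with a mix of BLAST, alignment editors and dotplot
viewers:

* **Pairwise overlap detection** — maximal exact word matches (default word
  length 30, words containing `N` never match) are chained into the best
  collinear chain per orientation; a chain that reaches the facing ends of
  both clones (a *dovetail*) within configured slack becomes an overlap
  call with boundary coordinates, identity and orientation. A non-matching
  terminal segment up to 1 kb is annotated as a *suspect terminus* (the
  signature of a misassembled clone end) instead of rejecting the junction.
* **Tiling-path construction** — orientations propagate over a spanning
  forest of the overlap graph, offsets follow from dovetail geometry,
  connected components become contigs, and gaps between contigs are sized
  by projection onto a reference chromosome.
* **Dotplot structural comparison** — Gepard-style word-match dotplots are
  collapsed into diagonal segments; changes of diagonal offset call indels
  (re-classified as N-run artefacts when the spanned region is mostly
  undefined nucleotides), reverse segments in a forward context call
  inversions, parallel diagonals call interspersed repeats, and a
  self-scan with the main diagonal masked recovers displaced terminal
  segments — misassemblies whose true origin lies elsewhere in the clone.
* **MHC class I classification** — predicted class I proteins are annotated
  (signal peptide and transmembrane domain by Kyte–Doolittle hydropathy
  heuristics, α1/α2/α3 boundaries by alignment projection from a bundled
  reference panel) and each locus is labelled **Ia** (classical) or **Ib**
  (nonclassical) by the standard ruminant criterion: a VPI/IPI/VLIK motif
  in the transmembrane domain and/or a truncated cytoplasmic tail ⇒ Ib;
  no detectable TM or tail ⇒ unclassified.

Seeded synthetic-data generators (`make_chromosome()`,
`simulate_clone_set()`, `inject_structural_event()`,
`make_class1_proteins()`, `simulate_tiling_fixture()`) produce chromosomes,
clone sets and proteins with complete ground truth, so every stage is
tested end-to-end without downloads.

## Worked example

Simulate the canonical fixture — 20 clones over a ~100-kb chromosome with 5
designated gaps, 13 reverse-complemented clones, one split displaced prefix
and one planted inversion — and run the tiling stages:

```r
library(bactile)

fx   <- simulate_tiling_fixture(seed = 1)
hits <- overlap_table(fx$clones)
path <- layout_contigs(hits, orient_clones(hits),
                       all_clones = tibble::tibble(clone_id = fx$clones$id,
                                                   length = nchar(fx$clones$seq)))
hint <- project_contigs(path, fx$clones, fx$chromosome$sequence)
path <- apply_reference_orientation(path, hint)
path$gaps <- call_gaps(path, hint)
glance(path)
#> # A tibble: 1 × 6
#>   n_clones n_contigs n_gaps n_unplaced n_conflicts n_suspect_termini
#>      <int>     <int>  <int>      <int>       <int>             <int>
#> 1       20         6      5          0           0                 1
```

The 20 clones resolve into 6 contigs separated by 5 gaps; exactly one
junction carries a suspect terminus — the clone whose prefix was planted
from sequence originating downstream. Gap sizes come from the reference
projection (the planted gaps are 2.5 kb):

```r
path$gaps[, c("left_clone", "right_clone", "size_estimate", "evidence")]
#>   left_clone right_clone size_estimate evidence
#> 1 CL04       CL05                 2500 reference-projection
#> 2 CL08       CL09                 2500 reference-projection
#> 3 CL11       CL12                 2500 reference-projection
#> 4 CL14       CL15                 2500 reference-projection
#> 5 CL17       CL18                 2544 reference-projection
```

The self-scan of clone 6 recovers its misassembled prefix: two segments
(split by a 44-bp N-run) whose true origins lie 2,000 and 2,900 bp
downstream, grouped as one event:

```r
sc <- self_consistency_scan(fx$clones[6, ])
sc[sc$kind == "displaced_segment", ]
#>   a_start a_end b_start displacement group
#> 1       1   330    2001         2000 prefix1
#> 2     375   700    3275         2900 prefix1
```

Classifying a synthetic protein panel reproduces the census-style locus
table (Type `No` marks loci with no classifiable TM/tail):

```r
prot <- make_class1_proteins(sample_class1_spec(6, seed = 2), seed = 3)
tabulate_loci(classify_proteins(prot$proteins, annotate = FALSE), prot$proteins)
#>   protein_id aa_len SP    TM      C_term    Type
#> 1 SYN001        344 1-24  309-331 "332-344" Ib
#> 2 SYN002        331 1-24  309-331 ""        No
#> 3 SYN003        364 1-24  309-331 "332-364" Ib
#> 4 SYN004        339 1-24  309-331 "332-339" Ib
#> 5 SYN005        335 1-24  309-331 "332-335" Ib
#> 6 SYN006        336 1-24  309-331 "332-336" Ib
```

`run_pipeline()` orchestrates all stages from a validated YAML config and
writes byte-stable TSV outputs plus a JSON manifest;
`inst/scripts/bactile.R` is a thin command-line wrapper
(`Rscript bactile.R run --clones clones.fasta --reference ref.fasta ...`).

## Package layout

* `R/seqio.R` — FASTA/GenBank reading, reverse complement, N-run detection,
  slicing (1-based inclusive coordinates throughout; BED export converts).
* `R/kmer.R`, `R/overlap.R` — word-match engine, anchor chaining, dovetail
  overlap detection, overlap tables.
* `R/tiling.R` — orientation resolution, contig layout, gap calling,
  truth comparison.
* `R/dotstruct.R` — dotplots, diagonal segments, structural-event calling,
  reference projection, self-consistency scan.
* `R/class1.R` — domain heuristics, reference-panel projection, Ia/Ib
  classification, locus tables.
* `R/physmap.R` — map assembly, map comparison, end-sequence placement,
  GFF3/BED/TSV export.
* `R/synthetic.R` — the seeded generators and the canonical fixture.
* `R/pipeline.R` — config, orchestration, manifests.

The methods vignette (`vignettes/bac-physical-mapping.Rmd`) documents the
model, parameter choices, generator assumptions and known limitations.
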