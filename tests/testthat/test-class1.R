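test_that("signal-peptide heuristic finds the planted leader and nothing else", {
  gen <- make_class1_proteins(tibble::tibble(name = "p", tm_motif = "none",
                                             tail_len = 28), seed = 1)
  sp <- detect_signal_peptide(gen$proteins)
  expect_false(is.null(sp))
  expect_equal(sp[1], 1)
  expect_lte(abs(sp[2] - 24), 3)
  # poly-glutamate N-terminus has no hydrophobic core
  polyE <- seq_tbl("e", paste0(strrep("E", 40), strrep("Q", 20)),
                   alphabet = "protein")
  expect_null(detect_signal_peptide(polyE))
  short <- seq_tbl("s", strrep("L", 30), alphabet = "protein")
  expect_error(detect_signal_peptide(short), "too short")
})

test_that("hydropathy scan recovers the transmembrane span", {
  gen <- make_class1_proteins(tibble::tibble(name = "p", tm_motif = "none",
                                             tail_len = 28), seed = 2)
  tr <- gen$truth
  tm <- detect_tm(gen$proteins, search_from = 250)
  ov <- min(tm[2], tr$tm_end) - max(tm[1], tr$tm_start) + 1
  expect_gte(ov, 0.8 * 23)
  polar <- seq_tbl("q", strrep("QESTDKRN", 50), alphabet = "protein")
  expect_null(detect_tm(polar))
  # equal-score windows: the earlier one wins
  two <- seq_tbl("two", paste0(strrep("Q", 30), strrep("L", 19), strrep("Q", 30),
                               strrep("L", 19), strrep("Q", 10)),
                 alphabet = "protein")
  tm2 <- detect_tm(two)
  expect_equal(tm2[1], 31)
})

test_that("domain projection recovers planted and reference boundaries", {
  panel <- class1_reference_panel()
  # a reference against itself returns its own marked boundaries exactly
  ann_self <- annotate_domains(panel$seqs[3, ], panel)
  expect_equal(ann_self$best_reference, "REF03")
  expect_equal(ann_self$a1_start, panel$boundaries$a1_start[3])
  expect_equal(ann_self$tm_end, panel$boundaries$tm_end[3])
  # each reference against the remaining panel: boundaries within 5 residues
  for (i in c(1, 4)) {
    rest <- list(seqs = panel$seqs[-i, ], boundaries = panel$boundaries[-i, ])
    ann <- annotate_domains(panel$seqs[i, ], rest)
    for (col in c("a1_start", "a2_start", "a3_start", "tm_start", "tm_end")) {
      expect_lte(abs(ann[[col]] - panel$boundaries[[col]][i]), 5)
    }
  }
  # planted spans on a fresh synthetic protein
  gen <- make_class1_proteins(tibble::tibble(name = "q", tm_motif = "none",
                                             tail_len = 30), seed = 9)
  ann2 <- annotate_domains(gen$proteins, panel)
  for (col in c("a1_start", "a1_end", "a2_start", "a2_end", "a3_start", "a3_end")) {
    expect_lte(abs(ann2[[col]] - gen$truth[[col]]), 3)
  }
  # alpha-3 deletion: remaining domains still recovered
  gen3 <- make_class1_proteins(tibble::tibble(name = "d", tm_motif = "none",
                                              tail_len = 28, drop_alpha3 = TRUE),
                               seed = 10)
  ann3 <- annotate_domains(gen3$proteins, panel)
  expect_lte(abs(ann3$a2_end - gen3$truth$a2_end), 3)
  # unrelated sequence: all-NA annotation flagged weak
  junk <- seq_tbl("j", strrep("GASTGHKE", 45), alphabet = "protein")
  annj <- annotate_domains(junk, panel)
  expect_match(annj$flags, "weak_match")
})

test_that("the Ia/Ib/unclassified rule is total, deterministic and monotone", {
  cfg <- class1_config()
  gen <- make_class1_proteins(tibble::tibble(
    name = c("ia", "motif", "trunc", "no_tm"),
    tm_motif = c("none", "VLIK", "none", "none"),
    tail_len = c(28, 28, 10, 28),
    has_tm = c(TRUE, TRUE, TRUE, FALSE)), seed = 12)
  calls <- classify_proteins(gen$proteins, annotate = FALSE)
  expect_equal(calls$call, c("Ia", "Ib", "Ib", "unclassified"))
  expect_equal(calls$motif_found[2], "VLIK")
  expect_true(all(calls$call %in% c("Ia", "Ib", "unclassified")))
  # monotonicity by direct sequence surgery on the Ia protein
  ia <- gen$proteins[1, ]
  tr <- gen$truth[1, ]
  truncated <- seq_tbl("t", substr(ia$seq, 1, tr$tm_end + 10), alphabet = "protein")
  expect_equal(classify_proteins(truncated, annotate = FALSE)$call, "Ib")
  no_tm <- seq_tbl("n", substr(ia$seq, 1, tr$tm_start - 1), alphabet = "protein")
  expect_equal(classify_proteins(no_tm, annotate = FALSE)$call, "unclassified")
  motif_in <- ia$seq
  substr(motif_in, tr$tm_start + 7, tr$tm_start + 9) <- "VPI"
  with_motif <- seq_tbl("m", motif_in, alphabet = "protein")
  expect_equal(classify_proteins(with_motif, annotate = FALSE)$call, "Ib")
})

test_that("classification matches the generator's intent on a mixed panel", {
  spec <- sample_class1_spec(30, seed = 44)
  gen <- make_class1_proteins(spec, seed = 45)
  calls <- classify_proteins(gen$proteins, annotate = FALSE)
  expect_identical(calls$call, gen$truth$intended_class)
  # the alignment-annotated route agrees on a subset
  calls_ann <- classify_proteins(gen$proteins[1:8, ])
  expect_identical(calls_ann$call, gen$truth$intended_class[1:8])
})

test_that("locus tables mirror the census layout", {
  spec <- sample_class1_spec(11, seed = 46)
  gen <- make_class1_proteins(spec, seed = 47)
  calls <- classify_proteins(gen$proteins, annotate = FALSE)
  tab <- tabulate_loci(calls, gen$proteins)
  expect_equal(nrow(tab), 11)
  expect_true(all(c("SP", "TM", "C_term", "Type", "aa_len") %in% names(tab)))
  expect_true(all(tab$Type %in% c("Ia", "Ib", "No")))
  # unclassified rows leave the C-terminus column empty
  expect_true(all(tab$C_term[tab$Type == "No"] == ""))
  expect_equal(nrow(tabulate_loci(calls[0, ], gen$proteins)), 0)
  expect_error(tabulate_loci(dplyr::bind_rows(calls, calls[1, ]), gen$proteins),
               "duplicate")
  ctx <- tibble::tibble(protein_id = gen$proteins$id, strand = "+",
                        start = 1L, end = 2L, homologue = "H")
  tab2 <- tabulate_loci(calls, gen$proteins, ctx)
  expect_true(all(c("strand", "homologue") %in% names(tab2)))
})

test_that("the bundled panel files round-trip through the loader", {
  fa <- system.file("extdata", "class1_reference_panel_synthetic.fasta",
                    package = "bactile")
  tsv <- system.file("extdata", "class1_reference_panel_synthetic_domains.tsv",
                     package = "bactile")
  panel <- load_class1_references(fa, tsv)
  expect_equal(nrow(panel$seqs), 8)
  expect_identical(panel$seqs$seq, class1_reference_panel()$seqs$seq)
  expect_identical(panel$boundaries$tm_start,
                   class1_reference_panel()$boundaries$tm_start)
})
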