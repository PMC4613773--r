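test_that("dotplot word matches equal the brute-force oracle and transpose", {
  withr::with_seed(91, {
    for (rep in 1:6) {
      n <- sample(100:600, 1)
      a <- random_dna_chr(n)
      b <- if (rep %% 3 == 0) paste0(substr(a, 1, 60), random_dna_chr(n - 60))
           else random_dna_chr(n)
      expect_equal(package_word_matches(a, b, 10),
                   brute_force_word_matches(a, b, 10), ignore_attr = TRUE)
      # transpose symmetry of the forward sub-matrix
      mab <- package_word_matches(a, b, 10)
      mba <- package_word_matches(b, a, 10)
      fab <- mab[mab$orientation == "forward", c("pos_a", "pos_b")]
      fba <- mba[mba$orientation == "forward", c("pos_b", "pos_a")]
      names(fba) <- c("pos_a", "pos_b")
      ord <- function(d) d[order(d$pos_a, d$pos_b), , drop = FALSE]
      expect_equal(ord(fab), ord(fba), ignore_attr = TRUE)
    }
  })
  # self-plot lies on the main diagonal; vs revcomp on the anti-diagonal
  a <- seq_tbl("a", random_dna_chr(800, 92))
  m <- dotplot_matrix(a, a)
  fwd <- m[m$orientation == "forward", ]
  expect_true(all(fwd$pos_b == fwd$pos_a))
  m2 <- dotplot_matrix(a, reverse_complement(a))
  rev <- m2[m2$orientation == "reverse", ]
  expect_equal(nrow(rev), 800 - 29)
  expect_true(all(rev$pos_b_rc == rev$pos_a))
})

test_that("diagonal segments capture overlaps, repeats and inversions", {
  ch <- make_chromosome(30000, n_loci = 0, n_repeat_families = 1,
                        repeat_copy_number = 3, repeat_length = 600,
                        seed = 93)
  ref <- ch$sequence
  cs <- simulate_clone_set(ch, tibble::tibble(start = 5001, length = 12000,
                                              orientation = "forward",
                                              gap_after = FALSE), seed = 94)
  segs <- diagonal_segments(dotplot_matrix(cs$clones, ref))
  main_like <- segs[segs$orientation == "forward" & segs$word_count > 100, ]
  expect_gte(nrow(main_like), 1)
  # 0 repeat families -> a self-plot has only the main diagonal
  ch0 <- make_chromosome(20000, n_loci = 0, n_repeat_families = 0, seed = 95)
  m0 <- dotplot_matrix(ch0$sequence, ch0$sequence)
  s0 <- diagonal_segments(m0)
  expect_true(all(s0$diag[s0$orientation == "forward"] == 0))
  # planted 3-copy repeat family: parallel segments at distinct offsets
  m1 <- dotplot_matrix(ch$sequence, ch$sequence)
  s1 <- diagonal_segments(m1, dotplot_params(min_segment_words = 5))
  off_diag <- s1[s1$orientation == "forward" & s1$diag != 0, ]
  expect_gte(length(unique(off_diag$diag)), 3 * 2)  # 3 copy pairs, symmetric
})

test_that("event calling sizes indels and finds inversions deterministically", {
  ch <- make_chromosome(30000, n_loci = 0, n_repeat_families = 0, seed = 96)
  ref <- ch$sequence
  cl <- simulate_clone_set(ch, tibble::tibble(start = 8001, length = 10000,
                                              orientation = "forward",
                                              gap_after = FALSE), seed = 97)$clones
  del <- inject_structural_event(cl, list(kind = "deletion", at = 4000, size = 500))
  segs <- diagonal_segments(dotplot_matrix(del$clone, ref))
  ev <- classify_events(segs, len_a = nchar(del$clone$seq), len_b = 30000)
  ind <- ev[ev$kind == "indel", ]
  expect_equal(nrow(ind), 1)
  expect_lte(abs(ind$size - 500), 29)
  expect_gt(ind$displacement, 0)   # extra sequence in the reference
  ins <- inject_structural_event(cl, list(kind = "insertion", at = 4000, size = 700),
                                 seed = 5)
  ev2 <- classify_events(diagonal_segments(dotplot_matrix(ins$clone, ref)),
                         len_a = nchar(ins$clone$seq), len_b = 30000)
  ind2 <- ev2[ev2$kind == "indel", ]
  expect_lte(abs(ind2$size - 700), 29)
  expect_lt(ind2$displacement, 0)
  inv <- inject_structural_event(cl, list(kind = "inversion", at = 3000, size = 800))
  segs3 <- diagonal_segments(dotplot_matrix(inv$clone, ref))
  ev3 <- classify_events(segs3, len_a = 10000, len_b = 30000)
  invs <- ev3[ev3$kind == "inversion", ]
  expect_equal(nrow(invs), 1)
  expect_lte(abs(invs$a_start - 3000), 29)
  expect_lte(abs(invs$size - 800), 58)
  # order-independence: shuffling segment rows leaves the calls unchanged
  withr::with_seed(98, {
    shuf <- segs3[sample.int(nrow(segs3)), ]
    expect_equal(classify_events(shuf, len_a = 10000, len_b = 30000), ev3)
  })
  # clean comparison: no indel or inversion calls
  ev0 <- classify_events(diagonal_segments(dotplot_matrix(cl, ref)),
                         len_a = 10000, len_b = 30000)
  expect_false(any(ev0$kind %in% c("indel", "inversion")))
})

test_that("indels spanning undefined nucleotides become n_run artefacts", {
  ch <- make_chromosome(30000, n_loci = 0, n_repeat_families = 0, seed = 99)
  cl <- simulate_clone_set(ch, tibble::tibble(start = 8001, length = 10000,
                                              orientation = "forward",
                                              gap_after = FALSE), seed = 100)$clones
  # replace a clone block with N, then delete it: the reference "insertion"
  # relative to the clone is backed by real sequence, but the clone-side
  # N-block deletion in reverse produces an N-backed reference gap
  ref_n <- inject_structural_event(ch$sequence,
                                   list(kind = "n_run", at = 12000, size = 400))
  del <- inject_structural_event(cl, list(kind = "deletion", at = 4000, size = 400))
  ev <- classify_events(
    diagonal_segments(dotplot_matrix(del$clone, ref_n$clone)),
    a_n_runs = find_ambiguity_runs(del$clone, 1),
    b_n_runs = find_ambiguity_runs(ref_n$clone, 1),
    len_a = 9600, len_b = 30000)
  kinds <- ev$kind[ev$kind %in% c("indel", "n_run_artifact")]
  expect_setequal(unique(kinds), "n_run_artifact")
})

test_that("self-consistency scan recovers split displaced prefixes", {
  ch <- make_chromosome(30000, n_loci = 0, n_repeat_families = 0, seed = 103)
  cl <- simulate_clone_set(ch, tibble::tibble(start = 5001, length = 9000,
                                              orientation = "forward",
                                              gap_after = FALSE), seed = 104)$clones
  expect_equal(nrow(self_consistency_scan(cl)), 0)  # clean negative control
  split <- inject_structural_event(cl, list(kind = "displaced_prefix", L = 700,
                                            D = 2000, part1_len = 330,
                                            n_run_len = 44, D2 = 2900))
  sc <- self_consistency_scan(split$clone)
  ds <- sc[sc$kind == "displaced_segment", ]
  expect_equal(nrow(ds), 2)
  expect_lte(abs(ds$displacement[1] - 2000), 29)
  expect_lte(abs(ds$displacement[2] - 2900), 29)
  expect_equal(length(unique(ds$group)), 1)  # both parts share one group
  single <- inject_structural_event(cl, list(kind = "displaced_prefix",
                                             L = 250, D = 1800))
  sc2 <- self_consistency_scan(single$clone)
  ds2 <- sc2[sc2$kind == "displaced_segment", ]
  expect_equal(nrow(ds2), 1)
  expect_lte(abs(ds2$displacement - 1800), 29)
})

test_that("reference projection reproduces source intervals and relations", {
  ch <- make_chromosome(40000, n_loci = 0, n_repeat_families = 0, seed = 105)
  cs <- simulate_clone_set(ch, tibble::tibble(
    start = c(5001, 12001, 30001), length = c(9000, 9000, 6000),
    orientation = c("forward", "revcomp", "forward"),
    gap_after = c(FALSE, TRUE, FALSE)), seed = 106)
  p1 <- project_to_reference(cs$clones[1, ], ch$sequence)
  expect_lte(abs(p1$ref_start - 5001), 29)
  expect_lte(abs(p1$ref_end - 14000), 29)
  expect_equal(p1$orientation, "forward")
  p2 <- project_to_reference(cs$clones[2, ], ch$sequence)
  expect_equal(p2$orientation, "reverse")
  expect_lte(abs(p2$ref_start - 12001), 29)
  rel <- reference_relation(p1, p2)
  expect_equal(rel$relation, "overlap")
  expect_lte(abs(rel$size - 2000), 58)
  p3 <- project_to_reference(cs$clones[3, ], ch$sequence)
  rel2 <- reference_relation(p2, p3)
  expect_equal(rel2$relation, "gap")
  expect_lte(abs(rel2$size - 9000), 58)
  # a foreign clone fails to project
  alien <- seq_tbl("alien", random_dna_chr(5000, 107))
  expect_null(project_to_reference(alien, ch$sequence))
})
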