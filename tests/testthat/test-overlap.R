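test_that("anchor matching equals the brute-force word oracle", {
  withr::with_seed(71, {
    for (rep in 1:10) {
      n <- sample(60:400, 1)
      a <- random_dna_chr(n)
      b <- random_dna_chr(n)
      # plant a shared segment in half the cases
      if (rep %% 2 == 0) {
        seg <- substr(a, 10, 10 + 49)
        b <- paste0(substr(b, 1, 20), seg, substr(b, 71, n))
      }
      k <- sample(c(8L, 12L), 1)
      expect_equal(package_word_matches(a, b, k),
                   brute_force_word_matches(a, b, k),
                   ignore_attr = TRUE)
    }
  })
})

test_that("self and reverse-complement anchors cover the full sequence", {
  a <- seq_tbl("a", random_dna_chr(2000, 5))
  anc <- anchor_matches(a, a, 30)
  fwd <- anc[anc$orientation == "forward", ]
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$pos_a, 1)
  expect_equal(fwd$length, 2000)
  rc <- reverse_complement(a)
  anc2 <- anchor_matches(a, rc, 30)
  rev <- anc2[anc2$orientation == "reverse", ]
  expect_equal(nrow(rev), 1)
  expect_equal(rev$length, 2000)
  expect_equal(rev$b_start, 1)
  # words containing N never match
  n_mid <- seq_tbl("n", paste0(substr(a$seq, 1, 1000), "N", substr(a$seq, 1001, 2000)))
  anc3 <- anchor_matches(n_mid, n_mid, 30)
  expect_true(all(anc3$pos_a + anc3$length - 1 <= 2001))
  expect_equal(nrow(anc3[anc3$orientation == "forward", ]), 2)
})

test_that("anchors tile a planted shared segment", {
  withr::with_seed(8, {
    a <- random_dna_chr(2000)
    b <- random_dna_chr(2000)
    seg <- substr(a, 501, 800)
    b <- paste0(substr(b, 1, 1000), seg, substr(b, 1301, 2000))
    anc <- anchor_matches(seq_tbl("a", a), seq_tbl("b", b), 30)
    fwd <- anc[anc$orientation == "forward" & anc$length >= 250, ]
    expect_equal(nrow(fwd), 1)
    # maximal matches may extend a base or two past the planted boundary when
    # the random background happens to agree there
    expect_lte(abs(fwd$pos_a - 501), 2)
    expect_lte(abs(fwd$b_start - 1001), 2)
    expect_lte(abs(fwd$length - 300), 4)
    expect_equal(fwd$b_start - fwd$pos_a, 500)
  })
})

test_that("chaining keeps collinear anchors and respects gap limits", {
  anc <- tibble::tibble(pos_a = c(1L, 200L), b_start = c(1L, 200L),
                        b_end = c(100L, 299L), q = c(1L, 200L),
                        length = c(100L, 100L),
                        orientation = "forward")
  ch <- chain_anchors(anc, max_gap = 6000, max_diag_drift = 300)
  expect_equal(nrow(ch$forward), 2)
  # gap above the limit breaks the chain: best chain is a single anchor
  ch2 <- chain_anchors(anc, max_gap = 50, max_diag_drift = 300)
  expect_equal(nrow(ch2$forward), 1)
  single <- chain_anchors(anc[1, ], max_gap = 100, max_diag_drift = 10)
  expect_equal(nrow(single$forward), 1)
  expect_equal(nrow(single$reverse), 0)
})

test_that("dovetail overlaps are recovered with near-exact boundaries", {
  ch <- make_chromosome(30000, n_loci = 0, n_repeat_families = 0, seed = 21)
  cs <- simulate_clone_set(ch, tibble::tibble(
    start = c(1, 4001, 20001), length = c(6000, 6000, 6000),
    orientation = "forward", gap_after = c(FALSE, TRUE, FALSE)), seed = 22)
  h <- detect_overlap(cs$clones[1, ], cs$clones[2, ])
  expect_false(is.null(h))
  expect_equal(h$orientation, "forward")
  expect_lte(abs(h$a_start - 4001), 29)
  expect_lte(abs(h$a_end - 6000), 29)
  expect_lte(abs(h$b_start - 1), 29)
  expect_lte(abs(h$b_end - 2000), 29)
  expect_gte(h$identity, 0.95)
  expect_lte(h$matched_bp, min(h$a_end - h$a_start, h$b_end - h$b_start) + 1)
  # disjoint-source clones yield no overlap
  expect_null(detect_overlap(cs$clones[1, ], cs$clones[3, ]))
})

test_that("orientation coherence: flipping one clone flips the call", {
  ch <- make_chromosome(30000, n_loci = 0, n_repeat_families = 0, seed = 31)
  cs <- simulate_clone_set(ch, tibble::tibble(
    start = c(1, 4001), length = c(6000, 6000), orientation = "forward",
    gap_after = FALSE), seed = 32)
  h1 <- detect_overlap(cs$clones[1, ], cs$clones[2, ])
  h2 <- detect_overlap(reverse_complement(cs$clones[1, ]), cs$clones[2, ])
  expect_equal(h1$orientation, "forward")
  expect_equal(h2$orientation, "reverse")
  # a-span maps by p -> len - p + 1
  expect_lte(abs(h2$a_start - (6000 - h1$a_end + 1)), 29)
  expect_lte(abs(h2$a_end - (6000 - h1$a_start + 1)), 29)
  expect_equal(h2$b_start, h1$b_start)
})

test_that("overlap tables cover chains and respect degenerate input", {
  ch <- make_chromosome(30000, n_loci = 0, n_repeat_families = 0, seed = 41)
  cs <- simulate_clone_set(ch, tibble::tibble(
    start = c(1, 4001, 8001), length = c(6000, 6000, 6000),
    orientation = c("forward", "revcomp", "forward"),
    gap_after = FALSE), seed = 42)
  tab <- overlap_table(cs$clones)
  expect_equal(nrow(tab), 2)
  key <- paste(pmin(tab$id_a, tab$id_b), pmax(tab$id_a, tab$id_b))
  expect_setequal(key, c("CL01 CL02", "CL02 CL03"))
  expect_true(all(tab$identity >= 0.95))
  expect_equal(nrow(overlap_table(cs$clones[1, ])), 0)
})

test_that("a non-matching terminal prefix is annotated, not rejected", {
  ch <- make_chromosome(30000, n_loci = 0, n_repeat_families = 0, seed = 51)
  cs <- simulate_clone_set(ch, tibble::tibble(
    start = c(1, 4001), length = c(6000, 6000), orientation = "forward",
    gap_after = FALSE), seed = 52)
  dp <- inject_structural_event(cs$clones[2, ],
                                list(kind = "displaced_prefix", L = 700, D = 2500))
  h <- detect_overlap(cs$clones[1, ], dp$clone)
  expect_false(is.null(h))
  expect_true(h$suspect_terminus != "")
  expect_gte(h$suspect_len, 600)
  expect_lte(h$suspect_len, 800)
  # a prefix beyond prefix_slack does veto the hit
  big <- inject_structural_event(cs$clones[2, ],
                                 list(kind = "displaced_prefix", L = 1500, D = 3000))
  expect_null(detect_overlap(cs$clones[1, ], big$clone))
})
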