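make_hit <- function(a, b, orientation = "forward", a_start = 4001, a_end = 6000,
                     b_start = 1, b_end = 2000, identity = 0.99) {
  tibble::tibble(id_a = a, id_b = b, a_start = a_start, a_end = a_end,
                 b_start = b_start, b_end = b_end, orientation = orientation,
                 direction = "ab", matched_bp = 1900, identity = identity,
                 dovetail = TRUE, suspect_terminus = "", suspect_len = 0,
                 ambiguous_orientation = FALSE, len_a = 6000L, len_b = 6000L)
}

test_that("orientation propagates over edges and reports contradictions", {
  one <- make_hit("a", "b", "reverse")
  o <- orient_clones(one)
  expect_equal(o$orientation$orientation[o$orientation$clone_id == "a"], "forward")
  expect_equal(o$orientation$orientation[o$orientation$clone_id == "b"], "revcomp")
  expect_equal(nrow(o$conflicts), 0)
  # triangle with one contradictory edge: exactly one conflict, never fatal
  tri <- dplyr::bind_rows(make_hit("a", "b", "forward"),
                          make_hit("b", "c", "forward"),
                          make_hit("a", "c", "reverse"))
  o2 <- orient_clones(tri)
  expect_equal(nrow(o2$conflicts), 1)
  expect_false(anyNA(o2$orientation$orientation))
  # all eight orientation patterns of a consistent triangle propagate cleanly
  for (ab in c("forward", "reverse")) for (bc in c("forward", "reverse")) {
    ac <- if (ab == bc) "forward" else "reverse"
    tri2 <- dplyr::bind_rows(make_hit("a", "b", ab), make_hit("b", "c", bc),
                             make_hit("a", "c", ac))
    expect_equal(nrow(orient_clones(tri2)$conflicts), 0)
  }
})

test_that("chained hits produce a single ordered contig", {
  hits <- dplyr::bind_rows(make_hit("c1", "c2"), make_hit("c2", "c3"),
                           make_hit("c3", "c4"))
  path <- layout_contigs(hits, orient_clones(hits))
  expect_s3_class(path, "tiling_path")
  expect_equal(length(unique(path$contigs$contig)), 1)
  expect_equal(path$contigs$clone_id, c("c1", "c2", "c3", "c4"))
  expect_equal(path$contigs$offset, c(0, 4000, 8000, 12000))
  # edgeless input: every clone its own contig
  lone <- layout_contigs(hits[0, ], orient_clones(hits[0, ]),
                         all_clones = tibble::tibble(clone_id = c("x", "y"),
                                                     length = c(100L, 200L)))
  expect_equal(length(unique(lone$contigs$contig)), 2)
})

test_that("gap calling orders contigs and sizes gaps only with a hint", {
  hits <- dplyr::bind_rows(make_hit("c1", "c2"), make_hit("c3", "c4"))
  path <- layout_contigs(hits, orient_clones(hits))
  gaps <- call_gaps(path)
  expect_equal(nrow(gaps), 1)
  expect_true(is.na(gaps$size_estimate))
  expect_equal(gaps$evidence, "no-overlap")
  hint <- tibble::tibble(contig = unique(path$contigs$contig),
                         ref_start = c(20000, 1), ref_end = c(30000, 9000))
  gaps2 <- call_gaps(path, hint)
  expect_equal(gaps2$size_estimate, 11000 - 1)
  expect_equal(gaps2$evidence, "reference-projection")
  expect_error(call_gaps(path, tibble::tibble(contig = "nope", ref_start = 1,
                                              ref_end = 2)), "parameter error")
})

test_that("the fixture tiling path is recovered exactly across clone shuffles", {
  fx <- simulate_tiling_fixture(seed = 61)
  all_clones <- tibble::tibble(clone_id = fx$clones$id,
                               length = nchar(fx$clones$seq))
  hits <- overlap_table(fx$clones)
  expect_equal(nrow(hits), 14)  # 20 clones - 6 contigs
  path <- layout_contigs(hits, orient_clones(hits), all_clones)
  rep <- compare_to_truth(path, fx$truth)
  expect_true(rep$partition_match)
  expect_true(rep$order_match)
  expect_true(rep$orientation_match)
  expect_lte(rep$max_junction_deviation, 29)
  ref_partition <- sort(table(path$contigs$contig))
  # partition invariance under input order
  withr::with_seed(62, {
    for (i in 1:3) {
      shuffled <- fx$clones[sample.int(20), ]
      hits_s <- overlap_table(shuffled)
      path_s <- layout_contigs(hits_s, orient_clones(hits_s), all_clones)
      expect_true(compare_to_truth(path_s, fx$truth)$partition_match)
    }
  })
  # the displaced-prefix junction is annotated as a suspect terminus
  expect_equal(nrow(path$suspect_termini), 1)
  expect_setequal(unlist(path$suspect_termini[, c("id_a", "id_b")]),
                  c("CL05", "CL06"))
  # implied pairwise offsets agree along every contig
  for (ctg in unique(path$contigs$contig)) {
    sub <- path$contigs[path$contigs$contig == ctg, ]
    if (nrow(sub) > 1) expect_true(all(diff(sub$offset) > 0))
  }
})

test_that("truth comparison detects shuffles and accepts whole-contig flips", {
  fx <- simulate_tiling_fixture(seed = 71)
  hits <- overlap_table(fx$clones)
  path <- layout_contigs(hits, orient_clones(hits),
                         tibble::tibble(clone_id = fx$clones$id,
                                        length = nchar(fx$clones$seq)))
  # negative control: move one clone to another contig
  broken <- path
  i <- which(broken$contigs$contig == "ctg1")[1]
  j <- which(broken$contigs$contig != "ctg1")[1]
  broken$contigs$contig[i] <- broken$contigs$contig[j]
  expect_false(compare_to_truth(broken, fx$truth)$partition_match)
  # flip-equivalence: reversing a whole contig stays accepted
  flipped <- path
  sel <- flipped$contigs$contig == flipped$contigs$contig[1]
  sub <- flipped$contigs[sel, ]
  span <- max(sub$offset + sub$length)
  flipped$contigs$offset[sel] <- span - (sub$offset + sub$length)
  flipped$contigs$orientation[sel] <- ifelse(sub$orientation == "forward",
                                             "revcomp", "forward")
  flipped$contigs[sel, ] <- flipped$contigs[sel, ][order(flipped$contigs$offset[sel]), ]
  rep2 <- compare_to_truth(flipped, fx$truth)
  expect_true(rep2$partition_match)
  expect_true(rep2$order_match)
  expect_true(rep2$orientation_match)
  expect_error(compare_to_truth(path, dplyr::mutate(fx$truth,
                                                    clone_id = paste0(clone_id, "_x"))),
               "parameter error")
})

test_that("reference projection sizes the designed gaps", {
  fx <- simulate_tiling_fixture(seed = 81)
  hits <- overlap_table(fx$clones)
  path <- layout_contigs(hits, orient_clones(hits),
                         tibble::tibble(clone_id = fx$clones$id,
                                        length = nchar(fx$clones$seq)))
  hint <- project_contigs(path, fx$clones, fx$chromosome$sequence)
  gaps <- call_gaps(path, hint)
  expect_equal(nrow(gaps), 5)
  expect_true(all(abs(gaps$size_estimate - 2500) <= 29))
})
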