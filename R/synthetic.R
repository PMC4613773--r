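# Seeded synthetic-data generators.  Every generator is a pure function of
# (parameters, seed): chromosomes with planted loci / repeat families /
# N-runs, clone sets with known positions, orientations and gaps, injected
# structural events (including the displaced-prefix misassembly), and class I
# proteins built from the consensus scaffold with controlled features.

place_features <- function(total_len, lengths, occupied = NULL, margin = 100) {
  # rejection-sample non-overlapping feature positions
  occ <- occupied %||% tibble::tibble(start = integer(), end = integer())
  out <- integer(length(lengths))
  for (i in seq_along(lengths)) {
    len <- lengths[i]
    ok <- FALSE
    for (try in seq_len(2000)) {
      st <- sample.int(total_len - len + 1L, 1L)
      en <- st + len - 1L
      if (!nrow(occ) || all(en + margin < occ$start | st - margin > occ$end)) {
        occ <- dplyr::bind_rows(occ, tibble::tibble(start = st, end = en))
        out[i] <- st
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("parameter error: cannot place features within the chromosome; ",
                  "feature lengths exceed available space")
  }
  list(starts = out, occupied = occ)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  idx <- which(stats::runif(length(chars)) < rate & chars != "N")
  if (length(idx)) {
    alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
    pick <- sample.int(3, length(idx), replace = TRUE)
    chars[idx] <- substring(alt[chars[idx]], pick, pick)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic chromosome with planted features
#'
#' Background sequence is i.i.d. uniform over ACGT.  Gene-like loci, repeat
#' families (copies of a family master with per-site substitutions) and runs
#' of undefined nucleotides are planted at non-overlapping positions, and the
#' complete ground truth is returned alongside the sequence.
#'
#' @param length Chromosome length in bp (>= 10 kb).
#' @param n_loci Number of gene-like loci to plant.
#' @param n_repeat_families,repeat_copy_number,repeat_length Repeat-family
#'   design: families, copies per family, copy length (bp).
#' @param n_run_spec Integer vector of N-run lengths to plant.
#' @param substitution_rate Per-site substitution rate between repeat copies.
#' @param locus_length Length of each planted locus (bp).
#' @param seed Integer seed; fixes all randomness.
#' @return A `chromosome_truth` list: `sequence` (sequence tibble), `loci`,
#'   `repeat_families`, `n_runs` tibbles, and the parameters used.
#' @export
make_chromosome <- function(length, n_loci = 8, n_repeat_families = 1,
                            repeat_copy_number = 3, repeat_length = 500,
                            n_run_spec = integer(), substitution_rate = 0.02,
                            locus_length = 800, seed) {
  stopifnot(length >= 10000)
  withr::with_seed(seed, {
    chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    n_rep <- n_repeat_families * repeat_copy_number
    lens <- c(rep(repeat_length, n_rep), n_run_spec, rep(locus_length, n_loci))
    if (sum(lens) > 0.5 * length) {
      stop("parameter error: planted features exceed half the chromosome length")
    }
    pl <- place_features(length, lens)
    starts <- pl$starts
    rep_tbl <- tibble::tibble(family = integer(), copy = integer(),
                              start = integer(), end = integer())
    idx <- 0L
    for (f in seq_len(n_repeat_families)) {
      master <- random_dna(repeat_length)
      for (cp in seq_len(repeat_copy_number)) {
        idx <- idx + 1L
        st <- starts[idx]
        copy <- mutate_dna(master, substitution_rate)
        chars[st:(st + repeat_length - 1L)] <- strsplit(copy, "")[[1]]
        rep_tbl <- dplyr::bind_rows(rep_tbl, tibble::tibble(
          family = f, copy = cp, start = st, end = st + repeat_length - 1L))
      }
    }
    nrun_tbl <- tibble::tibble(start = integer(), end = integer(), length = integer())
    for (j in seq_along(n_run_spec)) {
      idx <- idx + 1L
      st <- starts[idx]
      chars[st:(st + n_run_spec[j] - 1L)] <- "N"
      nrun_tbl <- dplyr::bind_rows(nrun_tbl, tibble::tibble(
        start = st, end = st + n_run_spec[j] - 1L, length = n_run_spec[j]))
    }
    loci_tbl <- tibble::tibble(name = character(), start = integer(),
                               end = integer(), category = character())
    if (n_loci > 0) {
      lst <- starts[(idx + 1L):(idx + n_loci)]
      cat_pool <- c("classI", "classI-like", "other")
      cats <- sample(cat_pool, n_loci, replace = TRUE, prob = c(0.4, 0.3, 0.3))
      ord <- order(lst)
      loci_tbl <- tibble::tibble(
        name = sprintf("GENE%02d", seq_len(n_loci)),
        start = lst[ord], end = lst[ord] + locus_length - 1L,
        category = cats[ord])
    }
    structure(list(
      sequence = seq_tbl("chr_synth", paste(chars, collapse = ""),
                         description = sprintf("synthetic chromosome seed %d", seed)),
      loci = loci_tbl,
      repeat_families = rep_tbl,
      n_runs = nrun_tbl,
      params = list(length = length, n_loci = n_loci,
                    n_repeat_families = n_repeat_families,
                    repeat_copy_number = repeat_copy_number,
                    repeat_length = repeat_length, n_run_spec = n_run_spec,
                    substitution_rate = substitution_rate, seed = seed)),
      class = "chromosome_truth")
  })
}

#' Simulate a clone set from a chromosome with known layout
#'
#' Each layout row cuts a clone from the chromosome, applies per-site
#' substitutions (clone-level sequencing/assembly noise) and, for
#' `orientation == "revcomp"`, emits the reverse complement.  Rows flagged
#' `gap_after` must not overlap the next clone.
#'
#' @param chrom A `chromosome_truth` from [make_chromosome()].
#' @param layout Tibble with columns `start`, `length`, `orientation`
#'   (`"forward"`/`"revcomp"`), `gap_after` (logical).
#' @param seed Integer seed.
#' @param substitution_rate Per-site clone substitution rate.
#' @return List with `clones` (sequence tibble) and `truth` (tibble
#'   `clone_id`, `start`, `end`, `orientation`, `gap_after`).
#' @export
simulate_clone_set <- function(chrom, layout, seed, substitution_rate = 0.005) {
  chrom_seq <- chrom$sequence$seq[1]
  n <- nrow(layout)
  ends <- layout$start + layout$length - 1L
  if (any(layout$start < 1L) || any(ends > nchar(chrom_seq))) {
    stop("layout intervals outside the chromosome")
  }
  if (n > 1) {
    overlap_next <- ends[-n] >= layout$start[-1]
    bad <- which(layout$gap_after[-n] & overlap_next)
    if (length(bad)) {
      stop("contradiction error: layout row ", bad[1],
           " is marked gap_after but overlaps the next clone")
    }
  }
  withr::with_seed(seed, {
    clones <- purrr::map_dfr(seq_len(n), function(i) {
      s <- substr(chrom_seq, layout$start[i], ends[i])
      s <- mutate_dna(s, substitution_rate)
      if (layout$orientation[i] == "revcomp") s <- revcomp_chr(s)
      seq_tbl(sprintf("CL%02d", i), s,
              description = sprintf("synthetic clone %d", i))
    })
    list(clones = clones,
         truth = tibble::tibble(clone_id = clones$id, start = layout$start,
                                end = ends, orientation = layout$orientation,
                                gap_after = layout$gap_after))
  })
}

#' Inject a structural event into a clone sequence
#'
#' Supported kinds: `deletion`, `insertion`, `inversion`, `n_run` and
#' `displaced_prefix`.  The displaced prefix replaces the clone's first `L`
#' bases with a copy of the clone's own sequence starting `D` bp downstream
#' (optionally split into two parts separated by an N-run, the second part
#' originating `D2` bp downstream) -- the signature of a terminal
#' misassembly.
#'
#' @param clone One-row sequence tibble.
#' @param event List with `kind` and kind-specific parameters: `at`, `size`
#'   for deletion/insertion/inversion/n_run; `L`, `D` and optionally
#'   `part1_len`, `n_run_len`, `D2` for `displaced_prefix`.
#' @param seed Integer seed (used for inserted sequence).
#' @return List with `clone` (modified one-row sequence tibble) and `truth`
#'   (tibble describing the injected event).
#' @export
inject_structural_event <- function(clone, event, seed = 1) {
  s <- clone$seq[1]
  n <- nchar(s)
  kind <- event$kind
  withr::with_seed(seed, {
    if (kind == "deletion") {
      stopifnot(event$at + event$size - 1 <= n)
      s2 <- paste0(substr(s, 1, event$at - 1), substr(s, event$at + event$size, n))
      truth <- tibble::tibble(kind = "deletion", at = event$at, size = event$size,
                              displacement = NA_integer_, part = NA_integer_)
    } else if (kind == "insertion") {
      stopifnot(event$at <= n)
      s2 <- paste0(substr(s, 1, event$at - 1), random_dna(event$size),
                   substr(s, event$at, n))
      truth <- tibble::tibble(kind = "insertion", at = event$at, size = event$size,
                              displacement = NA_integer_, part = NA_integer_)
    } else if (kind == "inversion") {
      stopifnot(event$at + event$size - 1 <= n)
      inv <- revcomp_chr(substr(s, event$at, event$at + event$size - 1))
      s2 <- paste0(substr(s, 1, event$at - 1), inv, substr(s, event$at + event$size, n))
      truth <- tibble::tibble(kind = "inversion", at = event$at, size = event$size,
                              displacement = NA_integer_, part = NA_integer_)
    } else if (kind == "n_run") {
      stopifnot(event$at + event$size - 1 <= n)
      s2 <- paste0(substr(s, 1, event$at - 1), strrep("N", event$size),
                   substr(s, event$at + event$size, n))
      truth <- tibble::tibble(kind = "n_run", at = event$at, size = event$size,
                              displacement = NA_integer_, part = NA_integer_)
    } else if (kind == "displaced_prefix") {
      L <- event$L; D <- event$D
      if (L >= n) stop("parameter error: displaced prefix length >= clone length")
      if (is.null(event$part1_len)) {
        # single-part displaced prefix: positions 1..L copy the clone's own
        # bases D bp downstream
        stopifnot(D + L <= n)
        s2 <- paste0(substr(s, D + 1, D + L), substr(s, L + 1, n))
        truth <- tibble::tibble(kind = "displaced_prefix", at = 1L, size = L,
                                displacement = D, part = 1L)
      } else {
        p1 <- event$part1_len; nr <- event$n_run_len; D2 <- event$D2
        p2 <- L - p1 - nr
        stopifnot(p2 > 0, D + p1 <= n, D2 + p1 + nr + p2 <= n)
        part2_src_start <- D2 + p1 + nr + 1L   # origin of part 2, D2 bp downstream
        s2 <- paste0(substr(s, D + 1, D + p1), strrep("N", nr),
                     substr(s, part2_src_start, part2_src_start + p2 - 1L),
                     substr(s, L + 1, n))
        truth <- tibble::tibble(
          kind = "displaced_prefix",
          at = c(1L, p1 + nr + 1L), size = c(p1, p2),
          displacement = c(D, D2), part = c(1L, 2L))
      }
    } else stop("unknown event kind: ", kind)
    list(clone = seq_tbl(clone$id[1], s2, description = clone$description[1]),
         truth = truth)
  })
}

#' Build synthetic class I proteins from the consensus scaffold
#'
#' Proteins follow the scaffold layout (24-aa signal peptide, 90/92/92-aa
#' alpha domains, 10-aa connecting peptide, 23-aa transmembrane domain, tail
#' of the requested length) with seeded point substitutions restricted to
#' the alpha-domain interiors (planted features are never mutated).  The
#' intended class follows the classifier's documented rule applied to the
#' planted features: no TM or no tail means unclassified; a VPI/IPI/VLIK
#' motif in the TM or a tail of at most `truncated_tail_max` residues means
#' Ib; otherwise Ia.
#'
#' @param spec Tibble with columns `name`, `tm_motif`
#'   (`"none"`/`"VPI"`/`"IPI"`/`"VLIK"`), `tail_len` (0-40), and optionally
#'   `has_tm`, `has_signal`, `drop_alpha3` (logicals, default `TRUE`,
#'   `TRUE`, `FALSE`).
#' @param seed Integer seed.
#' @param substitution_rate Per-site substitution rate in alpha-domain
#'   interiors (substitutions draw from polar residues so no spurious
#'   hydrophobic stretch can arise).
#' @param config Classifier configuration ([class1_config()]); fixes the
#'   truncation threshold used for the intended class.
#' @return List with `proteins` (sequence tibble) and `truth` (tibble of
#'   planted spans, motif, tail length and `intended_class`).
#' @export
make_class1_proteins <- function(spec, seed, substitution_rate = 0.02,
                                 config = class1_config()) {
  sc <- CLASS1_SCAFFOLD
  if (!"has_tm" %in% names(spec)) spec$has_tm <- TRUE
  if (!"has_signal" %in% names(spec)) spec$has_signal <- TRUE
  if (!"drop_alpha3" %in% names(spec)) spec$drop_alpha3 <- FALSE
  stopifnot(all(spec$tail_len >= 0), all(spec$tail_len <= nchar(sc$tail)))
  polar <- c("D", "E", "N", "Q", "K", "R", "S", "T", "H", "Y", "G")
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(nrow(spec)), function(i) {
      r <- spec[i, ]
      tm <- sc$tm
      if (r$tm_motif != "none") {
        m <- r$tm_motif
        substr(tm, 8, 8 + nchar(m) - 1L) <- m
      }
      parts <- list()
      truth <- list()
      pos <- 0L
      add <- function(piece, label) {
        parts[[length(parts) + 1L]] <<- piece
        truth[[label]] <<- c(pos + 1L, pos + nchar(piece))
        pos <<- pos + nchar(piece)
      }
      if (r$has_signal) add(sc$signal, "sp")
      add(sc$alpha1, "a1"); add(sc$alpha2, "a2")
      if (!r$drop_alpha3) add(sc$alpha3, "a3")
      add(sc$connect, "connect")
      if (r$has_tm) add(tm, "tm")
      if (r$tail_len > 0) add(substr(sc$tail, 1, r$tail_len), "ct")
      s <- paste(unlist(parts), collapse = "")
      # substitutions in alpha-domain interiors only
      chars <- strsplit(s, "")[[1]]
      elig <- unlist(lapply(c("a1", "a2", "a3"), function(d) {
        sp <- truth[[d]]
        if (is.null(sp)) return(integer(0))
        (sp[1] + 3L):(sp[2] - 3L)
      }))
      hit <- elig[stats::runif(length(elig)) < substitution_rate]
      for (p in hit) {
        repl <- sample(setdiff(polar, chars[p]), 1L)
        chars[p] <- repl
      }
      s <- paste(chars, collapse = "")
      span <- function(lbl) truth[[lbl]] %||% c(NA_integer_, NA_integer_)
      intended <- if (!r$has_tm) "unclassified"
        else if (r$tail_len == 0) "unclassified"
        else if (r$tm_motif != "none" || r$tail_len <= config$truncated_tail_max) "Ib"
        else "Ia"
      list(seq = s, truth = tibble::tibble(
        protein_id = r$name,
        sp_start = span("sp")[1], sp_end = span("sp")[2],
        a1_start = span("a1")[1], a1_end = span("a1")[2],
        a2_start = span("a2")[1], a2_end = span("a2")[2],
        a3_start = span("a3")[1], a3_end = span("a3")[2],
        tm_start = span("tm")[1], tm_end = span("tm")[2],
        ct_start = span("ct")[1], ct_end = span("ct")[2],
        tm_motif = r$tm_motif, tail_len = r$tail_len,
        intended_class = intended))
    })
    list(proteins = seq_tbl(spec$name, purrr::map_chr(rows, "seq"),
                            alphabet = "protein",
                            description = "synthetic class I protein"),
         truth = purrr::map_dfr(rows, "truth"))
  })
}

#' Random class I protein specification
#'
#' Draws a mixed panel of classical, nonclassical (motif and/or truncated
#' tail) and unclassifiable (no TM, or no tail) proteins with clearly
#' separated tail-length classes (truncated 3-15, canonical 26-33 residues).
#'
#' @param n Number of proteins.
#' @param seed Integer seed.
#' @return A spec tibble for [make_class1_proteins()].
#' @export
sample_class1_spec <- function(n, seed) {
  withr::with_seed(seed, {
    kind <- sample(c("Ia", "Ib_motif", "Ib_trunc", "Ib_both", "no_tm", "no_tail"),
                   n, replace = TRUE, prob = c(0.2, 0.2, 0.2, 0.1, 0.15, 0.15))
    motifs <- c("VPI", "IPI", "VLIK")
    tibble::tibble(
      name = sprintf("SYN%03d", seq_len(n)),
      tm_motif = dplyr::case_when(
        kind %in% c("Ib_motif", "Ib_both") ~ sample(motifs, n, replace = TRUE),
        TRUE ~ "none"),
      tail_len = dplyr::case_when(
        kind %in% c("Ib_trunc", "Ib_both") ~ sample(3:15, n, replace = TRUE),
        kind == "no_tail" ~ 0L,
        TRUE ~ sample(26:33, n, replace = TRUE)),
      has_tm = kind != "no_tm",
      has_signal = TRUE,
      drop_alpha3 = FALSE)
  })
}

#' Clone-local annotations of planted chromosome loci
#'
#' Projects each planted locus that falls fully inside a clone's source
#' interval into that clone's local coordinates (reverse-complemented clones
#' get flipped coordinates and strand), producing the per-clone annotation
#' table consumed by [assemble_map()].
#'
#' @param chrom A `chromosome_truth`.
#' @param clone_truth Clone-truth tibble from [simulate_clone_set()].
#' @return Tibble: `clone_id`, `name`, `start`, `end`, `strand`, `category`.
#' @export
clone_locus_annotations <- function(chrom, clone_truth) {
  purrr::map_dfr(seq_len(nrow(clone_truth)), function(i) {
    cl <- clone_truth[i, ]
    len <- cl$end - cl$start + 1L
    loci <- chrom$loci[chrom$loci$start >= cl$start & chrom$loci$end <= cl$end, ]
    if (!nrow(loci)) return(tibble::tibble())
    ls <- loci$start - cl$start + 1L
    le <- loci$end - cl$start + 1L
    if (cl$orientation == "revcomp") {
      tmp <- ls
      ls <- len - le + 1L
      le <- len - tmp + 1L
      strand <- "-"
    } else strand <- "+"
    tibble::tibble(clone_id = cl$clone_id, name = loci$name, start = ls,
                   end = le, strand = strand, category = loci$category)
  })
}

#' The canonical integration fixture: 20 clones, 5 gaps, planted anomalies
#'
#' A scaled-down clone-set fixture shaped like the study design: 20 clones
#' over a ~100-kb synthetic chromosome partitioned by 5 designated gaps into
#' 6 contigs, with a mix of forward and reverse-complemented clones, one
#' displaced-prefix misassembly (split by an N-run) at the start of clone 6,
#' one planted inversion inside clone 10, a 3-copy repeat family and planted
#' N-runs on the chromosome.
#'
#' @param seed Integer seed.
#' @param clone_len Clone length (bp).
#' @param overlap_len Overlap between consecutive clones within a contig (bp).
#' @param gap_len Gap size between contigs (bp).
#' @return List: `chromosome` (`chromosome_truth`), `clones`, `truth` (clone
#'   truth), `events` (injected event truth per clone), `contig_truth`
#'   (clone id -> contig index), and the layout used.
#' @export
simulate_tiling_fixture <- function(seed, clone_len = 6000, overlap_len = 2000,
                                    gap_len = 2500) {
  n_clones <- 20L
  gaps_after <- c(4L, 8L, 11L, 14L, 17L)
  step <- clone_len - overlap_len
  starts <- integer(n_clones)
  starts[1] <- 500L
  for (i in 2:n_clones) {
    starts[i] <- starts[i - 1L] +
      (if ((i - 1L) %in% gaps_after) clone_len + gap_len else step)
  }
  chrom_len <- max(starts) + clone_len + 500L
  chrom <- make_chromosome(chrom_len, n_loci = 10, n_repeat_families = 1,
                           repeat_copy_number = 3, repeat_length = 500,
                           n_run_spec = c(300L, 150L), seed = seed)
  orient <- withr::with_seed(seed + 1L, {
    o <- rep("forward", n_clones)
    o[sample.int(n_clones, 13L)] <- "revcomp"  # 13 of 20 reverse, as in a
    o                                          # telomeric-to-centromeric set
  })
  orient[c(6L, 10L)] <- "forward"  # clones carrying injected events stay forward
  layout <- tibble::tibble(start = starts, length = clone_len,
                           orientation = orient,
                           gap_after = seq_len(n_clones) %in% gaps_after)
  cs <- simulate_clone_set(chrom, layout, seed = seed + 2L)
  # displaced-prefix misassembly at the 5' end of clone 6 (split by an N-run)
  ev6 <- inject_structural_event(cs$clones[6L, ],
                                 list(kind = "displaced_prefix", L = 700L, D = 2000L,
                                      part1_len = 330L, n_run_len = 44L, D2 = 2900L),
                                 seed = seed + 3L)
  cs$clones[6L, ] <- ev6$clone
  # inversion inside clone 10, outside its overlap regions
  ev10 <- inject_structural_event(cs$clones[10L, ],
                                  list(kind = "inversion", at = 2800L, size = 800L),
                                  seed = seed + 4L)
  cs$clones[10L, ] <- ev10$clone
  contig_truth <- cumsum(c(1L, utils::head(layout$gap_after, -1L)))
  list(chromosome = chrom, clones = cs$clones, truth = cs$truth,
       events = list(CL06 = ev6$truth, CL10 = ev10$truth),
       contig_truth = tibble::tibble(clone_id = cs$truth$clone_id,
                                     contig = contig_truth),
       layout = layout, seed = seed)
}
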