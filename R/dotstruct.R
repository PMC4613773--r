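# Gepard-style dotplot computation and structural-event calling.
# The analysis is read off dotplot geometry (exact word matches, diagonal
# segments), not from scored alignment: indels are diagonal-offset changes,
# inversions are reverse-orientation segments embedded in a forward context,
# interspersed repeats are parallel diagonals, and displaced terminal
# segments betray misassembled clone ends.

#' Dotplot parameters
#'
#' @param word_length Exact-match word length (bp); the study's dotplots use
#'   word length 30.
#' @param min_segment_words Minimum word matches per diagonal segment.
#' @param max_diagonal_gap Maximum within-diagonal gap merged into one
#'   segment (bp).
#' @param min_terminus Minimum unaligned terminal region reported (bp).
#' @param min_projection_fraction Minimum fraction of a clone that must
#'   align for a reference projection.
#' @return Named parameter list.
#' @export
dotplot_params <- function(word_length = 30, min_segment_words = 5,
                           max_diagonal_gap = 2000, min_terminus = 1000,
                           min_projection_fraction = 0.3) {
  stopifnot(word_length >= 8)
  list(word_length = word_length, min_segment_words = min_segment_words,
       max_diagonal_gap = max_diagonal_gap, min_terminus = min_terminus,
       min_projection_fraction = min_projection_fraction)
}

#' Sparse dotplot: all exact word matches in both orientations
#'
#' @param a,b One-row sequence tibbles (self-comparison allowed).
#' @param params Dotplot parameters.
#' @return Tibble of word matches (`pos_a`, `pos_b`, `pos_b_rc`,
#'   `orientation`) with attributes `len_a`, `len_b`, `word_length`.
#' @export
dotplot_matrix <- function(a, b, params = dotplot_params()) {
  m <- word_matches(a$seq[1], b$seq[1], params$word_length)
  attr(m, "len_a") <- nchar(a$seq[1])
  attr(m, "len_b") <- nchar(b$seq[1])
  attr(m, "word_length") <- params$word_length
  m
}

#' Collapse word matches into diagonal segments
#'
#' Maximal runs of at least `min_segment_words` matches on a common diagonal
#' (zero drift), merged across within-diagonal gaps up to
#' `max_diagonal_gap`; sorted by position in `a`.
#'
#' @param matches Dotplot tibble from [dotplot_matrix()].
#' @param params Dotplot parameters.
#' @return Tibble of segments: `a_start`, `a_end`, `b_start`, `b_end`
#'   (native-b), `q_start`, `q_end` (revcomp-b coordinates for reverse
#'   segments), `orientation`, `diag` (signed `q_start - a_start`),
#'   `word_count`.
#' @export
diagonal_segments <- function(matches, params = dotplot_params()) {
  k <- attr(matches, "word_length") %||% params$word_length
  len_b <- attr(matches, "len_b")
  empty <- tibble::tibble(a_start = integer(), a_end = integer(),
                          b_start = integer(), b_end = integer(),
                          q_start = integer(), q_end = integer(),
                          orientation = character(), diag = integer(),
                          word_count = integer())
  if (!nrow(matches)) return(empty)
  segs <- matches %>%
    dplyr::mutate(q = ifelse(.data$orientation == "forward", .data$pos_b,
                             .data$pos_b_rc),
                  diag = .data$q - .data$pos_a) %>%
    dplyr::arrange(.data$orientation, .data$diag, .data$pos_a) %>%
    dplyr::group_by(.data$orientation, .data$diag) %>%
    dplyr::mutate(run = cumsum(c(0L, diff(.data$pos_a) > params$max_diagonal_gap))) %>%
    dplyr::group_by(.data$orientation, .data$diag, .data$run) %>%
    dplyr::summarise(a_start = min(.data$pos_a), a_end = max(.data$pos_a) + k - 1L,
                     q_start = min(.data$q), q_end = max(.data$q) + k - 1L,
                     word_count = dplyr::n(), .groups = "drop") %>%
    dplyr::filter(.data$word_count >= params$min_segment_words) %>%
    dplyr::mutate(
      b_start = ifelse(.data$orientation == "forward", .data$q_start,
                       len_b - .data$q_end + 1L),
      b_end = ifelse(.data$orientation == "forward", .data$q_end,
                     len_b - .data$q_start + 1L)) %>%
    dplyr::arrange(.data$a_start, .data$q_start) %>%
    dplyr::select("a_start", "a_end", "b_start", "b_end", "q_start", "q_end",
                  "orientation", "diag", "word_count")
  segs
}

# maximum-word-count collinear chain over forward segments (the main chain)
main_chain <- function(segments) {
  fwd <- segments[segments$orientation == "forward", ]
  if (!nrow(fwd)) return(fwd)
  fwd <- dplyr::arrange(fwd, .data$a_start, .data$q_start)
  n <- nrow(fwd)
  score <- as.numeric(fwd$word_count)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)[-1]) {
    for (j in seq_len(i - 1L)) {
      if (fwd$a_start[j] < fwd$a_start[i] && fwd$q_start[j] < fwd$q_start[i] &&
          fwd$a_end[j] < fwd$a_end[i] && fwd$q_end[j] < fwd$q_end[i]) {
        cand <- score[j] + fwd$word_count[i]
        if (cand > score[i]) { score[i] <- cand; prev[i] <- j }
      }
    }
  }
  best <- which.max(score)
  path <- integer(0)
  while (!is.na(best)) { path <- c(best, path); best <- prev[path[1]] }
  fwd[path, ]
}

n_fraction <- function(n_runs, start, end) {
  if (is.null(n_runs) || !nrow(n_runs) || end < start) return(0)
  ov <- pmin(n_runs$end, end) - pmax(n_runs$start, start) + 1
  sum(pmax(ov, 0)) / (end - start + 1)
}

event_row <- function(kind, a_start = NA, a_end = NA, b_start = NA, b_end = NA,
                      size = NA, support = "", displacement = NA, group = NA) {
  tibble::tibble(kind = kind, a_start = a_start, a_end = a_end,
                 b_start = b_start, b_end = b_end, size = size,
                 support = support, displacement = displacement, group = group)
}

#' Call structural events from diagonal segments
#'
#' Rules: (i) consecutive main-chain segments with a diagonal-offset change
#' call an indel of that size; (ii) an indel whose spanned region is at
#' least half undefined nucleotides is reclassified `n_run_artifact`;
#' (iii) reverse segments flanked by forward main-chain segments call an
#' inversion sized by the reverse span; (iv) same-orientation segments
#' overlapping in `a` with distinct offsets call an interspersed repeat;
#' (v) a terminal region of either sequence at least `min_terminus` bp with
#' no segment is an unaligned terminus; (vi) a terminal region aligning
#' wholly off the main chain is a displaced segment with its displacement
#' distance.
#'
#' @param segments Segment tibble from [diagonal_segments()].
#' @param a_n_runs,b_n_runs Ambiguity-run tibbles ([find_ambiguity_runs()])
#'   for the two sequences (may be `NULL`).
#' @param params Dotplot parameters.
#' @param len_a,len_b Sequence lengths (taken from segment extent if absent).
#' @return Tibble of structural events.
#' @export
classify_events <- function(segments, a_n_runs = NULL, b_n_runs = NULL,
                            params = dotplot_params(),
                            len_a = NULL, len_b = NULL) {
  events <- list()
  segments <- dplyr::arrange(segments, .data$a_start, .data$q_start)
  main <- main_chain(segments)
  len_a <- len_a %||% max(segments$a_end, 0)
  len_b <- len_b %||% max(segments$b_end, 0)
  seg_id <- function(rows) paste(rows, collapse = ",")
  # (i)/(ii) indels along the main chain
  if (nrow(main) >= 2) {
    for (i in seq_len(nrow(main) - 1L)) {
      delta <- main$diag[i + 1L] - main$diag[i]
      if (delta == 0) next
      a_gap <- c(main$a_end[i] + 1L, main$a_start[i + 1L] - 1L)
      b_gap <- c(main$b_end[i] + 1L, main$b_start[i + 1L] - 1L)
      region_n <- if (delta > 0) n_fraction(b_n_runs, b_gap[1], b_gap[2])
                  else n_fraction(a_n_runs, a_gap[1], a_gap[2])
      kind <- if (region_n >= 0.5) "n_run_artifact" else "indel"
      events[[length(events) + 1L]] <- event_row(
        kind, a_gap[1], a_gap[2], b_gap[1], b_gap[2],
        size = abs(delta), support = seg_id(c(i, i + 1L)),
        displacement = delta)   # signed: positive = extra sequence in b
    }
  }
  # (iii) inversions: reverse segments inside the forward context
  revs <- segments[segments$orientation == "reverse", ]
  if (nrow(revs) && nrow(main)) {
    span_lo <- min(main$a_start); span_hi <- max(main$a_end)
    inside <- revs[revs$a_start >= span_lo & revs$a_end <= span_hi, ]
    if (nrow(inside)) {
      inside <- dplyr::arrange(inside, .data$a_start)
      grp <- cumsum(c(1L, utils::tail(inside$a_start, -1L) -
                        utils::head(inside$a_end, -1L) > params$max_diagonal_gap))
      for (g in unique(grp)) {
        sub <- inside[grp == g, ]
        events[[length(events) + 1L]] <- event_row(
          "inversion", min(sub$a_start), max(sub$a_end),
          min(sub$b_start), max(sub$b_end),
          size = max(sub$a_end) - min(sub$a_start) + 1L,
          support = seg_id(which(grp == g)))
      }
    }
  }
  # (iv) interspersed repeats: parallel same-orientation segments
  for (o in c("forward", "reverse")) {
    sub <- segments[segments$orientation == o, ]
    if (nrow(sub) < 2) next
    # pairs overlapping in a with distinct diagonals
    ov <- which(outer(sub$a_start, sub$a_end, "<=") &
                  outer(sub$a_end, sub$a_start, ">=") &
                  outer(sub$diag, sub$diag, "!=") &
                  upper.tri(matrix(0, nrow(sub), nrow(sub))), arr.ind = TRUE)
    if (!nrow(ov)) next
    members <- sort(unique(c(ov[, 1], ov[, 2])))
    # cluster members chained by a-overlap
    cl <- seq_along(members)
    for (r in seq_len(nrow(ov))) {
      i <- match(ov[r, 1], members); j <- match(ov[r, 2], members)
      cl[cl == cl[j]] <- cl[i]
    }
    for (g in unique(cl)) {
      sub2 <- sub[members[cl == g], ]
      events[[length(events) + 1L]] <- event_row(
        "interspersed_repeat", min(sub2$a_start), max(sub2$a_end),
        min(sub2$b_start), max(sub2$b_end),
        size = max(sub2$a_end) - min(sub2$a_start) + 1L,
        support = seg_id(members[cl == g]))
    }
  }
  # (v)/(vi) terminal regions
  if (nrow(main)) {
    md <- main$diag[which.max(main$word_count)]
    main_key <- paste(main$a_start, main$q_start, main$orientation)
    seg_key <- paste(segments$a_start, segments$q_start, segments$orientation)
    term <- list(
      a5 = c(1L, min(main$a_start) - 1L), a3 = c(max(main$a_end) + 1L, len_a))
    for (side in names(term)) {
      span <- term[[side]]
      width <- span[2] - span[1] + 1L
      if (width < params$min_terminus) next
      off <- segments[!(seg_key %in% main_key) &
                        segments$a_start >= span[1] - params$word_length &
                        segments$a_end <= span[2] + params$word_length, ]
      covered <- if (nrow(off)) sum(pmin(off$a_end, span[2]) -
                                      pmax(off$a_start, span[1]) + 1L) else 0L
      if (covered >= 0.5 * width) {
        for (r in seq_len(nrow(off))) {
          events[[length(events) + 1L]] <- event_row(
            "displaced_segment", off$a_start[r], off$a_end[r],
            off$b_start[r], off$b_end[r],
            size = off$a_end[r] - off$a_start[r] + 1L,
            displacement = abs(off$diag[r] - md), group = side)
        }
      } else {
        events[[length(events) + 1L]] <- event_row(
          "unaligned_terminus", span[1], span[2], size = width, group = side)
      }
    }
    term_b <- list(
      b5 = c(1L, min(main$b_start) - 1L), b3 = c(max(main$b_end) + 1L, len_b))
    for (side in names(term_b)) {
      span <- term_b[[side]]
      width <- span[2] - span[1] + 1L
      if (width < params$min_terminus) next
      off <- segments[!(seg_key %in% main_key) &
                        segments$b_start >= span[1] - params$word_length &
                        segments$b_end <= span[2] + params$word_length, ]
      covered <- if (nrow(off)) sum(pmin(off$b_end, span[2]) -
                                      pmax(off$b_start, span[1]) + 1L) else 0L
      if (covered >= 0.5 * width) {
        for (r in seq_len(nrow(off))) {
          events[[length(events) + 1L]] <- event_row(
            "displaced_segment", off$a_start[r], off$a_end[r],
            off$b_start[r], off$b_end[r],
            size = off$b_end[r] - off$b_start[r] + 1L,
            displacement = abs(off$diag[r] - md), group = side)
        }
      } else {
        events[[length(events) + 1L]] <- event_row(
          "unaligned_terminus", b_start = span[1], b_end = span[2],
          size = width, group = side)
      }
    }
  }
  out <- dplyr::bind_rows(events)
  if (!nrow(out)) return(event_row("none")[0, ])
  dplyr::arrange(out, .data$kind, .data$a_start)
}

#' Project a clone onto reference coordinates
#'
#' The clone is word-matched against the reference; the maximal collinear
#' chain (per orientation, best taken) gives the reference interval the
#' clone covers.  Two clones' projected intervals yield an overlap length
#' (intersection) or a gap size (distance) on the reference.
#'
#' @param clone,reference One-row sequence tibbles.
#' @param params Dotplot parameters.
#' @return One-row tibble (`clone_id`, `ref_start`, `ref_end`,
#'   `orientation`, `coverage`), or `NULL` when less than
#'   `min_projection_fraction` of the clone aligns.
#' @export
project_to_reference <- function(clone, reference, params = dotplot_params()) {
  m <- dotplot_matrix(clone, reference, params)
  segs <- diagonal_segments(m, params)
  if (!nrow(segs)) return(NULL)
  best <- NULL
  for (o in c("forward", "reverse")) {
    sub <- segs[segs$orientation == o, ]
    if (!nrow(sub)) next
    # chain in (a, q) space; q is monotone for both orientations
    sub$orientation <- "forward"
    ch <- main_chain(sub)
    cov <- sum(ch$a_end - ch$a_start + 1L)
    if (is.null(best) || cov > best$cov) best <- list(chain = ch, cov = cov, o = o)
  }
  len_clone <- nchar(clone$seq[1])
  if (best$cov / len_clone < params$min_projection_fraction) return(NULL)
  ch <- best$chain
  len_ref <- nchar(reference$seq[1])
  if (best$o == "forward") {
    rs <- min(ch$b_start); re <- max(ch$b_end)
  } else {
    # b_start/b_end were computed from q assuming forward; recover native
    rs <- min(len_ref - ch$q_end + 1L); re <- max(len_ref - ch$q_start + 1L)
  }
  tibble::tibble(clone_id = clone$id[1], ref_start = rs, ref_end = re,
                 orientation = best$o, coverage = best$cov / len_clone)
}

#' Overlap or gap between two reference-projected intervals
#'
#' @param p1,p2 One-row projections from [project_to_reference()].
#' @return One-row tibble with `relation` (`"overlap"`/`"gap"`) and `size`
#'   (intersection length or separating distance, bp).
#' @export
reference_relation <- function(p1, p2) {
  lo <- max(p1$ref_start, p2$ref_start)
  hi <- min(p1$ref_end, p2$ref_end)
  if (lo <= hi) {
    tibble::tibble(relation = "overlap", size = hi - lo + 1)
  } else {
    tibble::tibble(relation = "gap", size = lo - hi - 1)
  }
}

#' Project tiling-path contigs onto a reference
#'
#' Projects each contig's first and last clone and returns the reference
#' span per contig, for use as a contig-order hint in [call_gaps()].
#'
#' @param path A `tiling_path`.
#' @param clones Sequence tibble containing the path's clones.
#' @param reference One-row sequence tibble.
#' @param params Dotplot parameters.
#' @return Tibble (`contig`, `ref_start`, `ref_end`, `reversed`); contigs
#'   that fail to project are omitted.  `reversed` is `TRUE` when the
#'   contig's internal direction opposes the reference direction (the
#'   assembly is flip-equivalent, so this is resolvable only by projection).
#' @export
project_contigs <- function(path, clones, reference, params = dotplot_params()) {
  purrr::map_dfr(unique(path$contigs$contig), function(ctg) {
    sub <- path$contigs[path$contigs$contig == ctg, ]
    edge_ids <- unique(c(sub$clone_id[1], sub$clone_id[nrow(sub)]))
    projs <- purrr::compact(purrr::map(edge_ids, function(id) {
      project_to_reference(clones[clones$id == id, ], reference, params)
    }))
    if (!length(projs)) return(tibble::tibble())
    pr <- dplyr::bind_rows(projs)
    # a contig runs along the reference iff clone placement orientation and
    # clone-vs-reference projection orientation agree (majority over edges)
    o_c <- sub$orientation[match(pr$clone_id, sub$clone_id)]
    rev_votes <- (o_c == "forward") != (pr$orientation == "forward")
    tibble::tibble(contig = ctg, ref_start = min(pr$ref_start),
                   ref_end = max(pr$ref_end),
                   reversed = mean(rev_votes) > 0.5)
  })
}

#' Orient and order a tiling path along a reference projection
#'
#' Contigs are re-ordered by projected reference start and any contig whose
#' internal direction opposes the reference is flipped (clone order
#' reversed, orientations toggled, offsets mirrored), fixing the map
#' direction (telomeric to centromeric when the reference runs that way).
#'
#' @param path A `tiling_path`.
#' @param hint Projection tibble from [project_contigs()].
#' @return The re-oriented `tiling_path`.
#' @export
apply_reference_orientation <- function(path, hint) {
  contigs <- path$contigs
  for (i in seq_len(nrow(hint))) {
    if (!isTRUE(hint$reversed[i])) next
    sel <- contigs$contig == hint$contig[i]
    sub <- contigs[sel, ]
    span <- max(sub$offset + sub$length)
    sub$offset <- span - (sub$offset + sub$length)
    sub$orientation <- ifelse(sub$orientation == "forward", "revcomp", "forward")
    sub <- sub[order(sub$offset), ]
    sub$rank <- seq_len(nrow(sub))
    contigs[sel, ] <- sub
  }
  ord <- hint$contig[order(hint$ref_start)]
  ord <- c(ord, setdiff(unique(contigs$contig), ord))
  path$contigs <- contigs[order(match(contigs$contig, ord), contigs$rank), ]
  path$contig_order <- "reference-projected"
  path
}

#' Scan a clone against itself for misassembly signatures
#'
#' Self-dotplot with the trivial main diagonal masked.  Off-diagonal
#' segments whose span lies in a terminal window are reported as displaced
#' segments with their origin offset (`displacement`, positive = the true
#' origin lies downstream); a displaced prefix split by an N-run yields two
#' events sharing a group id.  Other off-diagonal segments are reported as
#' interspersed repeats.
#'
#' @param clone One-row sequence tibble.
#' @param params Dotplot parameters.
#' @param terminal_window Terminal span examined for displaced segments (bp).
#' @return Tibble of structural events (possibly empty).
#' @export
self_consistency_scan <- function(clone, params = dotplot_params(),
                                  terminal_window = 1000) {
  m <- dotplot_matrix(clone, clone, params)
  len <- attr(m, "len_a")
  m2 <- m[!(m$orientation == "forward" & m$pos_b == m$pos_a), ]
  m2 <- m2[m2$pos_b >= m2$pos_a, ]  # self-plot is symmetric: keep upper triangle
  attr(m2, "len_a") <- len; attr(m2, "len_b") <- len
  attr(m2, "word_length") <- attr(m, "word_length")
  segs <- diagonal_segments(m2, params)
  if (!nrow(segs)) {
    return(event_row("none")[0, ])
  }
  is_term <- segs$a_end <= terminal_window |
    segs$a_start >= len - terminal_window + 1L
  events <- list()
  disp <- segs[is_term & segs$orientation == "forward", ]
  if (nrow(disp)) {
    disp <- dplyr::arrange(disp, .data$a_start)
    n_runs <- find_ambiguity_runs(clone, min_len = 1)
    grp <- 1L
    grps <- integer(nrow(disp))
    grps[1] <- 1L
    if (nrow(disp) > 1) {
      for (i in 2:nrow(disp)) {
        gap_lo <- disp$a_end[i - 1L] + 1L
        gap_hi <- disp$a_start[i] - 1L
        gap <- gap_hi - gap_lo + 1L
        joined <- gap <= 0 || gap <= 100 ||
          n_fraction(n_runs, gap_lo, gap_hi) >= 0.5
        if (!joined) grp <- grp + 1L
        grps[i] <- grp
      }
    }
    for (i in seq_len(nrow(disp))) {
      events[[length(events) + 1L]] <- event_row(
        "displaced_segment", disp$a_start[i], disp$a_end[i],
        disp$b_start[i], disp$b_end[i],
        size = disp$a_end[i] - disp$a_start[i] + 1L,
        displacement = disp$b_start[i] - disp$a_start[i],
        group = sprintf("prefix%d", grps[i]))
    }
  }
  reps <- segs[!(is_term & segs$orientation == "forward"), ]
  for (i in seq_len(nrow(reps))) {
    events[[length(events) + 1L]] <- event_row(
      "interspersed_repeat", reps$a_start[i], reps$a_end[i],
      reps$b_start[i], reps$b_end[i],
      size = reps$a_end[i] - reps$a_start[i] + 1L)
  }
  out <- dplyr::bind_rows(events)
  if (!nrow(out)) return(event_row("none")[0, ])
  dplyr::arrange(out, .data$a_start)
}
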