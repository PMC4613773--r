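# Orientation resolution, contig layout and gap calling: turning pairwise
# dovetail overlaps into a tiling path.

#' Resolve clone orientations from pairwise overlap hits
#'
#' Orientations are propagated over a spanning forest of the overlap graph
#' by breadth-first traversal; each component's seed clone is taken forward.
#' A non-tree edge whose orientation flag contradicts the propagated
#' assignment is recorded as a conflict (and later excluded from layout),
#' never an error.
#'
#' @param hits Overlap-hit tibble from [overlap_table()].
#' @return List with `orientation` (tibble `clone_id`, `orientation`) and
#'   `conflicts` (tibble `id_a`, `id_b`, `explanation`).
#' @export
orient_clones <- function(hits) {
  ids <- unique(c(hits$id_a, hits$id_b))
  ori <- stats::setNames(rep(NA_character_, length(ids)), ids)
  conflicts <- tibble::tibble(id_a = character(), id_b = character(),
                              explanation = character())
  flip <- function(o) ifelse(o == "forward", "revcomp", "forward")
  for (seed_id in ids) {
    if (!is.na(ori[seed_id])) next
    ori[seed_id] <- "forward"
    queue <- seed_id
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      adj <- hits[hits$id_a == cur | hits$id_b == cur, ]
      for (r in seq_len(nrow(adj))) {
        other <- if (adj$id_a[r] == cur) adj$id_b[r] else adj$id_a[r]
        want <- if (adj$orientation[r] == "forward") ori[cur] else flip(ori[cur])
        if (is.na(ori[other])) {
          ori[other] <- want
          queue <- c(queue, other)
        } else if (ori[other] != want) {
          conflicts <- dplyr::bind_rows(conflicts, tibble::tibble(
            id_a = adj$id_a[r], id_b = adj$id_b[r],
            explanation = "orientation contradicts spanning-tree propagation"))
        }
      }
    }
  }
  list(orientation = tibble::tibble(clone_id = ids, orientation = unname(ori)),
       conflicts = dplyr::distinct(conflicts))
}

# oriented start of a span within a clone of length len
orient_pos <- function(start, end, len, orientation) {
  if (orientation == "forward") c(start, end) else c(len - end + 1L, len - start + 1L)
}

#' Order clones into contigs from overlap geometry
#'
#' Connected components of the (conflict-free) overlap graph become contigs;
#' within a component clone offsets are propagated from dovetail overlap
#' spans, and clones are ordered by offset.  When a clone has more than two
#' partners, lowest-identity excess edges are dropped and logged.  A
#' component that still cannot be linearised is flagged tangled and its
#' clones listed as unplaced.  Contigs are ordered by decreasing span
#' (an arbitrary but deterministic order until a reference hint is applied).
#'
#' @param hits Overlap-hit tibble.
#' @param orientation Result of [orient_clones()].
#' @param all_clones Optional tibble (`clone_id`, `length`) so clones with
#'   no overlaps become singleton contigs.
#' @param word_length Offset-consistency tolerance is `word_length - 1` bp.
#' @return A `tiling_path` object: list with `contigs` (tibble `contig`,
#'   `rank`, `clone_id`, `orientation`, `offset`, `length`), `gaps` (empty
#'   until [call_gaps()]), `unplaced`, `conflicts`, `dropped_edges`.
#' @export
layout_contigs <- function(hits, orientation, all_clones = NULL, word_length = 30) {
  if (!nrow(hits)) {
    hits <- tibble::tibble(id_a = character(), id_b = character(),
                           a_start = integer(), a_end = integer(),
                           b_start = integer(), b_end = integer(),
                           orientation = character(), identity = numeric(),
                           suspect_terminus = character(),
                           suspect_len = numeric(), len_a = integer(),
                           len_b = integer())
  }
  ori <- stats::setNames(orientation$orientation$orientation,
                         orientation$orientation$clone_id)
  conflicts <- orientation$conflicts
  lens <- c(stats::setNames(hits$len_a, hits$id_a),
            stats::setNames(hits$len_b, hits$id_b))
  lens <- lens[!duplicated(names(lens))]
  use <- hits
  if (nrow(conflicts)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    use <- use[!(key(use$id_a, use$id_b) %in% key(conflicts$id_a, conflicts$id_b)), ]
  }
  # drop lowest-identity excess edges at clones with more than two partners
  dropped <- use[0, ]
  repeat {
    deg <- table(c(use$id_a, use$id_b))
    busy <- names(deg)[deg > 2]
    if (!length(busy)) break
    cand <- use[use$id_a %in% busy | use$id_b %in% busy, ]
    worst <- which(use$identity == min(cand$identity) &
                     (use$id_a %in% busy | use$id_b %in% busy))[1]
    dropped <- dplyr::bind_rows(dropped, use[worst, ])
    use <- use[-worst, ]
  }
  ids <- unique(c(use$id_a, use$id_b))
  offset <- stats::setNames(rep(NA_real_, length(ids)), ids)
  comp <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  ncomp <- 0L
  for (seed_id in ids) {
    if (!is.na(comp[seed_id])) next
    ncomp <- ncomp + 1L
    comp[seed_id] <- ncomp
    offset[seed_id] <- 0
    queue <- seed_id
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      adj <- use[use$id_a == cur | use$id_b == cur, ]
      for (r in seq_len(nrow(adj))) {
        a <- adj$id_a[r]; b <- adj$id_b[r]
        other <- if (a == cur) b else a
        sa <- orient_pos(adj$a_start[r], adj$a_end[r], adj$len_a[r], ori[a])
        sb <- orient_pos(adj$b_start[r], adj$b_end[r], adj$len_b[r], ori[b])
        # same map position: offset[a] + sa[1] == offset[b] + sb[1]
        delta <- sa[1] - sb[1]   # offset[b] - offset[a]
        implied <- if (a == cur) offset[cur] + delta else offset[cur] - delta
        if (is.na(offset[other])) {
          offset[other] <- implied
          comp[other] <- ncomp
          queue <- c(queue, other)
        } else if (abs(offset[other] - implied) > word_length - 1) {
          conflicts <- dplyr::bind_rows(conflicts, tibble::tibble(
            id_a = a, id_b = b,
            explanation = sprintf("offset inconsistency of %.0f bp",
                                  abs(offset[other] - implied))))
        }
      }
    }
  }
  contigs <- tibble::tibble(clone_id = ids, component = unname(comp[ids]),
                            orientation = unname(ori[ids]),
                            offset = unname(offset[ids]),
                            length = unname(lens[ids]))
  # singleton contigs for clones without any overlap
  if (!is.null(all_clones)) {
    lone <- all_clones[!all_clones$clone_id %in% ids, ]
    if (nrow(lone)) {
      contigs <- dplyr::bind_rows(contigs, tibble::tibble(
        clone_id = lone$clone_id, component = ncomp + seq_len(nrow(lone)),
        orientation = "forward", offset = 0, length = lone$length))
      ncomp <- ncomp + nrow(lone)
    }
  }
  # linearity check: consecutive clones in a component must share a used hit
  unplaced <- character(0)
  tangled <- integer(0)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  hit_keys <- key(use$id_a, use$id_b)
  for (cmp in unique(contigs$component)) {
    sub <- contigs[contigs$component == cmp, ]
    sub <- sub[order(sub$offset), ]
    if (nrow(sub) < 2) next
    pairs <- key(sub$clone_id[-nrow(sub)], sub$clone_id[-1])
    if (!all(pairs %in% hit_keys)) {
      tangled <- c(tangled, cmp)
      unplaced <- c(unplaced, sub$clone_id)
    }
  }
  contigs <- contigs[!contigs$component %in% tangled, ]
  # normalise offsets and order contigs by decreasing span
  contigs <- contigs %>%
    dplyr::group_by(.data$component) %>%
    dplyr::mutate(offset = .data$offset - min(.data$offset)) %>%
    dplyr::arrange(.data$offset, .by_group = TRUE) %>%
    dplyr::mutate(span = max(.data$offset + .data$length)) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(dplyr::desc(.data$span), .data$component)
  contig_ids <- stats::setNames(
    sprintf("ctg%d", seq_along(unique(contigs$component))),
    unique(contigs$component))
  contigs <- contigs %>%
    dplyr::mutate(contig = unname(contig_ids[as.character(.data$component)])) %>%
    dplyr::group_by(.data$contig) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::ungroup() %>%
    dplyr::select("contig", "rank", "clone_id", "orientation", "offset", "length")
  suspects <- hits[hits$suspect_terminus != "", c("id_a", "id_b", "suspect_terminus",
                                                  "suspect_len")]
  structure(list(contigs = contigs, gaps = tibble::tibble(),
                 unplaced = unplaced, conflicts = dplyr::distinct(conflicts),
                 dropped_edges = dropped, suspect_termini = suspects,
                 contig_order = "arbitrary (decreasing span)"),
            class = "tiling_path")
}

#' Call gaps between consecutive contigs
#'
#' One gap record per pair of consecutive contigs.  Without a reference hint
#' the contig order is the path's own (decreasing span, flagged arbitrary)
#' and gap sizes are unknown; with a reference projection hint the contigs
#' are re-ordered along the reference and gap sizes estimated from projected
#' intervals.
#'
#' @param path A `tiling_path`.
#' @param contig_order_hint Optional tibble (`contig`, `ref_start`,
#'   `ref_end`) from [project_contigs()].
#' @return Tibble of gap records (`left_contig`, `right_contig`,
#'   `left_clone`, `right_clone`, `size_estimate`, `evidence`).
#' @export
call_gaps <- function(path, contig_order_hint = NULL) {
  contigs <- path$contigs
  order_ids <- unique(contigs$contig)
  hinted <- !is.null(contig_order_hint)
  if (hinted) {
    unknown <- setdiff(contig_order_hint$contig, order_ids)
    if (length(unknown)) stop("parameter error: hint references unknown contigs: ",
                              paste(unknown, collapse = ", "))
    h <- contig_order_hint[order(contig_order_hint$ref_start), ]
    order_ids <- c(h$contig, setdiff(order_ids, h$contig))
  }
  if (length(order_ids) < 2) {
    return(tibble::tibble(left_contig = character(), right_contig = character(),
                          left_clone = character(), right_clone = character(),
                          size_estimate = numeric(), evidence = character()))
  }
  edge_clone <- function(ctg, side) {
    sub <- contigs[contigs$contig == ctg, ]
    if (side == "right") sub$clone_id[which.max(sub$rank)] else sub$clone_id[1]
  }
  purrr::map_dfr(seq_len(length(order_ids) - 1L), function(i) {
    lc <- order_ids[i]; rc <- order_ids[i + 1L]
    size <- NA_real_
    evidence <- "no-overlap"
    if (hinted && all(c(lc, rc) %in% contig_order_hint$contig)) {
      hl <- contig_order_hint[contig_order_hint$contig == lc, ]
      hr <- contig_order_hint[contig_order_hint$contig == rc, ]
      size <- max(hr$ref_start - hl$ref_end - 1, 0)
      evidence <- "reference-projection"
    }
    tibble::tibble(left_contig = lc, right_contig = rc,
                   left_clone = edge_clone(lc, "right"),
                   right_clone = edge_clone(rc, "left"),
                   size_estimate = size, evidence = evidence)
  })
}

#' Compare a tiling path against generator truth
#'
#' @param path A `tiling_path`.
#' @param truth Clone-truth tibble from [simulate_clone_set()].
#' @return List: `partition_match`, `order_match`, `orientation_match`
#'   (per-contig flips allowed), `junctions` (per-junction offset deviations
#'   in bp) and `max_junction_deviation`.
#' @export
compare_to_truth <- function(path, truth) {
  contigs <- path$contigs
  if (!setequal(c(contigs$clone_id, path$unplaced), truth$clone_id)) {
    stop("parameter error: clone ids in path and truth differ")
  }
  truth_contig <- cumsum(c(1L, utils::head(truth$gap_after, -1L)))
  truth_sets <- split(truth$clone_id, truth_contig)
  path_sets <- split(contigs$clone_id, contigs$contig)
  canon <- function(sets) sort(unname(vapply(sets, function(s)
    paste(sort(s), collapse = ","), character(1))))
  partition_match <- identical(canon(truth_sets), canon(path_sets))
  order_match <- TRUE
  orientation_match <- TRUE
  junctions <- tibble::tibble(left = character(), right = character(),
                              deviation = numeric())
  truth_by_id <- truth[match(contigs$clone_id, truth$clone_id), ]
  for (ctg in unique(contigs$contig)) {
    sub <- contigs[contigs$contig == ctg, ]
    tr <- truth[match(sub$clone_id, truth$clone_id), ]
    ord_truth <- order(tr$start)
    fwd <- identical(ord_truth, seq_len(nrow(sub)))
    rev <- identical(ord_truth, rev(seq_len(nrow(sub))))
    if (!(fwd || rev)) order_match <- FALSE
    same <- sub$orientation == tr$orientation
    flipped <- sub$orientation != tr$orientation
    if (!(all(same) || all(flipped))) orientation_match <- FALSE
    if (nrow(sub) >= 2 && (fwd || rev)) {
      est_delta <- diff(sub$offset)
      truth_delta <- if (fwd) diff(tr$start) else -diff(tr$start)
      junctions <- dplyr::bind_rows(junctions, tibble::tibble(
        left = sub$clone_id[-nrow(sub)], right = sub$clone_id[-1],
        deviation = abs(est_delta - truth_delta)))
    }
  }
  list(partition_match = partition_match, order_match = order_match,
       orientation_match = orientation_match, junctions = junctions,
       max_junction_deviation = if (nrow(junctions)) max(junctions$deviation) else 0)
}

#' @export
print.tiling_path <- function(x, ...) {
  n_ctg <- length(unique(x$contigs$contig))
  cat(sprintf("<tiling_path> %d clones in %d contig(s); %d unplaced; %d gap(s) called\n",
              nrow(x$contigs), n_ctg, length(x$unplaced), nrow(x$gaps)))
  cat(sprintf("contig order: %s\n", x$contig_order))
  print(x$contigs, ...)
  invisible(x)
}
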