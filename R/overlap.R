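#' Parameters for pairwise overlap detection
#'
#' The source study gives no numeric thresholds for calling an overlap;
#' these defaults reproduce its qualitative calls and are all exposed here.
#'
#' @param word_length Exact-match word length in bp (the dotplot word size).
#' @param min_overlap Minimum overlap span to report (bp).
#' @param min_identity Minimum identity over the chained alignment.
#' @param end_slack How close a chain must come to the facing clone ends to
#'   count as a dovetail (bp).
#' @param max_gap Maximum inter-anchor gap bridged by a chain (bp); large
#'   enough to bridge multi-kb runs of undefined nucleotides.
#' @param max_diag_drift Maximum diagonal drift within a chain (bp).
#' @param prefix_slack A non-matching terminal segment up to this size does
#'   not veto an otherwise-dovetail overlap; it is annotated as a suspect
#'   terminus instead (the displaced-prefix misassembly case).
#' @return Named list of parameters.
#' @export
overlap_params <- function(word_length = 30, min_overlap = 1000,
                           min_identity = 0.95, end_slack = 500,
                           max_gap = 6000, max_diag_drift = 300,
                           prefix_slack = 1000) {
  stopifnot(word_length >= 8)
  list(word_length = word_length, min_overlap = min_overlap,
       min_identity = min_identity, end_slack = end_slack,
       max_gap = max_gap, max_diag_drift = max_diag_drift,
       prefix_slack = prefix_slack)
}

#' Best collinear anchor chain per orientation
#'
#' Chains are monotone in both coordinates (reverse-orientation anchors are
#' pre-flipped into revcomp-b coordinates), broken where the inter-anchor
#' gap exceeds `max_gap` or the diagonal drifts more than `max_diag_drift`.
#' The highest-coverage chain of each orientation is returned.
#'
#' @param anchors Anchor tibble from [anchor_matches()].
#' @param max_gap,max_diag_drift Chain-breaking thresholds (bp).
#' @return Named list with elements `forward` and `reverse`, each an anchor
#'   tibble (possibly empty) with a `coverage` attribute (matched bp).
#' @export
chain_anchors <- function(anchors, max_gap = 6000, max_diag_drift = 300) {
  out <- lapply(c(forward = "forward", reverse = "reverse"), function(o) {
    chain_one_orientation(anchors[anchors$orientation == o, , drop = FALSE],
                          max_gap, max_diag_drift)
  })
  out
}

# matched bp / identity over a chain, plus ungapped boundary extension.
# a_chr / b_chr are single-character vectors of a and of b-in-chain-orientation.
# Returns list(a_start, a_end, q_start, q_end, matched, aligned).
chain_alignment <- function(chain, a_chr, b_chr, window = 50, min_window_identity = 0.8) {
  ord <- order(chain$pos_a)
  pa <- chain$pos_a[ord]; q <- chain$q[ord]; len <- chain$length[ord]
  ea <- pa + len - 1L; eq <- q + len - 1L
  matched <- 0L; aligned <- 0L
  for (i in seq_along(pa)) {
    ov <- if (i == 1L) 0L else max(0L, ea[i - 1L] - pa[i] + 1L, eq[i - 1L] - q[i] + 1L)
    matched <- matched + len[i] - ov
    aligned <- aligned + len[i] - ov
    if (i > 1L) {
      ga <- pa[i] - ea[i - 1L] - 1L
      gq <- q[i] - eq[i - 1L] - 1L
      if (ga > 0L || gq > 0L) {
        if (ga == gq) {
          matched <- matched +
            sum(a_chr[(ea[i - 1L] + 1L):(pa[i] - 1L)] == b_chr[(eq[i - 1L] + 1L):(q[i] - 1L)])
        }
        aligned <- aligned + max(ga, gq, 0L)
      }
    }
  }
  ext <- function(i0, j0, step) {
    # greedy ungapped extension; stop when identity in the trailing window
    # drops below min_window_identity, then trim back to the last match
    i <- i0; j <- j0; hits <- integer(8192); add <- 0L; last_match <- 0L; n <- 0L
    na <- length(a_chr); nb <- length(b_chr)
    while (i >= 1L && i <= na && j >= 1L && j <= nb && n < 8000L) {
      m <- a_chr[i] == b_chr[j]
      n <- n + 1L; hits[n] <- m
      if (m) { last_match <- n; add <- add + 1L }
      if (n >= 20L) {
        w <- hits[max(1L, n - window + 1L):n]
        if (mean(w) < min_window_identity) break
      }
      i <- i + step; j <- j + step
    }
    list(steps = last_match, matched = if (last_match) sum(hits[seq_len(last_match)]) else 0L)
  }
  up <- ext(pa[1] - 1L, q[1] - 1L, -1L)
  dn <- ext(ea[length(ea)] + 1L, eq[length(eq)] + 1L, +1L)
  list(a_start = pa[1] - up$steps, a_end = ea[length(ea)] + dn$steps,
       q_start = q[1] - up$steps, q_end = eq[length(eq)] + dn$steps,
       matched = matched + up$matched + dn$matched,
       aligned = aligned + up$steps + dn$steps)
}

#' Detect the best dovetail overlap between two clones
#'
#' Anchors are chained in both orientations; the best chain is extended to
#' refined boundaries and tested for dovetail geometry (the overlap must
#' reach the facing ends of both clones within `end_slack`).  A non-matching
#' terminal segment of at most `prefix_slack` bp does not reject the hit but
#' is annotated as a suspect terminus.  Coordinates are reported in each
#' clone's native orientation, 1-based inclusive.
#'
#' @param a,b One-row sequence tibbles.
#' @param params Parameter list from [overlap_params()].
#' @return A one-row tibble (`id_a`, `id_b`, `a_start`, `a_end`, `b_start`,
#'   `b_end`, `orientation`, `direction`, `matched_bp`, `identity`,
#'   `dovetail`, `suspect_terminus`, `suspect_len`, `len_a`, `len_b`), or
#'   `NULL` when no chain passes the thresholds.  `direction` is `"ab"` when
#'   `a`'s 3' end overlaps the (orientation-normalised) 5' end of `b`.
#' @export
detect_overlap <- function(a, b, params = overlap_params()) {
  p <- params
  a_seq <- a$seq[1]; b_seq <- b$seq[1]
  len_a <- nchar(a_seq); len_b <- nchar(b_seq)
  m <- word_matches(a_seq, b_seq, p$word_length)
  anc <- merge_anchors(m, p$word_length)
  if (!nrow(anc)) return(NULL)
  chains <- chain_anchors(anc, p$max_gap, p$max_diag_drift)
  cov_f <- if (nrow(chains$forward)) attr(chains$forward, "coverage") else -Inf
  cov_r <- if (nrow(chains$reverse)) attr(chains$reverse, "coverage") else -Inf
  ambiguous <- is.finite(cov_f) && is.finite(cov_r) && cov_f == cov_r
  orientation <- if (cov_f >= cov_r) "forward" else "reverse"  # forward wins ties
  chain <- chains[[orientation]]
  if (!nrow(chain)) return(NULL)
  b_chr <- strsplit(if (orientation == "forward") b_seq else revcomp_chr(b_seq), "")[[1]]
  a_chr <- strsplit(a_seq, "")[[1]]
  al <- chain_alignment(chain, a_chr, b_chr)
  span_len <- al$a_end - al$a_start + 1L
  identity <- al$matched / max(al$aligned, 1L)
  if (span_len < p$min_overlap || identity < p$min_identity) return(NULL)
  # dovetail geometry in (a forward, b-in-chain-orientation) coordinates
  t_ab <- max(len_a - al$a_end, al$q_start - 1L)      # a precedes b'
  t_ba <- max(len_b - al$q_end, al$a_start - 1L)      # b' precedes a
  direction <- if (t_ab <= t_ba) "ab" else "ba"
  t <- min(t_ab, t_ba)
  if (t > p$prefix_slack) return(NULL)
  suspect <- t > p$end_slack
  suspect_side <- ""
  if (suspect) {
    # which facing terminus carries the unmatched segment
    if (direction == "ab") {
      suspect_side <- if ((len_a - al$a_end) >= (al$q_start - 1L)) "a3" else "b5"
    } else {
      suspect_side <- if ((len_b - al$q_end) >= (al$a_start - 1L)) "b3" else "a5"
    }
  }
  # native-b coordinates of the overlap span
  if (orientation == "forward") {
    b_start <- al$q_start; b_end <- al$q_end
  } else {
    b_start <- len_b - al$q_end + 1L; b_end <- len_b - al$q_start + 1L
  }
  tibble::tibble(id_a = a$id[1], id_b = b$id[1],
                 a_start = al$a_start, a_end = al$a_end,
                 b_start = b_start, b_end = b_end,
                 orientation = orientation, direction = direction,
                 matched_bp = al$matched, identity = identity,
                 dovetail = TRUE, suspect_terminus = suspect_side,
                 suspect_len = if (suspect) t else 0L,
                 ambiguous_orientation = ambiguous,
                 len_a = len_a, len_b = len_b)
}

#' All pairwise dovetail overlaps in a clone set
#'
#' Every unordered clone pair is screened with a shared-word prefilter and
#' tested in both orientations; one row per overlapping pair.  When the hits
#' support a linear tiling path the rows are sorted along it, otherwise by
#' clone id.
#'
#' @param clones Sequence tibble of two or more clones.
#' @param params Parameter list from [overlap_params()].
#' @return Tibble of overlap hits (see [detect_overlap()]); zero rows if none.
#' @export
overlap_table <- function(clones, params = overlap_params()) {
  empty_hits <- tibble::tibble(
    id_a = character(), id_b = character(), a_start = integer(),
    a_end = integer(), b_start = integer(), b_end = integer(),
    orientation = character(), direction = character(),
    matched_bp = numeric(), identity = numeric(), dovetail = logical(),
    suspect_terminus = character(), suspect_len = numeric(),
    ambiguous_orientation = logical(), len_a = integer(), len_b = integer())
  if (nrow(clones) < 2) return(empty_hits)
  k <- params$word_length
  # prefilter on words sampled every 16 bp
  sampled <- lapply(clones$seq, function(s) {
    kp <- kmer_positions(s, k)
    kp$word[kp$pos %% 16L == 1L]
  })
  wordsets <- lapply(clones$seq, function(s) {
    c(kmer_positions(s, k)$word, kmer_positions(revcomp_chr(s), k)$word)
  })
  n <- nrow(clones)
  hits <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (sum(sampled[[i]] %in% wordsets[[j]]) < 5L) next
      h <- detect_overlap(clones[i, ], clones[j, ], params)
      if (!is.null(h)) hits[[length(hits) + 1L]] <- h
    }
  }
  out <- dplyr::bind_rows(hits)
  if (!nrow(out)) return(empty_hits)
  # sort along the inferred path when one exists
  ord <- tryCatch({
    path <- layout_contigs(out, orient_clones(out))
    rank <- stats::setNames(seq_len(nrow(path$contigs)),
                            path$contigs$clone_id)
    order(pmin(rank[out$id_a], rank[out$id_b], na.rm = TRUE))
  }, error = function(e) order(out$id_a, out$id_b))
  out[ord, ]
}
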