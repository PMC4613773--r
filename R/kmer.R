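# Exact word-match engine shared by the overlap and dotplot stages.
# Words containing N never match (any ambiguity is non-informative).

# All word start positions and words of length k, N-containing words dropped.
kmer_positions <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(tibble::tibble(pos = integer(), word = character()))
  pos <- seq_len(n - k + 1L)
  word <- substring(seq, pos, pos + k - 1L)
  keep <- !grepl("N", word, fixed = TRUE)
  tibble::tibble(pos = pos[keep], word = word[keep])
}

# Word matches between a and b in both orientations.  Coordinates are
# 1-based word start positions; for reverse matches pos_b is the start of
# the matched word in b's NATIVE coordinates and pos_b_rc its start in
# revcomp(b) coordinates (pos_b = len_b - (pos_b_rc + k - 1) + 1).
# Self-comparison (a identical to b) is supported.
word_matches <- function(a_seq, b_seq, k, ka = NULL, kb = NULL, kb_rc = NULL) {
  if (is.null(ka)) ka <- kmer_positions(a_seq, k)
  if (is.null(kb)) kb <- kmer_positions(b_seq, k)
  if (is.null(kb_rc)) kb_rc <- kmer_positions(revcomp_chr(b_seq), k)
  len_b <- nchar(b_seq)
  fwd <- dplyr::inner_join(ka, kb, by = "word", suffix = c("_a", "_b"),
                           relationship = "many-to-many")
  rev <- dplyr::inner_join(ka, kb_rc, by = "word", suffix = c("_a", "_b"),
                           relationship = "many-to-many")
  dplyr::bind_rows(
    tibble::tibble(pos_a = fwd$pos_a, pos_b = fwd$pos_b,
                   pos_b_rc = len_b - (fwd$pos_b + k - 1L) + 1L,
                   orientation = rep("forward", nrow(fwd))),
    tibble::tibble(pos_a = rev$pos_a,
                   pos_b = len_b - (rev$pos_b + k - 1L) + 1L,
                   pos_b_rc = rev$pos_b,
                   orientation = rep("reverse", nrow(rev)))
  )
}

# Merge word matches into maximal exact matches (anchors).  Within one
# orientation, word hits on a common diagonal at consecutive positions
# belong to one maximal match of length run + k - 1.
# q = pos_b for forward, pos_b_rc for reverse (monotone coordinate).
merge_anchors <- function(matches, k) {
  if (!nrow(matches)) {
    return(tibble::tibble(pos_a = integer(), pos_b = integer(), q = integer(),
                          length = integer(), orientation = character()))
  }
  matches %>%
    dplyr::mutate(q = ifelse(.data$orientation == "forward", .data$pos_b, .data$pos_b_rc),
                  diag = .data$q - .data$pos_a) %>%
    dplyr::arrange(.data$orientation, .data$diag, .data$pos_a) %>%
    dplyr::group_by(.data$orientation, .data$diag) %>%
    dplyr::mutate(run = cumsum(c(1L, diff(.data$pos_a) != 1L))) %>%
    dplyr::group_by(.data$orientation, .data$diag, .data$run) %>%
    dplyr::summarise(pos_a = min(.data$pos_a), q = min(.data$q),
                     length = dplyr::n() + k - 1L, .groups = "drop") %>%
    dplyr::mutate(pos_b = ifelse(.data$orientation == "forward", .data$q, NA_integer_)) %>%
    dplyr::select("pos_a", "pos_b", "q", "length", "orientation") %>%
    dplyr::arrange(.data$orientation, .data$pos_a, .data$q)
}

# Fill native-b coordinates for reverse anchors: anchor occupies
# rc positions [q, q+len-1] <=> native [len_b - (q+len-1) + 1, len_b - q + 1].
anchor_native_b <- function(anchors, len_b) {
  dplyr::mutate(anchors,
    b_start = ifelse(.data$orientation == "forward", .data$q,
                     len_b - (.data$q + .data$length - 1L) + 1L),
    b_end = .data$b_start + .data$length - 1L)
}

# Best collinear chain of anchors for one orientation by dynamic programming.
# Monotone in pos_a and q; breaks where the inter-anchor gap exceeds max_gap
# or the diagonal drifts more than max_diag_drift.  Score = covered bp
# (anchor length minus overlap with the previous anchor in the chain).
chain_one_orientation <- function(anc, max_gap, max_diag_drift) {
  n <- nrow(anc)
  if (!n) return(anc[0, ])
  anc <- dplyr::arrange(anc, .data$pos_a, .data$q)
  pa <- anc$pos_a; q <- anc$q; len <- anc$length
  ea <- pa + len - 1L; eq <- q + len - 1L; dg <- q - pa
  score <- as.numeric(len)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)[-1]) {
    lo <- max(1L, i - 400L)  # bounded look-back keeps the DP near-linear
    for (j in lo:(i - 1L)) {
      if (pa[j] >= pa[i] || q[j] >= q[i]) next
      if (abs(dg[i] - dg[j]) > max_diag_drift) next
      gap <- max(pa[i] - ea[j] - 1L, q[i] - eq[j] - 1L)
      if (gap > max_gap) next
      ov <- max(0L, ea[j] - pa[i] + 1L, eq[j] - q[i] + 1L)
      cand <- score[j] + len[i] - ov
      if (cand > score[i]) { score[i] <- cand; prev[i] <- j }
    }
  }
  best <- which.max(score)
  path <- integer(0)
  while (!is.na(best)) { path <- c(best, path); best <- prev[path[1]] }
  out <- anc[path, ]
  attr(out, "coverage") <- max(score)
  out
}

#' Maximal exact word matches between two sequences
#'
#' Reports all maximal exact matches of length at least `word_length` between
#' `a` and `b` in both orientations.  Words containing `N` never match.  For
#' reverse-orientation anchors `b_start`/`b_end` are given in `b`'s native
#' coordinates and `q` is the anchor start in revcomp(`b`) coordinates.
#'
#' @param a,b One-row sequence tibbles (or plain character strings).
#' @param word_length Word length in bp (minimum 8).
#' @return Tibble of anchors: `pos_a`, `b_start`, `b_end`, `q`, `length`,
#'   `orientation`.
#' @export
anchor_matches <- function(a, b, word_length = 30) {
  stopifnot(word_length >= 8)
  a_seq <- if (is.character(a)) a else a$seq[1]
  b_seq <- if (is.character(b)) b else b$seq[1]
  m <- word_matches(a_seq, b_seq, word_length)
  anc <- merge_anchors(m, word_length)
  anchor_native_b(anc, nchar(b_seq)) %>%
    dplyr::select("pos_a", "b_start", "b_end", "q", "length", "orientation")
}
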