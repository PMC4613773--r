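# shared helpers: independent brute-force oracles and tiny sequence builders

random_dna_chr <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

revcomp_oracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# brute-force all-words comparison: every word of a tested against every
# word position of b (forward) and revcomp(b) by direct string equality.
# Deliberately independent of the package's join/merge engine.
brute_force_word_matches <- function(a, b, k) {
  words_of <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }
  wa <- words_of(a)
  hits <- list()
  scan <- function(wb, orientation, len_b) {
    for (i in seq_along(wa)) {
      if (grepl("N", wa[i], fixed = TRUE)) next
      j <- which(wb == wa[i] & !grepl("N", wb, fixed = TRUE))
      if (length(j)) {
        pos_b <- if (orientation == "forward") j else len_b - (j + k - 1L) + 1L
        hits[[length(hits) + 1L]] <<- data.frame(
          pos_a = i, pos_b = pos_b, orientation = orientation)
      }
    }
  }
  scan(words_of(b), "forward", nchar(b))
  scan(words_of(revcomp_oracle(b)), "reverse", nchar(b))
  out <- do.call(rbind, hits)
  if (is.null(out)) out <- data.frame(pos_a = integer(), pos_b = integer(),
                                      orientation = character())
  out[order(out$orientation, out$pos_a, out$pos_b), , drop = FALSE]
}

# canonical word-level view of the package's dotplot for oracle comparison
package_word_matches <- function(a, b, k) {
  m <- bactile::dotplot_matrix(bactile::seq_tbl("a", a), bactile::seq_tbl("b", b),
                               bactile::dotplot_params(word_length = k))
  out <- data.frame(pos_a = m$pos_a, pos_b = m$pos_b, orientation = m$orientation)
  out[order(out$orientation, out$pos_a, out$pos_b), , drop = FALSE]
}
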