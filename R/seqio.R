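#' Sequence tables
#'
#' Sequences are carried through the package as plain tibbles with one row per
#' record and columns `id`, `seq`, `alphabet` (`"nucleotide"` or `"protein"`)
#' and `description`.  Nucleotide sequences are restricted to `A`, `C`, `G`,
#' `T`, `N`; other IUPAC ambiguity codes are converted to `N` on construction
#' (with a warning), since all downstream word matching treats any ambiguity
#' as a non-matchable position.
#'
#' @param id Character vector of unique record identifiers.
#' @param seq Character vector of sequences (same length as `id`).
#' @param alphabet `"nucleotide"` or `"protein"`, recycled across records.
#' @param description Free-text descriptions, recycled.
#' @return A tibble with columns `id`, `seq`, `alphabet`, `description`.
#' @export
seq_tbl <- function(id, seq, alphabet = "nucleotide", description = "") {
  stopifnot(length(id) == length(seq))
  if (anyDuplicated(id)) {
    stop("duplicate sequence ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  alphabet <- rep_len(alphabet, length(id))
  description <- rep_len(description, length(id))
  seq <- toupper(seq)
  if (any(!nzchar(seq))) stop("empty sequence for id ", id[!nzchar(seq)][1])
  is_nt <- alphabet == "nucleotide"
  if (any(is_nt)) {
    bad <- stringr::str_detect(seq[is_nt], "[^ACGTN]")
    if (any(bad)) {
      # non-N IUPAC codes collapse to N; anything else is a format error
      fixed <- gsub("[RYSWKMBDHV]", "N", seq[is_nt][bad])
      still <- stringr::str_locate(fixed, "[^ACGTN]")
      if (any(!is.na(still[, 1]))) {
        i <- which(!is.na(still[, 1]))[1]
        stop(sprintf("illegal character in nucleotide record '%s' at position %d",
                     id[is_nt][bad][i], still[i, 1]))
      }
      warning(sprintf("%d record(s) contained non-N IUPAC ambiguity codes; converted to N",
                      sum(bad)))
      seq[is_nt][bad] <- fixed
    }
  }
  is_aa <- alphabet == "protein"
  if (any(is_aa)) {
    bad <- stringr::str_locate(seq[is_aa], "[^ACDEFGHIKLMNPQRSTVWYX*]")
    if (any(!is.na(bad[, 1]))) {
      i <- which(!is.na(bad[, 1]))[1]
      stop(sprintf("illegal character in protein record '%s' at position %d",
                   id[is_aa][i], bad[i, 1]))
    }
  }
  tibble::tibble(id = as.character(id), seq = seq, alphabet = alphabet,
                 description = as.character(description))
}

#' Read sequences from FASTA or GenBank flatfile
#'
#' FASTA parsing goes through [Biostrings::readBStringSet()]; GenBank
#' flatfiles are parsed with a minimal LOCUS/DEFINITION/ORIGIN reader
#' (sequence and identity only -- features are ignored).  Records are
#' uppercased; order is preserved.
#'
#' @param path Path to the file.
#' @param format `"fasta"` or `"genbank"`.
#' @param alphabet Declared alphabet of the records.
#' @return A sequence tibble (see [seq_tbl()]).
#' @export
load_sequences <- function(path, format = c("fasta", "genbank"),
                           alphabet = "nucleotide") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) stop("FASTA parse error in ", path, ": ",
                                             conditionMessage(e)))
    if (length(set) == 0) stop("format error: no records in ", path)
    nm <- names(set)
    id <- sub("\\s.*$", "", nm)
    desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
    return(seq_tbl(id, unname(as.character(set)), alphabet = alphabet,
                   description = desc))
  }
  read_genbank(path, alphabet = alphabet)
}

# Minimal GenBank flatfile reader: LOCUS name + VERSION (preferred id),
# DEFINITION, ORIGIN sequence block.  Multi-record files ("//" separated)
# are supported.
read_genbank <- function(path, alphabet = "nucleotide") {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(startsWith(lines, "LOCUS"))) {
    stop("format error: ", path, " does not look like a GenBank flatfile")
  }
  rec_start <- which(startsWith(lines, "LOCUS"))
  rec_end <- c(rec_start[-1] - 1L, length(lines))
  recs <- purrr::map2(rec_start, rec_end, function(s, e) {
    chunk <- lines[s:e]
    locus <- strsplit(trimws(chunk[1]), "\\s+")[[1]][2]
    ver <- grep("^VERSION", chunk, value = TRUE)
    id <- if (length(ver)) strsplit(trimws(ver[1]), "\\s+")[[1]][2] else locus
    defn <- grep("^DEFINITION", chunk, value = TRUE)
    desc <- if (length(defn)) sub("^DEFINITION\\s+", "", defn[1]) else ""
    ori <- which(startsWith(chunk, "ORIGIN"))
    if (!length(ori)) stop("format error: record ", id, " has no ORIGIN block")
    stop_at <- which(startsWith(chunk, "//"))
    stop_at <- if (length(stop_at)) stop_at[stop_at > ori[1]][1] else length(chunk) + 1L
    body <- chunk[(ori[1] + 1L):(stop_at - 1L)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
    list(id = id, seq = seq, desc = desc)
  })
  seq_tbl(purrr::map_chr(recs, "id"), purrr::map_chr(recs, "seq"),
          alphabet = alphabet,
          description = purrr::map_chr(recs, "desc"))
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Sequence tibble.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  set <- Biostrings::BStringSet(seqs$seq)
  names(set) <- ifelse(nzchar(seqs$description),
                       paste(seqs$id, seqs$description), seqs$id)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse-complement nucleotide records
#'
#' Each record's id gains an `rc` suffix (or loses one it already has, so the
#' operation is an involution on ids as well as sequences).
#'
#' @param seqs Sequence tibble (nucleotide records only).
#' @return Sequence tibble of the same shape.
#' @export
reverse_complement <- function(seqs) {
  if (any(seqs$alphabet != "nucleotide")) {
    stop("reverse_complement is defined for nucleotide records only")
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs$seq)))
  dplyr::mutate(seqs,
    seq = rc,
    id = ifelse(endsWith(.data$id, "rc"),
                sub("rc$", "", .data$id), paste0(.data$id, "rc")))
}

# revcomp of a bare character string (internal fast path)
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Locate maximal runs of undefined nucleotides (N)
#'
#' @param seqs Sequence tibble (nucleotide).
#' @param min_len Minimum run length to report (bp).
#' @return Tibble with columns `seq_id`, `start`, `end`, `length`; runs are
#'   maximal, disjoint and sorted by start within each record.  Coordinates
#'   are 1-based inclusive.
#' @export
find_ambiguity_runs <- function(seqs, min_len = 1) {
  stopifnot(all(seqs$alphabet == "nucleotide"))
  purrr::map2_dfr(seqs$id, seqs$seq, function(id, s) {
    loc <- stringr::str_locate_all(s, "N+")[[1]]
    if (!nrow(loc)) {
      return(tibble::tibble(seq_id = character(), start = integer(),
                            end = integer(), length = integer()))
    }
    len <- loc[, 2] - loc[, 1] + 1L
    keep <- len >= min_len
    tibble::tibble(seq_id = id, start = as.integer(loc[keep, 1]),
                   end = as.integer(loc[keep, 2]), length = as.integer(len[keep]))
  })
}

#' Extract a sub-sequence by 1-based inclusive coordinates
#'
#' A minus-strand request returns the reverse complement of the forward
#' slice.  Provenance (parent id and coordinates) is recorded in the
#' description.
#'
#' @param seqs Sequence tibble.
#' @param seq_id Id of the record to slice.
#' @param start,end 1-based inclusive span, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return One-row sequence tibble.
#' @export
slice_region <- function(seqs, seq_id, start, end, strand = "+") {
  row <- seqs[seqs$id == seq_id, ]
  if (nrow(row) != 1) stop("unknown seq_id: ", seq_id)
  n <- nchar(row$seq)
  if (start < 1 || end > n || start > end) {
    stop(sprintf("range error: slice (%d,%d) outside 1..%d of '%s'", start, end, n, seq_id))
  }
  s <- substr(row$seq, start, end)
  if (strand == "-") {
    if (row$alphabet != "nucleotide") stop("minus-strand slice requires a nucleotide record")
    s <- revcomp_chr(s)
  }
  seq_tbl(sprintf("%s:%d-%d%s", seq_id, start, end, if (strand == "-") "(-)" else ""),
          s, alphabet = row$alphabet,
          description = sprintf("slice of %s %d..%d strand %s", seq_id, start, end, strand))
}

# Named character vector id -> sequence (internal convenience)
seq_vec <- function(seqs) stats::setNames(seqs$seq, seqs$id)
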