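# Physical-map assembly and cross-map comparison: lifting clone-local locus
# annotations through the tiling path into contiguous map coordinates,
# comparing gene content and order between maps, and placing BAC end
# sequences.

# clone-local -> map coordinates for one clone placement
lift_interval <- function(base, offset, clone_len, orientation, start, end) {
  if (orientation == "forward") {
    c(base + offset + start, base + offset + end)
  } else {
    c(base + offset + (clone_len - end + 1), base + offset + (clone_len - start + 1))
  }
}

# inverse of lift_interval (map -> clone-local)
unlift_interval <- function(base, offset, clone_len, orientation, mstart, mend) {
  if (orientation == "forward") {
    c(mstart - base - offset, mend - base - offset)
  } else {
    c(clone_len - (mend - base - offset) + 1, clone_len - (mstart - base - offset) + 1)
  }
}

#' Assemble an ordered physical map from a tiling path and locus annotations
#'
#' Clone-local locus intervals are lifted through each clone's orientation
#' and offset into contiguous map coordinates (contigs laid end to end,
#' separated by their estimated gap size or by `gap_spacer` when unknown).
#' Duplicate annotations of the same locus in overlap regions are merged
#' when their lifted intervals intersect; non-intersecting duplicates are
#' flagged as conflicts.  Locus symbols are matched case-insensitively,
#' optionally through a synonym table.
#'
#' @param path A `tiling_path` (gaps called or not).
#' @param locus_annotations Tibble: `clone_id`, `name`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), `category`.
#' @param gap_spacer Spacer between contigs when a gap size is unknown (bp).
#' @param synonyms Optional tibble (`name`, `canonical`) for symbol
#'   normalisation.
#' @param source Label recorded in the `source` column.
#' @return Tibble of map entries: `locus_name`, `source`, `map_start`,
#'   `map_end`, `strand`, `rank`, `category`, `contig`, `clones`, `flag`.
#' @export
assemble_map <- function(path, locus_annotations, gap_spacer = 5000,
                         synonyms = NULL, source = "cloneset") {
  ann <- locus_annotations
  if (!nrow(ann)) {
    return(tibble::tibble(locus_name = character(), source = character(),
                          map_start = numeric(), map_end = numeric(),
                          strand = character(), rank = integer(),
                          category = character(), contig = character(),
                          clones = character(), flag = character()))
  }
  contigs <- path$contigs
  placed <- ann$clone_id %in% contigs$clone_id
  if (any(!placed)) {
    warning("annotations on unplaced clones emitted with clone-local coordinates: ",
            paste(unique(ann$clone_id[!placed]), collapse = ", "))
  }
  # contig base coordinates in path order
  ctg_ids <- unique(contigs$contig)
  spans <- vapply(ctg_ids, function(cg) {
    sub <- contigs[contigs$contig == cg, ]
    max(sub$offset + sub$length)
  }, numeric(1))
  gap_for <- function(cg) {
    g <- path$gaps
    if (is.null(g) || !nrow(g)) return(gap_spacer)
    row <- g[g$left_contig == cg, ]
    if (nrow(row) && !is.na(row$size_estimate[1])) row$size_estimate[1] else gap_spacer
  }
  base <- stats::setNames(numeric(length(ctg_ids)), ctg_ids)
  acc <- 0
  for (i in seq_along(ctg_ids)) {
    base[ctg_ids[i]] <- acc
    acc <- acc + spans[i] + gap_for(ctg_ids[i])
  }
  norm <- toupper(ann$name)
  if (!is.null(synonyms)) {
    hit <- match(norm, toupper(synonyms$name))
    norm[!is.na(hit)] <- toupper(synonyms$canonical[hit[!is.na(hit)]])
  }
  lifted <- purrr::map_dfr(seq_len(nrow(ann)), function(i) {
    r <- ann[i, ]
    cl <- contigs[contigs$clone_id == r$clone_id, ]
    if (!nrow(cl)) {
      return(tibble::tibble(locus_name = norm[i], map_start = r$start,
                            map_end = r$end, strand = r$strand,
                            category = r$category, contig = NA_character_,
                            clones = r$clone_id, flag = "unplaced"))
    }
    iv <- unname(lift_interval(base[[cl$contig]], cl$offset, cl$length,
                               cl$orientation, r$start, r$end))
    strand <- if (cl$orientation == "forward") r$strand else
      ifelse(r$strand == "+", "-", "+")
    tibble::tibble(locus_name = norm[i], map_start = iv[1], map_end = iv[2],
                   strand = strand, category = r$category, contig = cl$contig,
                   clones = r$clone_id, flag = "")
  })
  merged <- lifted %>%
    dplyr::group_by(.data$locus_name) %>%
    dplyr::group_modify(function(g, key) {
      if (nrow(g) == 1) return(g)
      # merge rows whose intervals intersect; conflicting duplicates kept
      g <- dplyr::arrange(g, .data$map_start)
      grp <- cumsum(c(1, utils::tail(g$map_start, -1) >
                        cummax(utils::head(g$map_end, -1))))
      g %>%
        dplyr::group_by(grp2 = grp) %>%
        dplyr::summarise(map_start = min(.data$map_start),
                         map_end = max(.data$map_end),
                         strand = .data$strand[1],
                         category = .data$category[1],
                         contig = .data$contig[1],
                         clones = paste(unique(.data$clones), collapse = ","),
                         n = dplyr::n(), .groups = "drop") %>%
        dplyr::mutate(flag = dplyr::case_when(
          dplyr::n() > 1 ~ "conflict",
          .data$n > 1 ~ "merged",
          TRUE ~ "")) %>%
        dplyr::select(-"grp2", -"n")
    }) %>%
    dplyr::ungroup()
  merged %>%
    dplyr::arrange(.data$map_start) %>%
    dplyr::mutate(rank = dplyr::row_number(), source = source) %>%
    dplyr::select("locus_name", "source", "map_start", "map_end", "strand",
                  "rank", "category", "contig", "clones", "flag")
}

#' Compare gene content and order between physical maps
#'
#' Builds a per-locus presence matrix across maps, pairwise order
#' concordance (fraction of shared-locus pairs in the same relative order)
#' and maximal reversed blocks of consecutive shared loci (inverted runs).
#'
#' @param maps Named list of 2-3 map-entry tibbles from [assemble_map()].
#' @return A `map_comparison` list: `presence`, `concordance`,
#'   `inverted_runs`, `discordant`.
#' @export
compare_maps <- function(maps) {
  stopifnot(length(maps) >= 2, length(maps) <= 3, !is.null(names(maps)))
  all_loci <- unique(unlist(lapply(maps, function(m) m$locus_name)))
  presence <- tibble::tibble(locus_name = all_loci)
  for (nm in names(maps)) presence[[nm]] <- all_loci %in% maps[[nm]]$locus_name
  pairs <- utils::combn(names(maps), 2, simplify = FALSE)
  conc <- list(); inv <- list(); discordant <- character(0)
  for (p in pairs) {
    a <- maps[[p[1]]]; b <- maps[[p[2]]]
    shared <- intersect(a$locus_name, b$locus_name)
    if (length(shared) < 2) {
      conc[[length(conc) + 1L]] <- tibble::tibble(
        map_a = p[1], map_b = p[2], n_shared = length(shared),
        concordance = NA_real_)
      next
    }
    ra <- a$rank[match(shared, a$locus_name)]
    rb <- b$rank[match(shared, b$locus_name)]
    ord <- order(ra)
    ra <- ra[ord]; rb <- rb[ord]; shared <- shared[ord]
    cp <- utils::combn(seq_along(shared), 2)
    same <- sign(ra[cp[1, ]] - ra[cp[2, ]]) == sign(rb[cp[1, ]] - rb[cp[2, ]])
    conc[[length(conc) + 1L]] <- tibble::tibble(
      map_a = p[1], map_b = p[2], n_shared = length(shared),
      concordance = mean(same))
    disc_pairs <- cp[, !same, drop = FALSE]
    discordant <- union(discordant, shared[unique(as.vector(disc_pairs))])
    # maximal reversed blocks: consecutive in a with strictly decreasing b-rank
    pos_b <- rank(rb)
    runs <- integer(0); start <- 1L
    for (i in seq_along(shared)[-1]) {
      if (pos_b[i] != pos_b[i - 1L] - 1L) {
        if (i - start >= 2L) {
          inv[[length(inv) + 1L]] <- tibble::tibble(
            map_a = p[1], map_b = p[2],
            block = paste(shared[start:(i - 1L)], collapse = ","),
            length = i - start)
        }
        start <- i
      }
    }
    if (length(shared) - start + 1L >= 2L) {
      inv[[length(inv) + 1L]] <- tibble::tibble(
        map_a = p[1], map_b = p[2],
        block = paste(shared[start:length(shared)], collapse = ","),
        length = length(shared) - start + 1L)
    }
  }
  structure(list(presence = presence,
                 concordance = dplyr::bind_rows(conc),
                 inverted_runs = dplyr::bind_rows(inv),
                 discordant = discordant),
            class = "map_comparison")
}

#' Place short end sequences on target clones
#'
#' Each end sequence is anchor-chained against every target; the best
#' placement is reported per end, or a no-placement row when chain coverage
#' is below half the end length ("no significant similarity").
#'
#' @param ends Sequence tibble of end sequences (<= 2 kb each).
#' @param targets Sequence tibble of target clones.
#' @param params Overlap parameters ([overlap_params()]); `word_length` and
#'   chain thresholds are used.
#' @param min_coverage Minimum chain coverage of the end length.
#' @return Tibble: `end_id`, `target_id`, `start`, `end`, `orientation`,
#'   `coverage`, `placed`.
#' @export
place_end_sequences <- function(ends, targets, params = overlap_params(),
                                min_coverage = 0.5) {
  stopifnot(all(nchar(ends$seq) <= 2000))
  purrr::map_dfr(seq_len(nrow(ends)), function(i) {
    e <- ends[i, ]
    best <- NULL
    for (j in seq_len(nrow(targets))) {
      t <- targets[j, ]
      anc <- anchor_matches(e, t, params$word_length)
      if (!nrow(anc)) next
      for (o in c("forward", "reverse")) {
        sub <- anc[anc$orientation == o, ]
        if (!nrow(sub)) next
        sub <- dplyr::rename(sub, pos_b = "b_start")
        ch <- chain_one_orientation(sub, params$max_gap, params$max_diag_drift)
        cov <- attr(ch, "coverage") / nchar(e$seq)
        if (is.null(best) || cov > best$coverage) {
          bs <- if (o == "forward") min(ch$q) else
            nchar(t$seq) - (max(ch$q + ch$length - 1L)) + 1L
          be <- if (o == "forward") max(ch$q + ch$length - 1L) else
            nchar(t$seq) - min(ch$q) + 1L
          best <- list(target = t$id, start = bs, end = be, orientation = o,
                       coverage = cov)
        }
      }
    }
    if (is.null(best) || best$coverage < min_coverage) {
      tibble::tibble(end_id = e$id, target_id = NA_character_,
                     start = NA_integer_, end = NA_integer_,
                     orientation = NA_character_, coverage = 0, placed = FALSE)
    } else {
      tibble::tibble(end_id = e$id, target_id = best$target,
                     start = best$start, end = best$end,
                     orientation = best$orientation,
                     coverage = best$coverage, placed = TRUE)
    }
  })
}

#' Export a physical map as GFF3, BED or TSV
#'
#' GFF3 keeps the package's 1-based inclusive coordinates; BED export
#' converts to 0-based half-open intervals (`bed_start = gff_start - 1`).
#'
#' @param map Map-entry tibble from [assemble_map()].
#' @param path Output file path.
#' @param format `"gff3"`, `"bed"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_annotations <- function(map, path, format = c("gff3", "bed", "tsv")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("parameter error: unknown format"))
  if (format == "tsv") {
    utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = map$source,
    ranges = IRanges::IRanges(start = map$map_start, end = map$map_end),
    strand = map$strand)
  S4Vectors::mcols(gr)$Name <- map$locus_name
  S4Vectors::mcols(gr)$category <- map$category
  if (format == "gff3") {
    S4Vectors::mcols(gr)$type <- "region"
    S4Vectors::mcols(gr)$ID <- sprintf("%s_%d", map$locus_name, map$rank)
  } else {
    names(gr) <- map$locus_name
  }
  rtracklayer::export(gr, path, format = format)
  invisible(path)
}

#' Read a map exported with [export_annotations()] back into a tibble
#'
#' @param path File path.
#' @param format `"gff3"`, `"bed"` or `"tsv"`.
#' @return Map-entry tibble (columns as written; `rank` recomputed).
#' @export
import_annotations <- function(path, format = c("gff3", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    return(tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE)))
  }
  gr <- rtracklayer::import(path, format = format)
  nm <- S4Vectors::mcols(gr)$Name %||% names(gr)
  cat_col <- S4Vectors::mcols(gr)$category
  tibble::tibble(
    locus_name = as.character(nm),
    source = as.character(GenomicRanges::seqnames(gr)),
    map_start = GenomicRanges::start(gr),
    map_end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    category = if (is.null(cat_col)) NA_character_ else as.character(cat_col)) %>%
    dplyr::arrange(.data$map_start) %>%
    dplyr::mutate(rank = dplyr::row_number())
}
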