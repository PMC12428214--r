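# Partition of a pre-miRNA hairpin into segments and classification of
# aligned reads into the five segmental groups: mature, loop (the
# within-precursor non-mature regions), border-crossing overlap, genomic
# extension beyond the hairpin, and antisense complement.

SEGMENT_CLASSES <- c("mature", "loop", "overlap", "extension", "complement",
                     "unassigned")

#' Build the segment map of a miRNA locus
#'
#' Tiles the hairpin, in transcription order, into leader (hairpin start to
#' the 5p arm), mature 5p, loop (between the arms), mature 3p and trailer
#' (3p arm to hairpin end), plus two flanking extension margins of
#' `margin_nt` outside the hairpin. Zero-length segments are kept (a
#' single-arm locus gets an empty slot on the missing side). Margins are
#' clipped at contig bounds when `contig_length` is given.
#'
#' @param locus a [mirna_locus()]
#' @param margin_nt width of each flanking margin (default 25)
#' @param contig_length optional contig length for clipping margins
#' @return object of class `segment_map`: locus fields plus a named list of
#'   half-open intervals `leader`, `mature5p`, `loop`, `mature3p`, `trailer`,
#'   `margin_left`, `margin_right` (genomic coordinates)
#' @export
build_segment_map <- function(locus, margin_nt = 25L, contig_length = NULL) {
  if (length(locus$arms) < 1L)
    stop("locus ", locus$mirna_id, " has no mature arm")
  hp <- locus$hairpin
  a5 <- locus$arms[["5p"]]
  a3 <- locus$arms[["3p"]]
  # genomic-order tiling; on the minus strand 5p is the right-hand arm
  if (locus$strand == "+") {
    lo_arm <- if (!is.null(a5)) a5 else c(hp[1L], hp[1L])
    hi_arm <- if (!is.null(a3)) a3 else c(hp[2L], hp[2L])
    seg <- list(leader   = c(hp[1L], lo_arm[1L]),
                mature5p = lo_arm,
                loop     = c(lo_arm[2L], hi_arm[1L]),
                mature3p = hi_arm,
                trailer  = c(hi_arm[2L], hp[2L]))
  } else {
    lo_arm <- if (!is.null(a3)) a3 else c(hp[1L], hp[1L])
    hi_arm <- if (!is.null(a5)) a5 else c(hp[2L], hp[2L])
    seg <- list(trailer  = c(hp[1L], lo_arm[1L]),
                mature3p = lo_arm,
                loop     = c(lo_arm[2L], hi_arm[1L]),
                mature5p = hi_arm,
                leader   = c(hi_arm[2L], hp[2L]))
  }
  m_lo <- c(max(0L, hp[1L] - as.integer(margin_nt)), hp[1L])
  m_hi_end <- hp[2L] + as.integer(margin_nt)
  if (!is.null(contig_length)) m_hi_end <- min(m_hi_end, contig_length)
  seg$margin_left <- m_lo
  seg$margin_right <- c(hp[2L], m_hi_end)
  structure(list(mirna_id = locus$mirna_id, contig_id = locus$contig_id,
                 strand = locus$strand, hairpin = hp, segments = seg,
                 family = locus$family),
            class = "segment_map")
}

# internal hairpin borders: boundaries between adjacent non-empty tiling
# segments, excluding the hairpin ends themselves
internal_borders <- function(map) {
  hp <- map$hairpin
  tiling <- map$segments[c("leader", "mature5p", "loop", "mature3p", "trailer")]
  if (map$strand == "-")
    tiling <- map$segments[c("trailer", "mature3p", "loop", "mature5p", "leader")]
  b <- unique(unlist(lapply(tiling, function(iv) iv)))
  b <- sort(b)
  b[b > hp[1L] & b < hp[2L]]
}

#' Classify one read against a segment map
#'
#' Decision order: (1) a read antisense to the locus strand is a
#' `complement`; (2) a read crossing a hairpin end with at least
#' `border_overhang` nt outside is an `extension`; (3) a read crossing an
#' internal segment border with at least `border_overhang` nt on both sides
#' is an `overlap`; (4) a read contained in a mature arm, allowing strictly
#' less than `border_overhang` nt of slop beyond the arm, is `mature`;
#' (5) a read contained in the loop, leader or trailer is `loop`;
#' (6) anything else is `unassigned`. A read that does not touch the hairpin
#' +/- margin window is an error: callers pre-filter by overlap.
#'
#' @param start,end half-open read interval (genomic)
#' @param strand read strand
#' @param map a `segment_map`
#' @param border_overhang nt past a border that count as "crossing" (default 3)
#' @return one of `"mature"`, `"loop"`, `"overlap"`, `"extension"`,
#'   `"complement"`, `"unassigned"`
#' @export
classify_read <- function(start, end, strand, map, border_overhang = 3L) {
  hp <- map$hairpin
  window <- c(map$segments$margin_left[1L], map$segments$margin_right[2L])
  if (!intervals_overlap(c(start, end), window))
    stop("read does not overlap the locus window; pre-filter by overlap")
  if (strand != map$strand) return("complement")
  oh <- as.integer(border_overhang)
  # (2) extension: crosses a hairpin end with >= oh nt outside
  if (start < hp[1L] && end > hp[1L] && hp[1L] - start >= oh)
    return("extension")
  if (end > hp[2L] && start < hp[2L] && end - hp[2L] >= oh)
    return("extension")
  # (3) overlap: crosses an internal border with >= oh nt on both sides
  for (b in internal_borders(map)) {
    if (start <= b - oh && end >= b + oh) return("overlap")
  }
  # (4) mature with < oh slop
  for (arm in map$segments[c("mature5p", "mature3p")]) {
    if (interval_width(arm) == 0L) next
    if (start >= arm[1L] - (oh - 1L) && end <= arm[2L] + (oh - 1L))
      return("mature")
  }
  # (5) loop / leader / trailer containment
  for (seg in map$segments[c("loop", "leader", "trailer")]) {
    if (interval_width(seg) == 0L) next
    if (start >= seg[1L] && end <= seg[2L]) return("loop")
  }
  "unassigned"
}

#' Segmental profile of a read set over miRNA loci
#'
#' Assigns each read to every locus whose hairpin +/- margin it overlaps,
#' classifies it, and tallies counts by (miRNA, class). "References" are
#' (miRNA, class) pairs with a nonzero count over the five named groups;
#' "unique items" are the distinct miRNAs among them.
#'
#' @param reads alignment data.frame ([read_alignments()])
#' @param loci named list of [mirna_locus()]
#' @param margin_nt,border_overhang see [build_segment_map()],
#'   [classify_read()]
#' @param contig_lengths optional named integer vector for margin clipping
#' @return object of class `segmental_profile`: `assignments` (read_id,
#'   mirna_id, class), `counts` (miRNA x class matrix), `class_totals`,
#'   `class_fractions`, `n_references`, `n_unique_items`, `class_sets`
#'   (per-class miRNA id sets for Venn analysis)
#' @export
profile_segments <- function(reads, loci, margin_nt = 25L,
                             border_overhang = 3L, contig_lengths = NULL) {
  maps <- lapply(loci, function(l)
    build_segment_map(l, margin_nt,
                      contig_length = contig_lengths[[l$contig_id]]))
  rows <- list()
  for (m in maps) {
    window <- c(m$segments$margin_left[1L], m$segments$margin_right[2L])
    sel <- reads$contig_id == m$contig_id &
           reads$start < window[2L] & reads$end > window[1L]
    if (!any(sel)) next
    sub <- reads[sel, , drop = FALSE]
    cls <- vapply(seq_len(nrow(sub)), function(i)
      classify_read(sub$start[i], sub$end[i], sub$strand[i], m,
                    border_overhang), character(1))
    rows[[m$mirna_id]] <- data.frame(read_id = sub$read_id,
                                     mirna_id = m$mirna_id, class = cls,
                                     stringsAsFactors = FALSE)
  }
  assignments <- if (length(rows)) do.call(rbind, rows)
                 else data.frame(read_id = character(), mirna_id = character(),
                                 class = character(), stringsAsFactors = FALSE)
  assignments <- assignments[order(assignments$mirna_id,
                                   assignments$read_id), , drop = FALSE]
  rownames(assignments) <- NULL
  counts <- matrix(0L, nrow = length(loci), ncol = length(SEGMENT_CLASSES),
                   dimnames = list(names(loci), SEGMENT_CLASSES))
  if (nrow(assignments)) {
    tab <- table(factor(assignments$mirna_id, levels = names(loci)),
                 factor(assignments$class, levels = SEGMENT_CLASSES))
    counts[] <- as.integer(tab)
  }
  group_cols <- setdiff(SEGMENT_CLASSES, "unassigned")
  class_totals <- colSums(counts)
  grp_tot <- class_totals[group_cols]
  class_fractions <- if (sum(grp_tot) > 0) grp_tot / sum(grp_tot)
                     else grp_tot
  nz <- counts[, group_cols, drop = FALSE] > 0L
  class_sets <- lapply(group_cols, function(g) rownames(counts)[nz[, g]])
  names(class_sets) <- group_cols
  structure(list(assignments = assignments, counts = counts,
                 class_totals = class_totals,
                 class_fractions = class_fractions,
                 n_references = sum(nz),
                 n_unique_items = sum(rowSums(nz) > 0L),
                 class_sets = class_sets),
            class = "segmental_profile")
}

#' @export
print.segmental_profile <- function(x, ...) {
  cat(sprintf("<segmental_profile> %d reads classified, %d references, %d unique items\n",
              nrow(x$assignments), x$n_references, x$n_unique_items))
  print(round(x$class_fractions, 3))
  invisible(x)
}

#' Venn partition of k named sets
#'
#' Enumerates all 2^k membership sections and counts the ids falling in each.
#' Every id in the union lands in exactly one section; the all-absent section
#' counts ids of `universe` outside the union (zero when no universe given).
#'
#' @param sets named list of 2 to 6 character vectors
#' @param universe optional id universe for the outside-union section
#' @return data.frame with one row per section: one logical column per set,
#'   `section` (label like `"A&B"`, `"(none)"`), `count`
#' @export
venn_partition <- function(sets, universe = NULL) {
  k <- length(sets)
  if (k < 2L || k > 6L) stop("venn_partition requires 2 to 6 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  sets <- lapply(sets, unique)
  ids <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1L) member <- matrix(member, nrow = 1L,
                                          dimnames = list(NULL, names(sets)))
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  names(grid) <- names(sets)
  section_of <- function(row) {
    inset <- names(sets)[as.logical(row)]
    if (length(inset) == 0L) "(none)" else paste(inset, collapse = "&")
  }
  counts <- integer(nrow(grid))
  if (length(ids)) {
    key_id <- apply(member, 1L, function(r) paste(as.integer(r), collapse = ""))
    key_grid <- apply(grid, 1L, function(r) paste(as.integer(r), collapse = ""))
    tab <- table(key_id)
    counts <- as.integer(tab[key_grid])
    counts[is.na(counts)] <- 0L
  }
  none_row <- rowSums(grid) == 0L
  counts[none_row] <- if (is.null(universe)) 0L
                      else length(setdiff(unique(universe), ids))
  out <- cbind(grid,
               data.frame(section = apply(grid, 1L, section_of),
                          count = counts, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
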