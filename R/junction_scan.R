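# Antisense splice-junction complementarity scan: find miRNA loci lying
# antisense to spliced transcripts and score Watson-Crick pairing of the
# mature arm against a window centred on the splice junction (by default the
# last 6 exonic and first 16 intronic nucleotides, a 22-nt duplex).

#' Extract a junction-centred sequence window
#'
#' The window covers positions -upstream..-1 (exonic) and +1..+downstream
#' (intronic) relative to the junction in transcription order; there is no
#' position 0. The sequence is returned on the transcript strand, 5'->3'.
#'
#' @param junction one row of [derive_junctions()] output
#' @param genome named `DNAStringSet`
#' @param upstream exonic nt upstream of the junction (default 6)
#' @param downstream intronic nt downstream (default 16)
#' @return list with `start`, `end` (genomic half-open interval), `strand`,
#'   `sequence` (length upstream + downstream), `intron_index`
#' @export
junction_window <- function(junction, genome, upstream = 6L,
                            downstream = 16L) {
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  stopifnot(upstream >= 0L, downstream >= 0L, upstream + downstream > 0L)
  d <- junction$donor_pos
  if (junction$strand == "+") {
    start <- d - upstream
    end <- d + downstream
  } else {
    # transcription runs towards lower coordinates: exonic side is above d
    start <- d - downstream + 1L
    end <- d + upstream + 1L
  }
  len <- length(genome[[junction$contig_id]])
  if (start < 0L || end > len)
    stop(sprintf("junction window [%d,%d) falls outside contig '%s'",
                 start, end, junction$contig_id))
  list(contig_id = junction$contig_id, start = start, end = end,
       strand = junction$strand,
       sequence = genome_slice(genome, junction$contig_id, start, end,
                               junction$strand),
       intron_index = junction$intron_index,
       transcript_id = junction$transcript_id)
}

PAIRS_WC <- c(A = "T", C = "G", G = "C", T = "A")

#' Score antiparallel Watson-Crick complementarity of a miRNA to a window
#'
#' The miRNA (5'->3') is aligned ungapped and antiparallel against the window
#' (3'->5'): position i of the miRNA faces position L-i+1 of the window.
#' `n_paired` counts A:T(U) and G:C pairs, plus G:T(U) wobble pairs when
#' `allow_gu` is set. When lengths differ, scoring runs over the shorter
#' length and `length_mismatch` is flagged; `full_complement` requires equal
#' lengths and every position paired.
#'
#' @param mirna_seq miRNA sequence 5'->3' (DNA or RNA alphabet)
#' @param window_seq window sequence 5'->3'
#' @param allow_gu allow G:U wobble pairs (default FALSE)
#' @return list with `n_paired`, `n_total`, `longest_paired_run`,
#'   `full_complement`, `length_mismatch`, `wobble_allowed`
#' @export
duplex_complementarity <- function(mirna_seq, window_seq, allow_gu = FALSE) {
  m <- strsplit(toupper(chartr("Uu", "Tt", mirna_seq)), "")[[1L]]
  w <- strsplit(toupper(chartr("Uu", "Tt", window_seq)), "")[[1L]]
  if (length(m) == 0L || length(w) == 0L) stop("empty sequence")
  n <- min(length(m), length(w))
  wr <- rev(w)[seq_len(n)]          # window read 3'->5'
  mm <- m[seq_len(n)]
  paired <- PAIRS_WC[mm] == wr
  if (allow_gu)
    paired <- paired | (mm == "G" & wr == "T") | (mm == "T" & wr == "G")
  paired[is.na(paired)] <- FALSE    # N never pairs
  runs <- rle(paired)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  list(n_paired = sum(paired), n_total = n,
       longest_paired_run = as.integer(longest),
       full_complement = length(m) == length(w) && all(paired),
       length_mismatch = length(m) != length(w),
       wobble_allowed = isTRUE(allow_gu))
}

# mature arm sequence on the locus strand, 5'->3'
mature_arm_seq <- function(locus, arm, genome) {
  iv <- locus$arms[[arm]]
  genome_slice(genome, locus$contig_id, iv[1L], iv[2L], locus$strand)
}

#' Scan miRNA loci against antisense transcripts for junction complementarity
#'
#' For every (miRNA locus, transcript) pair on opposite strands with genomic
#' overlap, and every junction of the transcript whose window overlaps the
#' miRNA hairpin, each mature arm is scored against the junction window.
#' With `exon_mode` the scan additionally reports miRNA loci overlapping an
#' exon of an antisense transcript (no duplex score), covering cluster
#' neighbours complementary to exonic sequence rather than to a junction.
#'
#' @param loci named list of [mirna_locus()]
#' @param transcripts named list of [transcript_model()]
#' @param genome named `DNAStringSet`
#' @param upstream,downstream window geometry (defaults 6 and 16)
#' @param allow_gu allow G:U wobble pairs
#' @param exon_mode also report exon-overlap (non-junction) antisense hits
#' @return data.frame sorted by `n_paired` descending then ids: mirna_id,
#'   arm, transcript_id, hit_type ("junction"/"exon"), intron_index or exon
#'   index, window_start, window_end, n_paired, n_total, longest_paired_run,
#'   full_complement
#' @export
scan_junctions <- function(loci, transcripts, genome, upstream = 6L,
                           downstream = 16L, allow_gu = FALSE,
                           exon_mode = FALSE) {
  rows <- list()
  for (tx in transcripts) {
    jn <- derive_junctions(tx)
    tx_span <- c(min(tx$exons[, "start"]), max(tx$exons[, "end"]))
    for (locus in loci) {
      if (locus$contig_id != tx$contig_id) next
      if (locus$strand == tx$strand) next
      if (!intervals_overlap(locus$hairpin, tx_span)) next
      for (j in seq_len(nrow(jn))) {
        win <- junction_window(jn[j, ], genome, upstream, downstream)
        if (!intervals_overlap(locus$hairpin, c(win$start, win$end))) next
        for (arm in names(locus$arms)) {
          mseq <- mature_arm_seq(locus, arm, genome)
          dup <- duplex_complementarity(mseq, win$sequence, allow_gu)
          rows[[length(rows) + 1L]] <- data.frame(
            mirna_id = locus$mirna_id, arm = arm,
            transcript_id = tx$transcript_id, hit_type = "junction",
            contig_id = locus$contig_id, index = win$intron_index,
            window_start = win$start, window_end = win$end,
            n_paired = dup$n_paired, n_total = dup$n_total,
            longest_paired_run = dup$longest_paired_run,
            full_complement = dup$full_complement,
            stringsAsFactors = FALSE)
        }
      }
      if (exon_mode) {
        for (e in seq_len(nrow(tx$exons))) {
          ex <- tx$exons[e, ]
          if (!intervals_overlap(locus$hairpin, ex)) next
          rows[[length(rows) + 1L]] <- data.frame(
            mirna_id = locus$mirna_id, arm = NA_character_,
            transcript_id = tx$transcript_id, hit_type = "exon",
            contig_id = locus$contig_id,
            index = if (tx$strand == "+") e else nrow(tx$exons) - e + 1L,
            window_start = ex[1L], window_end = ex[2L],
            n_paired = NA_integer_, n_total = NA_integer_,
            longest_paired_run = NA_integer_, full_complement = FALSE,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(mirna_id = character(), arm = character(),
                         transcript_id = character(), hit_type = character(),
                         contig_id = character(),
                         index = integer(), window_start = integer(),
                         window_end = integer(), n_paired = integer(),
                         n_total = integer(), longest_paired_run = integer(),
                         full_complement = logical(),
                         stringsAsFactors = FALSE)
  ord <- order(-ifelse(is.na(out$n_paired), -1L, out$n_paired),
               out$mirna_id, out$transcript_id, out$index)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a junction-scan report as TSV plus a BED track of hit windows
#' @param hits [scan_junctions()] output
#' @param tsv_path report path
#' @param bed_path optional BED6 path for junction-hit windows
#' @export
write_scan_report <- function(hits, tsv_path, bed_path = NULL) {
  utils::write.table(hits, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bed_path)) {
    jh <- hits[hits$hit_type == "junction", , drop = FALSE]
    writeLines(sprintf("%s\t%d\t%d\t%s|%s\t%d\t.",
                       jh$contig_id, jh$window_start,
                       jh$window_end, jh$mirna_id, jh$transcript_id,
                       jh$n_paired),
               bed_path)
  }
  invisible(tsv_path)
}
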