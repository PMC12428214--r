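# Readers and writers for the formats the pipeline consumes: FASTA genomes,
# GFF3 transcript models and miRNA loci (miRBase dialect), BED6/SAM read
# alignments, TSV count matrices and trend tables. Coordinate-convention
# conversion happens here and only here.

#' Read a genome FASTA into a DNAStringSet
#'
#' Sequences are uppercased; any character outside A/C/G/T/N is replaced by N
#' with a warning. Duplicate contig ids and empty files are hard errors.
#'
#' @param path FASTA file
#' @return named `DNAStringSet`
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate contig id in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  chr <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", chr)
  if (any(bad)) {
    warning(sum(bad), " contig(s) contained non-ACGTN characters; mapped to N")
    chr[bad] <- gsub("[^ACGTN]", "N", chr[bad])
  }
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- names(seqs)
  out
}

#' Write a genome FASTA
#' @param genome named `DNAStringSet`
#' @param path output file
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, format = "fasta")
  invisible(path)
}

#' Construct a transcript model
#'
#' @param transcript_id,gene_id,contig_id identifiers
#' @param strand `"+"` or `"-"`
#' @param exons two-column matrix of 0-based half-open exon intervals in
#'   genomic order (sorted by start, non-overlapping)
#' @param biotype e.g. `"protein_coding"`, `"lncRNA"`
#' @return object of class `transcript_model`
#' @export
transcript_model <- function(transcript_id, gene_id, contig_id, strand, exons,
                             biotype = "protein_coding") {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stop("transcript must have >= 1 exon")
  if (any(exons[, "end"] <= exons[, "start"]))
    stop("exon with end <= start in ", transcript_id)
  exons <- exons[order(exons[, "start"]), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons[-1L, "start"] < exons[-nrow(exons), "end"]))
    stop("overlapping exons in transcript ", transcript_id)
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 contig_id = contig_id, strand = strand,
                 exons = exons, biotype = biotype),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s %d exon(s) [%s]\n",
              x$transcript_id, x$gene_id, x$contig_id, x$strand,
              nrow(x$exons),
              paste(sprintf("%d-%d", x$exons[, 1], x$exons[, 2]),
                    collapse = ", ")))
  invisible(x)
}

#' Read transcript models from GFF3
#'
#' Expects gene/transcript/exon features with `Parent` attributes linking
#' exons to transcripts. GFF3 1-based inclusive coordinates are converted to
#' 0-based half-open.
#'
#' @param path GFF3 file
#' @return named list of `transcript_model`
#' @export
read_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  is_tx <- typ %in% c("transcript", "mRNA", "lnc_RNA", "lncRNA")
  is_exon <- typ == "exon"
  if (!any(is_tx)) stop("no transcript features in ", path)
  tx <- gr[is_tx]
  tx_id <- as.character(tx$ID)
  tx_gene <- vapply(as.list(tx$Parent), function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))
  tx_bio <- if (!is.null(tx$biotype)) as.character(tx$biotype)
            else rep(NA_character_, length(tx))
  ex <- gr[is_exon]
  ex_parent <- as.list(ex$Parent)
  if (any(lengths(ex_parent) == 0L))
    stop("exon without parent transcript in ", path)
  ex_parent <- vapply(ex_parent, function(p) as.character(p[[1L]]), character(1))
  if (!all(ex_parent %in% tx_id))
    stop("exon parent not a transcript feature: ",
         paste(setdiff(unique(ex_parent), tx_id), collapse = ", "))
  out <- lapply(seq_along(tx), function(i) {
    sel <- ex_parent == tx_id[i]
    if (!any(sel)) stop("transcript without exons: ", tx_id[i])
    e <- ex[sel]
    exons <- gff_to_halfopen(BiocGenerics::start(e), BiocGenerics::end(e))
    transcript_model(tx_id[i],
                     if (is.na(tx_gene[i])) tx_id[i] else tx_gene[i],
                     as.character(GenomicRanges::seqnames(tx[i])),
                     as.character(BiocGenerics::strand(tx[i])),
                     exons,
                     biotype = if (is.na(tx_bio[i])) "unknown" else tx_bio[i])
  })
  names(out) <- tx_id
  out
}

#' Write transcript models to GFF3
#' @param transcripts named list of `transcript_model`
#' @param path output file
#' @export
write_transcripts <- function(transcripts, path) {
  transcripts <- transcripts[order(names(transcripts))]
  lines <- c("##gff-version 3")
  for (t in transcripts) {
    g <- halfopen_to_gff(t$exons[, "start"], t$exons[, "end"])
    lines <- c(lines,
      sprintf("%s\tspliceomir\ttranscript\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;biotype=%s",
              t$contig_id, min(g[, "start"]), max(g[, "end"]), t$strand,
              t$transcript_id, t$gene_id, t$biotype),
      sprintf("%s\tspliceomir\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
              t$contig_id, g[, "start"], g[, "end"], t$strand,
              t$transcript_id, seq_len(nrow(g)), t$transcript_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Derive splice junctions from a transcript model
#'
#' A transcript with n exons yields n-1 introns. For each intron the
#' five-prime (donor) position is the first intronic base in transcription
#' order and the three-prime (acceptor) position the last; on the minus
#' strand the donor therefore sits at the higher genomic coordinate.
#'
#' @param transcript a `transcript_model`
#' @return data.frame with columns transcript_id, contig_id, strand,
#'   intron_index, donor_pos, acceptor_pos (0-based positions). Zero rows for
#'   a single-exon transcript.
#' @export
derive_junctions <- function(transcript) {
  ex <- transcript$exons
  n <- nrow(ex)
  empty <- data.frame(transcript_id = character(), contig_id = character(),
                      strand = character(), intron_index = integer(),
                      donor_pos = integer(), acceptor_pos = integer(),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  # introns in genomic order: [end of exon i, start of exon i+1)
  g_lo <- ex[-n, "end"]
  g_hi <- ex[-1L, "start"]
  if (transcript$strand == "+") {
    donor <- g_lo
    acceptor <- g_hi - 1L
    idx <- seq_len(n - 1L)
  } else {
    donor <- g_hi - 1L
    acceptor <- g_lo
    idx <- rev(seq_len(n - 1L))   # intron 1 is the most downstream-genomic gap
  }
  out <- data.frame(transcript_id = transcript$transcript_id,
                    contig_id = transcript$contig_id,
                    strand = transcript$strand,
                    intron_index = idx,
                    donor_pos = as.integer(donor),
                    acceptor_pos = as.integer(acceptor),
                    stringsAsFactors = FALSE)
  out[order(out$intron_index), , drop = FALSE]
}

#' miRNA family from a miRBase-style identifier
#'
#' Strips the species prefix, arm suffix (-5p/-3p), locus-copy suffixes and
#' trailing letter variants, keeping the numeric stem: `hsa-let-7a-1` and
#' `hsa-let-7c` both give `let-7`; `hsa-mir-125a` gives `mir-125`.
#'
#' @param mirna_id character vector of ids
#' @return character vector of family names
#' @export
mirna_family <- function(mirna_id) {
  x <- sub("^[A-Za-z]{3,4}-", "", mirna_id)     # species prefix
  x <- sub("-(5p|3p)$", "", x)
  m <- regmatches(x, regexec("^([A-Za-z]+)-([0-9]+)", x))
  vapply(seq_along(x), function(i) {
    if (length(m[[i]]) == 3L)
      paste0(tolower(m[[i]][2L]), "-", m[[i]][3L])
    else tolower(x[i])
  }, character(1))
}

#' Construct a miRNA locus
#'
#' @param mirna_id identifier, e.g. `"hsa-mir-99b"`
#' @param contig_id,strand location
#' @param hairpin length-2 integer, 0-based half-open hairpin interval
#' @param arms named list with optional elements `"5p"` and `"3p"`, each a
#'   length-2 half-open interval contained in the hairpin; the 5p arm must be
#'   upstream of the 3p arm in transcription order
#' @return object of class `mirna_locus`
#' @export
mirna_locus <- function(mirna_id, contig_id, strand, hairpin, arms = list()) {
  stopifnot(strand %in% c("+", "-"), length(hairpin) == 2L)
  hairpin <- as.integer(hairpin)
  if (hairpin[2L] <= hairpin[1L]) stop("empty hairpin for ", mirna_id)
  if (!all(names(arms) %in% c("5p", "3p")))
    stop("arm names must be '5p'/'3p'")
  arms <- lapply(arms, as.integer)
  for (nm in names(arms)) {
    a <- arms[[nm]]
    if (!interval_within(a, hairpin))
      stop(sprintf("%s arm [%d,%d) extends outside hairpin [%d,%d) of %s",
                   nm, a[1L], a[2L], hairpin[1L], hairpin[2L], mirna_id))
  }
  if (all(c("5p", "3p") %in% names(arms))) {
    a5 <- arms[["5p"]]; a3 <- arms[["3p"]]
    if (intervals_overlap(a5, a3)) stop("overlapping arms in ", mirna_id)
    upstream_ok <- if (strand == "+") a5[2L] <= a3[1L] else a3[2L] <= a5[1L]
    if (!upstream_ok)
      stop("5p arm must be upstream of 3p arm in transcription order: ",
           mirna_id)
  }
  structure(list(mirna_id = mirna_id, contig_id = contig_id, strand = strand,
                 hairpin = hairpin, arms = arms,
                 family = mirna_family(mirna_id)),
            class = "mirna_locus")
}

#' @export
print.mirna_locus <- function(x, ...) {
  cat(sprintf("<mirna_locus> %s %s:%d-%d(%s) arms: %s; family %s\n",
              x$mirna_id, x$contig_id, x$hairpin[1L], x$hairpin[2L], x$strand,
              if (length(x$arms))
                paste(sprintf("%s[%d,%d)", names(x$arms),
                              vapply(x$arms, `[`, integer(1), 1L),
                              vapply(x$arms, `[`, integer(1), 2L)),
                      collapse = " ")
              else "none",
              x$family))
  invisible(x)
}

#' Read miRNA loci from a miRBase-dialect GFF3
#'
#' Expects `miRNA_primary_transcript` hairpin features and `miRNA` mature
#' features whose `Derives_from` attribute names their hairpin. A mature arm
#' not contained in its hairpin is an error.
#'
#' @param path GFF3 file
#' @return named list of `mirna_locus`
#' @export
read_mirna_loci <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  hp <- gr[typ == "miRNA_primary_transcript"]
  mat <- gr[typ == "miRNA"]
  if (length(hp) == 0L) stop("no miRNA_primary_transcript features in ", path)
  hp_id <- as.character(hp$ID)
  hp_name <- if (!is.null(hp$Name)) as.character(hp$Name) else hp_id
  der <- if (!is.null(mat$Derives_from)) as.character(mat$Derives_from)
         else stop("miRNA features lack Derives_from in ", path)
  out <- lapply(seq_along(hp), function(i) {
    strand_i <- as.character(BiocGenerics::strand(hp[i]))
    hairpin <- as.integer(gff_to_halfopen(BiocGenerics::start(hp[i]),
                                          BiocGenerics::end(hp[i])))
    sel <- der == hp_id[i]
    arms <- list()
    if (any(sel)) {
      m <- mat[sel]
      m_name <- if (!is.null(m$Name)) as.character(m$Name)
                else as.character(m$ID)
      ivs <- gff_to_halfopen(BiocGenerics::start(m), BiocGenerics::end(m))
      arm_key <- ifelse(grepl("-5p$", m_name), "5p",
                 ifelse(grepl("-3p$", m_name), "3p", NA))
      if (anyNA(arm_key)) {
        # no explicit arm suffix: assign by transcription order
        ord <- order(ivs[, "start"])
        if (strand_i == "-") ord <- rev(ord)
        arm_key[ord] <- c("5p", "3p")[seq_along(ord)]
      }
      for (k in seq_len(nrow(ivs))) arms[[arm_key[k]]] <- ivs[k, ]
    }
    mirna_locus(hp_name[i],
                as.character(GenomicRanges::seqnames(hp[i])),
                strand_i, hairpin, arms)
  })
  names(out) <- hp_name
  out[order(names(out))]
}

#' Write miRNA loci to a miRBase-dialect GFF3
#' @param loci named list of `mirna_locus`
#' @param path output file
#' @export
write_mirna_loci <- function(loci, path) {
  loci <- loci[order(vapply(loci, `[[`, character(1), "mirna_id"))]
  lines <- "##gff-version 3"
  for (l in loci) {
    g <- halfopen_to_gff(l$hairpin[1L], l$hairpin[2L])
    lines <- c(lines, sprintf(
      "%s\tspliceomir\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      l$contig_id, g[1L], g[2L], l$strand, l$mirna_id, l$mirna_id))
    for (nm in names(l$arms)) {
      a <- halfopen_to_gff(l$arms[[nm]][1L], l$arms[[nm]][2L])
      lines <- c(lines, sprintf(
        "%s\tspliceomir\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s-%s;Name=%s-%s;Derives_from=%s",
        l$contig_id, a[1L], a[2L], l$strand,
        l$mirna_id, nm, l$mirna_id, nm, l$mirna_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read small-RNA read alignments from BED6 or SAM
#'
#' Alignments are consumed as gapless intervals. SAM records whose CIGAR is
#' anything other than a single match run (indels, splices, clipping) are
#' rejected; the rejection count is attached as attribute `n_rejected`.
#'
#' @param path alignment file
#' @param dialect `"bed"` (0-based half-open) or `"sam"` (1-based)
#' @return data.frame with read_id, contig_id, strand, start, end, length
#'   (0-based half-open), attribute `n_rejected`
#' @export
read_alignments <- function(path, dialect = c("bed", "sam")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    out <- data.frame(
      read_id = if (!is.null(gr$name)) as.character(gr$name)
                else paste0("read", seq_along(gr)),
      contig_id = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(BiocGenerics::strand(gr)),
      start = BiocGenerics::start(gr) - 1L,
      end = BiocGenerics::end(gr),
      stringsAsFactors = FALSE)
    attr(out, "n_rejected") <- 0L
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
    n_rejected <- 0L
    rows <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
      if (length(f) < 6L) stop("malformed SAM line ", i, " in ", path)
      flag <- as.integer(f[2L])
      cigar <- f[6L]
      if (bitwAnd(flag, 4L) > 0L) next                      # unmapped
      if (!grepl("^[0-9]+M$", cigar)) {                      # gapless only
        n_rejected <- n_rejected + 1L
        next
      }
      pos0 <- as.integer(f[4L]) - 1L
      len <- as.integer(sub("M$", "", cigar))
      rows[[i]] <- data.frame(
        read_id = f[1L], contig_id = f[3L],
        strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+",
        start = pos0, end = pos0 + len, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(out))
      out <- data.frame(read_id = character(), contig_id = character(),
                        strand = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
    attr(out, "n_rejected") <- n_rejected
  }
  if (nrow(out) && any(out$end <= out$start))
    stop("alignment with non-positive length in ", path)
  out$length <- out$end - out$start
  out
}

#' Write read alignments as BED6
#' @param reads alignment data.frame (see [read_alignments()])
#' @param path output file
#' @export
write_alignments <- function(reads, path) {
  reads <- reads[order(reads$contig_id, reads$start, reads$read_id), ,
                 drop = FALSE]
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     reads$contig_id, reads$start, reads$end,
                     reads$read_id, reads$strand),
             path)
  invisible(path)
}

#' Read a miRNA x sample count table (TSV, first column mirna_id)
#' @param path TSV file
#' @return numeric matrix, rows miRNAs, columns samples
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("negative counts in ", path)
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("duplicate row/column labels in ", path)
  m
}

#' Write a count matrix as TSV (rows sorted lexicographically)
#' @param counts numeric matrix with miRNA rownames and sample colnames
#' @param path output file
#' @export
write_counts <- function(counts, path) {
  counts <- counts[order(rownames(counts)), , drop = FALSE]
  df <- data.frame(mirna_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trend-report table (mirna_id, disease, n_up, n_down)
#' @param path TSV file
#' @return data.frame
#' @export
read_trend_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "disease", "n_up", "n_down")
  if (!all(need %in% names(df)))
    stop("trend table must have columns ", paste(need, collapse = ", "))
  if (any(df$n_up + df$n_down < 1L))
    stop("trend record with no reports")
  df
}

#' Write a trend-report table
#' @param trends data.frame with mirna_id, disease, n_up, n_down
#' @param path output file
#' @export
write_trend_table <- function(trends, path) {
  trends <- trends[order(trends$mirna_id, trends$disease), , drop = FALSE]
  utils::write.table(trends, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
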