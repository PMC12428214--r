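#' @keywords internal
"_PACKAGE"

# All internal coordinates are 0-based half-open [start, end).
# GFF3 (1-based inclusive), SAM (1-based) and BED (0-based half-open) are
# converted at the I/O boundary and nowhere else.

#' Convert 1-based inclusive coordinates to 0-based half-open
#' @param start,end 1-based inclusive coordinates (GFF3/SAM convention)
#' @return two-column integer matrix with half-open columns `start`, `end`
#' @keywords internal
gff_to_halfopen <- function(start, end) {
  cbind(start = as.integer(start) - 1L, end = as.integer(end))
}

#' Convert 0-based half-open coordinates to 1-based inclusive
#' @keywords internal
halfopen_to_gff <- function(start, end) {
  cbind(start = as.integer(start) + 1L, end = as.integer(end))
}

#' Length of a half-open interval
#' @keywords internal
interval_width <- function(iv) iv[2L] - iv[1L]

#' Do two half-open intervals overlap?
#' @keywords internal
intervals_overlap <- function(a, b) a[1L] < b[2L] && b[1L] < a[2L]

#' Is interval `a` contained in interval `b`?
#' @keywords internal
interval_within <- function(a, b) a[1L] >= b[1L] && a[2L] <= b[2L]

#' Extract a genomic slice as a character string
#'
#' @param genome a named `DNAStringSet`
#' @param contig_id contig name
#' @param start,end 0-based half-open interval
#' @param strand `"+"` returns the slice as stored; `"-"` returns its
#'   reverse complement (the sequence read off the minus strand 5'->3')
#' @return character scalar, uppercase DNA
#' @export
genome_slice <- function(genome, contig_id, start, end, strand = "+") {
  if (!contig_id %in% names(genome))
    stop("unknown contig: ", contig_id)
  len <- length(genome[[contig_id]])
  if (start < 0L || end > len || start >= end)
    stop(sprintf("slice [%d,%d) outside contig '%s' of length %d",
                 start, end, contig_id, len))
  s <- Biostrings::subseq(genome[[contig_id]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Reverse-complement a DNA string (U accepted on input, mapped to T)
#' @param x character scalar
#' @return character scalar
#' @export
revcomp <- function(x) {
  x <- chartr("Uu", "Tt", x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
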