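# Shared fixtures and independent oracles. Oracles deliberately use different
# arithmetic (per-base position sets, direct enumeration) from the package
# implementation they check.

# deterministic toy genome: repeatable sequence without calling the generator
toy_genome <- function(len = 1000L, contig = "chrT", seed = 42L) {
  set.seed(seed)
  g <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
  names(g) <- contig
  g
}

# a plus-strand locus mirroring the canonical worked geometry:
# hairpin [5000,5085), 5p [5006,5028), 3p [5058,5080)
toy_locus <- function(strand = "+") {
  mirna_locus("hsa-mir-demo", "chrT", strand,
              hairpin = c(5000L, 5085L),
              arms = if (strand == "+")
                list("5p" = c(5006L, 5028L), "3p" = c(5058L, 5080L))
              else
                list("5p" = c(5057L, 5079L), "3p" = c(5005L, 5027L)))
}

# map a half-open interval through reverse-complementing a contig of length L
flip_interval <- function(iv, L) c(L - iv[2L], L - iv[1L])
flip_strand <- function(s) ifelse(s == "+", "-", "+")

# independent per-base classifier: enumerates read positions as sets and
# counts memberships, instead of interval endpoint arithmetic
oracle_classify <- function(start, end, strand, locus, margin_nt = 25L,
                            border_overhang = 3L, contig_length = NULL) {
  pos <- seq(start, end - 1L)
  hp <- locus$hairpin
  if (strand != locus$strand) return("complement")
  oh <- border_overhang
  inside <- pos >= hp[1L] & pos < hp[2L]
  left_out <- sum(pos < hp[1L])
  right_out <- sum(pos >= hp[2L])
  if ((left_out >= oh && any(inside)) || (right_out >= oh && any(inside)))
    return("extension")
  # segment of each base, in genomic terms
  a5 <- locus$arms[["5p"]]; a3 <- locus$arms[["3p"]]
  arms <- list(a5, a3)
  lo_arm <- arms[[which.min(c(a5[1L], a3[1L]))]]
  hi_arm <- arms[[which.max(c(a5[1L], a3[1L]))]]
  borders <- c(lo_arm, hi_arm)
  borders <- borders[borders > hp[1L] & borders < hp[2L]]
  for (b in borders) {
    if (sum(pos < b) >= oh && sum(pos >= b) >= oh) return("overlap")
  }
  for (arm in list(a5, a3)) {
    slop_lo <- arm[1L] - (oh - 1L); slop_hi <- arm[2L] + (oh - 1L)
    if (all(pos >= slop_lo & pos < slop_hi)) return("mature")
  }
  non_mature <- list(c(hp[1L], lo_arm[1L]), c(lo_arm[2L], hi_arm[1L]),
                     c(hi_arm[2L], hp[2L]))
  for (seg in non_mature) {
    if (seg[2L] > seg[1L] && all(pos >= seg[1L] & pos < seg[2L]))
      return("loop")
  }
  "unassigned"
}

# brute-force Watson-Crick pairing count over an explicit pairing table
oracle_n_paired <- function(mirna, window, allow_gu = FALSE) {
  pair_ok <- function(x, y) {
    wc <- (x == "A" & y == "T") | (x == "T" & y == "A") |
          (x == "G" & y == "C") | (x == "C" & y == "G")
    if (allow_gu) wc <- wc | (x == "G" & y == "T") | (x == "T" & y == "G")
    wc
  }
  m <- strsplit(toupper(chartr("U", "T", mirna)), "")[[1L]]
  w <- strsplit(toupper(chartr("U", "T", window)), "")[[1L]]
  n <- min(length(m), length(w))
  sum(vapply(seq_len(n),
             function(i) pair_ok(m[i], w[length(w) - i + 1L]), logical(1)))
}

# per-id bitmask enumeration of Venn sections
oracle_venn_counts <- function(sets) {
  ids <- unique(unlist(sets))
  mask <- vapply(ids, function(id)
    sum(2^(which(vapply(sets, function(s) id %in% s, logical(1))) - 1L)),
    numeric(1))
  table(mask)
}

# build id sets realizing given pairwise/triple partition cardinalities for
# three groups (sections named by membership pattern, e.g. ABC, AB, A)
sets_from_partition <- function(parts) {
  out <- list(A = character(), B = character(), C = character())
  for (sec in names(parts)) {
    k <- parts[[sec]]
    if (k == 0L) next
    new_ids <- sprintf("%s_%03d", sec, seq_len(k))
    for (g in c("A", "B", "C"))
      if (grepl(g, sec)) out[[g]] <- c(out[[g]], new_ids)
  }
  out
}
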