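# Readers/writers, coordinate conventions and junction derivation.

test_that("genome FASTA reading canonicalizes and validates", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "acgtACGT", ">c2", "ACGRN"), fa)
  expect_warning(g <- read_genome(fa), "non-ACGTN")
  expect_equal(as.character(g[["c1"]]), "ACGTACGT")
  expect_equal(as.character(g[["c2"]]), "ACGNN")

  dup <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT", ">c1", "TTTT"), dup)
  expect_error(read_genome(dup), "duplicate contig")

  empty <- tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(read_genome(empty))
})

test_that("genome_slice respects bounds and strand", {
  g <- Biostrings::DNAStringSet(c(c1 = "ACGTACGT"))
  expect_equal(genome_slice(g, "c1", 0L, 4L), "ACGT")
  expect_equal(genome_slice(g, "c1", 0L, 4L, "-"), "ACGT")
  expect_equal(genome_slice(g, "c1", 1L, 4L, "-"), "ACG")  # revcomp of CGT
  expect_error(genome_slice(g, "c1", -1L, 4L))
  expect_error(genome_slice(g, "c1", 4L, 9L))
  expect_error(genome_slice(g, "nope", 0L, 2L), "unknown contig")
})

test_that("GFF3 transcript coordinates convert 1-based inclusive to half-open", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "chrT\tx\ttranscript\t101\t400\t.\t+\t.\tID=tx1;Parent=g1",
    "chrT\tx\texon\t101\t200\t.\t+\t.\tID=e1;Parent=tx1",
    "chrT\tx\texon\t301\t400\t.\t+\t.\tID=e2;Parent=tx1"), gff)
  tx <- read_transcripts(gff)[["tx1"]]
  expect_equal(unname(tx$exons[, "start"]), c(100L, 300L))
  expect_equal(unname(tx$exons[, "end"]), c(200L, 400L))
})

test_that("transcript models reject malformed exon structure", {
  expect_error(transcript_model("t", "g", "c", "+",
                                rbind(c(100L, 90L))), "end <= start")
  expect_error(transcript_model("t", "g", "c", "+",
                                rbind(c(100L, 200L), c(150L, 250L))),
               "overlapping exons")
  # minus-strand exons stored in genomic order regardless of input order
  tx <- transcript_model("t", "g", "c", "-",
                         rbind(c(300L, 400L), c(100L, 200L)))
  expect_equal(unname(tx$exons[, "start"]), c(100L, 300L))
})

test_that("junctions follow transcription order on both strands", {
  plus <- transcript_model("p", "g", "c", "+",
                           rbind(c(100L, 200L), c(300L, 400L)))
  jp <- derive_junctions(plus)
  expect_equal(jp$donor_pos, 200L)
  expect_equal(jp$acceptor_pos, 299L)
  expect_equal(jp$intron_index, 1L)

  minus <- transcript_model("m", "g", "c", "-",
                            rbind(c(100L, 200L), c(300L, 400L)))
  jm <- derive_junctions(minus)
  expect_equal(jm$donor_pos, 299L)
  expect_equal(jm$acceptor_pos, 200L)

  three <- transcript_model("t3", "g", "c", "+",
                            rbind(c(0L, 10L), c(20L, 30L), c(40L, 50L)))
  expect_equal(derive_junctions(three)$intron_index, c(1L, 2L))
  single <- transcript_model("s", "g", "c", "+", rbind(c(0L, 10L)))
  expect_equal(nrow(derive_junctions(single)), 0L)
})

test_that("minus-strand junctions match the reverse-complement oracle", {
  # flipping the contig and strand then applying the plus-strand rule must
  # land on the same genomic boundaries
  L <- 1000L
  exons <- rbind(c(100L, 250L), c(400L, 500L), c(650L, 900L))
  minus <- transcript_model("m", "g", "c", "-", exons)
  jm <- derive_junctions(minus)
  flipped <- t(apply(exons, 1L, flip_interval, L = L))
  plus <- transcript_model("m", "g", "c", "+", flipped)
  jp <- derive_junctions(plus)
  # a donor at p on the flipped plus strand maps back to L - 1 - p
  expect_equal(jm$donor_pos[order(jm$intron_index)],
               (L - 1L) - jp$donor_pos[order(jp$intron_index)])
  expect_equal(jm$acceptor_pos[order(jm$intron_index)],
               (L - 1L) - jp$acceptor_pos[order(jp$intron_index)])
})

test_that("miRNA family extraction strips copies, arms and variants", {
  expect_equal(mirna_family("hsa-let-7c"), "let-7")
  expect_equal(mirna_family("hsa-let-7a-1"), "let-7")
  expect_equal(mirna_family("hsa-miR-99b-5p"), "mir-99")
  expect_equal(mirna_family("hsa-mir-7704"), "mir-7704")
  expect_equal(mirna_family(c("hsa-let-7g", "hsa-mir-125a")),
               c("let-7", "mir-125"))
})

test_that("miRNA locus invariants are enforced", {
  expect_error(mirna_locus("m", "c", "+", c(5000L, 5085L),
                           arms = list("5p" = c(5006L, 5090L))),
               "outside hairpin")
  # 5p downstream of 3p on plus strand is rejected
  expect_error(mirna_locus("m", "c", "+", c(5000L, 5085L),
                           arms = list("5p" = c(5058L, 5080L),
                                       "3p" = c(5006L, 5028L))),
               "upstream")
  l <- toy_locus()
  expect_equal(l$hairpin, c(5000L, 5085L))
  expect_equal(l$arms[["5p"]], c(5006L, 5028L))
})

test_that("miRNA GFF3 round-trips identically", {
  loci <- list(toy_locus(), mirna_locus("hsa-mir-x", "chrT", "-",
                                        c(100L, 180L),
                                        arms = list("5p" = c(150L, 172L))))
  names(loci) <- vapply(loci, `[[`, character(1), "mirna_id")
  p <- tempfile(fileext = ".gff3")
  write_mirna_loci(loci, p)
  back <- read_mirna_loci(p)
  expect_setequal(names(back), names(loci))
  for (nm in names(loci)) {
    expect_equal(back[[nm]]$hairpin, loci[[nm]]$hairpin)
    expect_equal(back[[nm]]$strand, loci[[nm]]$strand)
    expect_equal(back[[nm]]$arms[order(names(back[[nm]]$arms))],
                 loci[[nm]]$arms[order(names(loci[[nm]]$arms))])
  }
})

test_that("transcript GFF3 round-trips identically", {
  txs <- list(
    "tx1" = transcript_model("tx1", "g1", "chrT", "+",
                             rbind(c(100L, 200L), c(300L, 400L)), "lncRNA"),
    "tx2" = transcript_model("tx2", "g2", "chrT", "-",
                             rbind(c(500L, 600L), c(700L, 800L))))
  p <- tempfile(fileext = ".gff3")
  write_transcripts(txs, p)
  back <- read_transcripts(p)
  for (nm in names(txs)) {
    expect_equal(back[[nm]]$exons, txs[[nm]]$exons)
    expect_equal(back[[nm]]$strand, txs[[nm]]$strand)
    expect_equal(back[[nm]]$biotype, txs[[nm]]$biotype)
  }
})

test_that("BED and SAM alignments unify to half-open intervals", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t5006\t5028\tr1\t0\t+", bed)
  b <- read_alignments(bed, "bed")
  expect_equal(b$start, 5006L)
  expect_equal(b$end, 5028L)
  expect_equal(b$length, 22L)

  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               "r1\t0\tchr1\t5007\t60\t22M\t*\t0\t0\t*\t*",
               "r2\t16\tchr1\t100\t60\t20M\t*\t0\t0\t*\t*",
               "r3\t0\tchr1\t200\t60\t10M2I10M\t*\t0\t0\t*\t*"), sam)
  s <- read_alignments(sam, "sam")
  expect_equal(nrow(s), 2L)
  expect_equal(s$start[s$read_id == "r1"], 5006L)
  expect_equal(s$end[s$read_id == "r1"], 5028L)
  expect_equal(s$strand[s$read_id == "r2"], "-")
  expect_equal(attr(s, "n_rejected"), 1L)
})

test_that("alignment BED round-trips intervals and strands", {
  reads <- data.frame(read_id = c("a", "b"), contig_id = "chrT",
                      strand = c("+", "-"), start = c(10L, 50L),
                      end = c(30L, 70L), length = c(20L, 20L),
                      stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".bed")
  write_alignments(reads, p)
  back <- read_alignments(p, "bed")
  back <- back[order(back$read_id), ]
  expect_equal(back$start, reads$start)
  expect_equal(back$end, reads$end)
  expect_equal(back$strand, reads$strand)
})

test_that("count and trend tables round-trip", {
  m <- matrix(c(1, 2, 3, 4), 2, dimnames = list(c("mB", "mA"),
                                                c("s1", "s2")))
  p <- tempfile(fileext = ".tsv")
  write_counts(m, p)
  back <- read_counts(p)
  expect_equal(back, m[order(rownames(m)), ])

  tr <- data.frame(mirna_id = "m1", disease = "d", n_up = 8L, n_down = 2L,
                   stringsAsFactors = FALSE)
  pt <- tempfile(fileext = ".tsv")
  write_trend_table(tr, pt)
  expect_equal(read_trend_table(pt), tr)
  bad <- data.frame(mirna_id = "m", disease = "d", n_up = 0L, n_down = 0L)
  pb <- tempfile(fileext = ".tsv")
  utils::write.table(bad, pb, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_trend_table(pb), "no reports")
})
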