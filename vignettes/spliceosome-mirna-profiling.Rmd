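---
title: "Segmental profiling and antisense junction scanning of nuclear miRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmental profiling and antisense junction scanning of nuclear miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceomir)
```

## The problem

miRNA reads sequenced from nuclear spliceosome-fraction preparations do not
behave like a cytoplasmic miRNA census. A substantial share of reads crosses
the canonical processing borders of the pre-miRNA hairpin, extends into the
genomic margins of the annotated precursor, or aligns antisense to the
locus. Separately, some miRNAs sit antisense to spliced transcripts and are
complementary to their splice junctions, suggesting direct RNA:RNA
interference with splice-site recognition. This package implements both
analyses — segmental read classification and antisense junction scanning —
together with the expression arithmetic used around them, and a synthetic
generator that provides ground truth for every stage.

## Coordinate model

All internal coordinates are 0-based half-open `[start, end)` on a named
contig. GFF3 (1-based inclusive) and SAM (1-based) are converted once, at
the I/O boundary; BED is native. A single arithmetic convention avoids
off-by-one drift between modules; every converted interval obeys
`(gff_start - 1, gff_end) == (start, end)`. Reads are modelled gapless:
classified small RNAs are ≤ ~50 nt on hairpin loci, so SAM records with
indels or splices are rejected and counted rather than interpreted.

Splice junctions are defined in transcription order: the donor (five-prime)
position is the first intronic base downstream of the exon, the acceptor the
last intronic base. On the minus strand the donor therefore has the *higher*
genomic coordinate; the tests verify this against an oracle that
reverse-complements the locus and applies the plus-strand rule.

## Segment model and read classes

`build_segment_map()` tiles a hairpin, in transcription order, into leader,
mature 5p, loop, mature 3p and trailer, plus two flanking margins
(`margin_nt`, default 25 nt). Empty segments are legal (single-arm loci).
`classify_read()` assigns exactly one class per read per locus, in a fixed
decision order:

1. antisense to the locus strand → **complement**;
2. crossing a hairpin end with ≥ `border_overhang` nt outside → **extension**;
3. crossing an internal segment border with ≥ `border_overhang` nt on both
   sides → **overlap**;
4. contained in a mature arm, allowing < `border_overhang` nt of slop →
   **mature**;
5. contained in loop/leader/trailer → **loop**;
6. otherwise **unassigned**.

`border_overhang` defaults to 3 nt: isomiR end-wobble of 1–2 nt around arm
boundaries is common and should not promote a read to the border-crossing
class, while a genuine junction-spanning read anchors with several
nucleotides on each side. It is a configuration knob, as is the choice
(adopted here) to bin leader/trailer reads with the loop as "within
precursor, non-mature". Precedence puts complement first and extension
before internal overlap, so a read that both leaves the hairpin and crosses
an internal border counts as extension; no published convention exists for
this corner, and the order is documented rather than configurable.

Per cell line, `profile_segments()` reports read counts by class,
"references" — (miRNA, class) pairs with nonzero count over the five named
groups — and "unique items" — distinct miRNAs among them — plus per-class
miRNA sets whose overlaps `venn_partition()` enumerates over all 2^k
sections (k ≤ 6; a five-class profile yields the full 32 sections).

## Junction windows and duplex scoring

`junction_window()` extracts the last 6 exonic and first 16 intronic
nucleotides around a donor site (positions −6..−1 and +1..+16; there is no
position 0), a 22-nt window matching the length of a mature miRNA. The
offsets are parameters because they generalize a single observed geometry.
`duplex_complementarity()` aligns the mature arm 5′→3′ against the window
3′→5′, ungapped and antiparallel, counting A:T(U) and G:C pairs, with
optional G:U wobble (never fewer pairs than without; a property test
enforces monotonicity). The scores are the pair count and the longest paired
run; no thermodynamic model is attempted — the biological claim being tested
is *full* complementarity, for which counting suffices. `scan_junctions()`
gates candidate pairs by opposite strandedness and genomic overlap of the
hairpin with the junction window, and an optional exon-overlap mode reports
cluster neighbours lying antisense to exonic sequence without a junction
score.

## Expression computations

Reads shorter than 17 nt are discarded (`filter_reads`), and withdrawn
catalog entries — hsa-miR-6087 by default — are removed *before* any
normalization so library totals shrink accordingly (`exclude_mirnas`; the
tests confirm the order is observable in every CPM value). Two
normalizations coexist deliberately:

* **CPM** (`cpm()`): used for detection thresholds (≥ 30 pooled CPM per cell
  line by default, a knob `units = "reads"` applies the same rule to raw
  pooled counts) and for the ≥ 50 / ≥ 150 normalized-read top-lists, because
  those thresholds are defined on CPM-scaled data.
* **Median-of-ratios size factors** (`size_factors()`): each sample's factor
  is the median, over rows with all-positive counts, of the count divided by
  the row's geometric mean. Fold-change DEM calls in the pipeline use pooled
  counts on this scale rather than CPM: CPM's closure (columns forced to
  10^6) means a genuinely changed dominant miRNA deflates every other fold
  in that column, and median-of-ratios is the standard correction for
  exactly this compositional distortion.

DEM calls use `fold = (a + pseudo)/(b + pseudo)` with `pseudo = 1` in
normalized units — a zero-handling rule that matters exactly at the
boundary: 500 vs 100 pooled reads gives 501/101 ≈ 4.96, *below* a 5-fold
cutoff. Swapping the contrast inverts folds and flips directions
(symmetry is property-tested). Replicates are pooled (summed) per cell line
before detection and fold change; size factors are available replicate-wise.

Family aggregation groups rows by a name-derived family: strip the species
prefix, the arm suffix and locus-copy digits, keep the letter-prefix plus
numeric stem (`hsa-let-7a-1` → `let-7`, `hsa-mir-125a` → `mir-125`). This
reproduces conventional family groupings without a family database.

`delta_delta_ct()` implements relative qPCR quantitation: per condition,
ΔCt = Ct_target − Ct_reference averaged over replicates; ΔΔCt is treated
minus control; fold = 2^−ΔΔCt, with SD propagated through per-replicate
treated folds against the mean control ΔCt.

## Trend concordance

`db_direction()` reduces a per-disease report tally to up/down/conflicted:
conflicted iff the minority share strictly exceeds 10% (so 1 of 10 opposite
reports is *not* conflicted, 2 of 10 is; a 50/50 tie is maximal conflict —
ties never arise in curated examples, so the choice is ours and documented).
`classify_concordance()` extends the prose categories to a total verdict
function per miRNA: `concordant_all`, `opposite_all`, `opposite_one` (some
but not all listed diseases opposite, including opposite-in-one with the
other absent), `concordant_one_absent_other`, `db_conflicted` (any listed
disease conflicted), `absent`. Reports are counted as given — no
deduplication or weighting, since the provenance of individual reports is
not modelled.

## The synthetic generator

`make_planted_locus()` builds a 20 kb contig with a fixed layout: a
plus-strand host gene (exons at 2.0–2.2 kb and 9.0–9.3 kb) whose intron
carries three plus-strand hairpins (at 3.0, 3.5 and 4.0 kb, each with 22-nt
5p/3p arms), and a minus-strand two-exon lncRNA whose intron-1 donor sits so
that the −6..+16 window coincides genomically with the first hairpin's 5p
arm. The window sequence read off the minus strand is therefore the exact
reverse complement of the mature arm *for every seed* — the identity is a
construction invariant, not a tuned sequence — while the remaining 20 kb is
uniform random, making accidental full 22-mer complements vanishingly
unlikely (4^−22). The lncRNA's first exon spans the two other hairpins,
exercising the exon-overlap reporting mode.

`simulate_reads()` draws read classes multinomially from a six-class simplex
(default: 55% mature-5p, 15% mature-3p, 8% loop, 12% overlap, 6% extension,
4% complement — a mature-dominant profile of the kind nuclear preparations
show) and places each read uniformly within its class's geometric
constraints; lengths are uniform on 17–30 nt, honouring the length filter
while leaving room to inject shorter reads to test it. A class that cannot
be realised on any locus raises an error rather than silently reassigning
mass.

`simulate_counts()` draws negative-binomial counts (dispersion 0.1,
Poisson at 0) with mean `baseline_share × depth × multiplier ×
library_factor`; defaults are three cell lines × three replicates at 10^5
expected reads per sample, baseline shares log-uniform over ~2.5 decades,
mild lognormal library factors, and an 8-fold planted change (half up, half
down) in 10% of a 60-miRNA roster. These sizes keep the full test suite and
acceptance runs fast while leaving the planted 8-fold change comfortably
detectable above NB noise. `simulate_trend_table()` writes
`round(conflict_fraction × n_reports)` contradicting reports per record —
deterministic rounding so the strict-10% boundary cases are exact.

What the generator does *not* emulate: sequencing error, quality scores,
multi-mapping, isomiR end heterogeneity beyond placement uniformity,
cross-contamination between fractions, or real miRNA sequence composition.
Passing tests therefore demonstrate the correctness of the arithmetic and
the recoverability of planted signal under idealised noise — not performance
on real libraries.

## Pipeline and determinism

`run_pipeline()` runs generate (or load) → filter → profile → scan →
express → concord, writing TSVs, a digest manifest and a JSON-lines log. A
single run seed fans out to per-stage seeds by a stable hash of the stage
name, so identical configurations are byte-identical (tested via md5) and
stages can be rerun independently. Figures are deliberately absent from the
contract: TSV outputs are the interface. The command-line entry point
(`inst/scripts/spliceomir.R`) is a thin wrapper over the exported functions.

## Known limitations

* The classifier's `unassigned` class absorbs reads that straddle a segment
  boundary by less than the overhang while not being contained in any
  segment-with-slop; they are counted but not interpreted.
* Reads are attributed to every locus whose window they overlap;
  overlapping loci would double-count (the planted layout keeps loci
  disjoint).
* Differential expression is a fold-change rule on pooled counts — no
  dispersion estimation, test statistics or FDR; the DEM flag is a screen,
  not an inference.
* The duplex score ignores bulges, internal loops and hybridisation energy;
  it measures positional Watson–Crick identity only.
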