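# Seeded synthetic data with full ground truth: a planted antisense-junction
# locus (a sense host gene whose intron carries a three-miRNA cluster, and an
# antisense spliced lncRNA whose first 5' splice junction is exactly
# complementary to one mature arm), segment-labelled reads, negative-binomial
# replicate count matrices with known fold changes, and trend tables with a
# controllable share of contradicting reports.

GENERATOR_CLASSES <- c("mature5p", "mature3p", "loop", "overlap",
                       "extension", "complement")

# run expr under a fixed RNG state, restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())),
          add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

#' Simulation configuration
#'
#' Defaults encode the emulated study design: three cell lines in biological
#' triplicate, small-RNA read lengths 17-30 nt, negative-binomial counts with
#' dispersion 0.1, a mature-dominant segmental profile, and an eight-fold
#' planted expression change in a tenth of the miRNA roster.
#'
#' @param seed integer seed (mandatory)
#' @param n_reads sequencing depth per sample (expected total counts)
#' @param n_mirnas number of miRNAs in the count roster
#' @param n_replicates replicates per cell line
#' @param cell_lines cell-line labels
#' @param read_len_range min/max simulated read length (nt)
#' @param dispersion negative-binomial dispersion (variance = mu + disp*mu^2);
#'   0 gives Poisson counts
#' @param segment_proportions named simplex over the six generator read
#'   classes
#' @param dem_fraction share of roster miRNAs given a planted fold change
#' @param dem_fold planted fold change between cell lines for those miRNAs
#' @param conflict_fraction share of trend reports contradicting the truth
#' @param n_reports reports per miRNA x disease trend record
#' @return validated list of class `simulation_config`
#' @export
simulation_config <- function(seed,
                              n_reads = 1e5L,
                              n_mirnas = 60L,
                              n_replicates = 3L,
                              cell_lines = c("lineA", "lineB", "lineC"),
                              read_len_range = c(17L, 30L),
                              dispersion = 0.1,
                              segment_proportions = c(mature5p = 0.55,
                                                      mature3p = 0.15,
                                                      loop = 0.08,
                                                      overlap = 0.12,
                                                      extension = 0.06,
                                                      complement = 0.04),
                              dem_fraction = 0.1,
                              dem_fold = 8,
                              conflict_fraction = 0.1,
                              n_reports = 10L) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_reads > 0, n_mirnas > 0, n_replicates > 0,
            length(cell_lines) >= 2L,
            read_len_range[1L] >= 1L,
            read_len_range[2L] >= read_len_range[1L],
            dispersion >= 0,
            dem_fraction >= 0, dem_fraction <= 1, dem_fold > 0,
            conflict_fraction >= 0, conflict_fraction <= 0.5,
            n_reports >= 1L)
  if (!setequal(names(segment_proportions), GENERATOR_CLASSES))
    stop("segment_proportions must be named over: ",
         paste(GENERATOR_CLASSES, collapse = ", "))
  segment_proportions <- segment_proportions[GENERATOR_CLASSES]
  if (any(segment_proportions < 0) ||
      abs(sum(segment_proportions) - 1) > 1e-9)
    stop("segment_proportions must be a simplex (sum 1)")
  structure(list(seed = as.integer(seed), n_reads = n_reads,
                 n_mirnas = as.integer(n_mirnas),
                 n_replicates = as.integer(n_replicates),
                 cell_lines = cell_lines,
                 read_len_range = as.integer(read_len_range),
                 dispersion = dispersion,
                 segment_proportions = segment_proportions,
                 dem_fraction = dem_fraction, dem_fold = dem_fold,
                 conflict_fraction = conflict_fraction,
                 n_reports = as.integer(n_reports)),
            class = "simulation_config")
}

# fixed geometry of the planted locus (0-based half-open, contig "chrSim")
PLANTED_GEOMETRY <- list(
  contig_id = "chrSim", contig_length = 20000L,
  host = list(id = "HOSTG", tx = "HOSTG-T1", strand = "+",
              exons = rbind(c(2000L, 2200L), c(9000L, 9300L))),
  antisense = list(id = "ASLNC", tx = "ASLNC-T1", strand = "-",
                   exons = rbind(c(2300L, 2600L), c(3026L, 4200L))),
  loci = list(
    list(id = "sim-mir-99b",  hairpin = c(3000L, 3090L),
         arm5p = c(3010L, 3032L), arm3p = c(3058L, 3080L)),
    list(id = "sim-let-7e",   hairpin = c(3500L, 3585L),
         arm5p = c(3510L, 3532L), arm3p = c(3553L, 3575L)),
    list(id = "sim-mir-125a", hairpin = c(4000L, 4088L),
         arm5p = c(4012L, 4034L), arm3p = c(4056L, 4078L))),
  planted_mirna = "sim-mir-99b", planted_arm = "5p",
  junction_window = c(3010L, 3032L))

#' Generate the planted antisense-junction locus
#'
#' Builds a 20 kb contig holding a two-exon sense host gene whose intron
#' carries a cluster of three miRNA hairpins, and a two-exon antisense lncRNA
#' whose intron-1 five-prime junction window (-6..+16, 22 nt) coincides
#' genomically with the first hairpin's 5p arm, so that arm is the exact
#' reverse complement of the window sequence by construction. Sequence
#' outside the constraint is uniform random under the seed.
#'
#' @param config a [simulation_config()]
#' @param seed seed (defaults to `config$seed`)
#' @return list with `genome` (`DNAStringSet`), `transcripts`, `loci`, and
#'   `truth` (planted miRNA/arm, antisense transcript, junction window,
#'   segment proportions, expression roster with per-cell-line multipliers)
#' @export
make_planted_locus <- function(config, seed = config$seed) {
  g <- PLANTED_GEOMETRY
  with_seed(seed, {
    dna <- paste(sample(c("A", "C", "G", "T"), g$contig_length,
                        replace = TRUE), collapse = "")
    genome <- Biostrings::DNAStringSet(dna)
    names(genome) <- g$contig_id

    transcripts <- list(
      transcript_model(g$host$tx, g$host$id, g$contig_id, g$host$strand,
                       g$host$exons, biotype = "protein_coding"),
      transcript_model(g$antisense$tx, g$antisense$id, g$contig_id,
                       g$antisense$strand, g$antisense$exons,
                       biotype = "lncRNA"))
    names(transcripts) <- vapply(transcripts, `[[`, character(1),
                                 "transcript_id")

    loci <- lapply(g$loci, function(l)
      mirna_locus(l$id, g$contig_id, "+", l$hairpin,
                  arms = list("5p" = l$arm5p, "3p" = l$arm3p)))
    names(loci) <- vapply(loci, `[[`, character(1), "mirna_id")

    # expression roster: the cluster loci, a let-7-like family block, and
    # anonymous background miRNAs
    extra <- max(0L, config$n_mirnas - length(loci) - 3L)
    ids <- c(names(loci), "sim-let-7a", "sim-let-7b", "sim-let-7c",
             sprintf("sim-mir-%d", 200L + seq_len(extra)))
    ids <- ids[seq_len(min(length(ids), max(config$n_mirnas, length(loci))))]
    baseline <- 10^stats::runif(length(ids), -3.7, -1.7)
    baseline <- baseline / sum(baseline)
    names(baseline) <- ids

    multipliers <- matrix(1, nrow = length(ids),
                          ncol = length(config$cell_lines),
                          dimnames = list(ids, config$cell_lines))
    n_dem <- round(config$dem_fraction * length(ids))
    dem_ids <- character(0)
    if (n_dem > 0L) {
      dem_ids <- sample(ids, n_dem)
      up <- rep(c(TRUE, FALSE), length.out = n_dem)
      # planted change in every non-reference line, relative to the first
      for (k in seq_along(dem_ids)) {
        f <- if (up[k]) config$dem_fold else 1 / config$dem_fold
        multipliers[dem_ids[k], -1L] <- f
      }
    }

    truth <- list(
      contig_id = g$contig_id, contig_length = g$contig_length,
      planted_mirna = g$planted_mirna, planted_arm = g$planted_arm,
      antisense_transcript = g$antisense$tx,
      junction = list(intron_index = 1L,
                      window = g$junction_window,
                      kind = "five_prime"),
      segment_proportions = config$segment_proportions,
      expression = list(ids = ids, baseline = baseline,
                        multipliers = multipliers, dem_ids = sort(dem_ids)),
      loci = loci)

    # construction invariant: planted arm revcomp == junction window sequence
    arm <- loci[[g$planted_mirna]]$arms[[g$planted_arm]]
    arm_seq <- genome_slice(genome, g$contig_id, arm[1L], arm[2L], "+")
    win_seq <- genome_slice(genome, g$contig_id, g$junction_window[1L],
                            g$junction_window[2L], "-")
    stopifnot(identical(revcomp(arm_seq), win_seq))

    list(genome = genome, transcripts = transcripts, loci = loci,
         truth = truth)
  })
}

# uniform placement of one read of class `cls` on locus map; returns c(start,
# end, strand) or NULL when the class is geometrically impossible
place_read <- function(cls, map, len_range, border_overhang = 3L) {
  hp <- map$hairpin
  seg <- map$segments
  lmin <- len_range[1L]; lmax <- len_range[2L]
  pick_inside <- function(iv) {
    w <- interval_width(iv)
    if (w < lmin) return(NULL)
    len <- sample(seq(lmin, min(lmax, w)), 1L)
    start <- iv[1L] + sample.int(w - len + 1L, 1L) - 1L
    c(start, start + len)
  }
  res <- switch(cls,
    mature5p = pick_inside(seg$mature5p),
    mature3p = pick_inside(seg$mature3p),
    loop = pick_inside(seg$loop),
    complement = pick_inside(hp),
    overlap = {
      borders <- internal_borders(map)
      ok <- NULL
      for (b in sample(borders)) {
        len <- sample(seq(lmin, lmax), 1L)
        lo <- max(hp[1L], b + border_overhang - len)
        hi <- min(b - border_overhang, hp[2L] - len)
        if (lo <= hi) {
          start <- lo + sample.int(hi - lo + 1L, 1L) - 1L
          ok <- c(start, start + len); break
        }
      }
      ok
    },
    extension = {
      side <- sample(c("left", "right"), 1L)
      len <- sample(seq(lmin, lmax), 1L)
      margin <- if (side == "left") seg$margin_left else seg$margin_right
      max_out <- min(len - border_overhang, interval_width(margin))
      if (max_out < border_overhang) return(NULL)
      out_nt <- sample(seq(border_overhang, max_out), 1L)
      if (side == "left") c(hp[1L] - out_nt, hp[1L] - out_nt + len)
      else c(hp[2L] + out_nt - len, hp[2L] + out_nt)
    })
  if (is.null(res)) return(NULL)
  strand <- if (cls == "complement") setdiff(c("+", "-"), map$strand)
            else map$strand
  list(start = res[1L], end = res[2L], strand = strand)
}

#' Simulate segment-labelled reads on the planted loci
#'
#' Read classes are drawn multinomially from the truth proportions; each read
#' is placed uniformly at random within the geometric constraints of its
#' class on a uniformly chosen locus. A class with positive probability that
#' is geometrically impossible on every locus is an error.
#'
#' @param truth `truth` element of [make_planted_locus()]
#' @param n_reads number of reads
#' @param seed RNG seed
#' @param margin_nt,border_overhang geometry knobs matching the classifier
#' @param read_len_range min/max read length; lower the minimum below 17 to
#'   exercise the length filter
#' @return list with `reads` (alignment data.frame) and `labels` (data.frame
#'   read_id, mirna_id, class, expected_class — the latter in classifier
#'   vocabulary, mature5p/mature3p collapsing to `mature`)
#' @export
simulate_reads <- function(truth, n_reads, seed, margin_nt = 25L,
                           border_overhang = 3L,
                           read_len_range = c(17L, 30L)) {
  stopifnot(n_reads >= 0)
  maps <- lapply(truth$loci, build_segment_map, margin_nt = margin_nt,
                 contig_length = truth$contig_length)
  p <- truth$segment_proportions
  len_range <- as.integer(read_len_range)
  if (n_reads == 0L) {
    reads <- data.frame(read_id = character(), contig_id = character(),
                        strand = character(), start = integer(),
                        end = integer(), length = integer(),
                        stringsAsFactors = FALSE)
    labels <- data.frame(read_id = character(), mirna_id = character(),
                         class = character(), expected_class = character(),
                         stringsAsFactors = FALSE)
    return(list(reads = reads, labels = labels))
  }
  with_seed(seed, {
    cls <- sample(names(p), n_reads, replace = TRUE, prob = p)
    loc <- sample(names(maps), n_reads, replace = TRUE)
    rows <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      placed <- place_read(cls[i], maps[[loc[i]]], len_range,
                           border_overhang)
      if (is.null(placed)) {
        # try the other loci before declaring the class impossible
        for (alt in setdiff(names(maps), loc[i])) {
          placed <- place_read(cls[i], maps[[alt]], len_range,
                               border_overhang)
          if (!is.null(placed)) { loc[i] <- alt; break }
        }
      }
      if (is.null(placed))
        stop("class '", cls[i], "' is geometrically impossible; ",
             "its proportion must be zero")
      rows[[i]] <- placed
    }
    reads <- data.frame(
      read_id = sprintf("r%06d", seq_len(n_reads)),
      contig_id = truth$contig_id,
      strand = vapply(rows, `[[`, character(1), "strand"),
      start = vapply(rows, `[[`, numeric(1), "start"),
      end = vapply(rows, `[[`, numeric(1), "end"),
      stringsAsFactors = FALSE)
    reads$start <- as.integer(reads$start)
    reads$end <- as.integer(reads$end)
    reads$length <- reads$end - reads$start
    expected <- ifelse(cls %in% c("mature5p", "mature3p"), "mature", cls)
    labels <- data.frame(read_id = reads$read_id, mirna_id = loc,
                         class = cls, expected_class = expected,
                         stringsAsFactors = FALSE)
    list(reads = reads, labels = labels)
  })
}

#' Simulate replicate count matrices with known fold changes
#'
#' Counts are negative binomial with mean
#' `baseline_share * n_reads * multiplier * library_factor`; per-sample
#' library factors are mildly lognormal. miRNAs whose multiplier ratio
#' between any two cell lines reaches `config$dem_fold >= 5` carry the
#' true-DEM flag.
#'
#' @param truth `truth` element of [make_planted_locus()]
#' @param config a [simulation_config()]
#' @param seed RNG seed
#' @return count matrix (miRNA x sample) with attributes `groups` (named
#'   cell-line label per sample), `true_dem` (ids), `library_factors`
#' @export
simulate_counts <- function(truth, config, seed = config$seed) {
  ex <- truth$expression
  with_seed(seed, {
    samples <- as.vector(t(outer(config$cell_lines,
                                 seq_len(config$n_replicates),
                                 function(l, r) paste0(l, "_rep", r))))
    groups <- rep(config$cell_lines, each = config$n_replicates)
    names(groups) <- samples
    lib <- exp(stats::rnorm(length(samples), 0, 0.15))
    names(lib) <- samples
    mu <- outer(ex$baseline, rep(1, length(samples))) *
          ex$multipliers[, groups, drop = FALSE] *
          rep(lib, each = length(ex$ids)) * config$n_reads
    counts <- matrix(0, nrow = length(ex$ids), ncol = length(samples),
                     dimnames = list(ex$ids, samples))
    if (config$dispersion > 0) {
      counts[] <- stats::rnbinom(length(mu), mu = as.vector(mu),
                                 size = 1 / config$dispersion)
    } else {
      counts[] <- stats::rpois(length(mu), lambda = as.vector(mu))
    }
    ratio <- apply(ex$multipliers, 1L, function(m) max(m) / min(m))
    attr(counts, "groups") <- groups
    attr(counts, "true_dem") <- sort(ex$ids[ratio >= 5])
    attr(counts, "library_factors") <- lib
    counts
  })
}

#' Simulate a literature trend table with controlled contradiction
#'
#' Each miRNA x disease record receives `n_reports` reports, of which
#' `round(conflict_fraction * n_reports)` contradict the true direction.
#'
#' @param true_trends data.frame with `mirna_id`, `disease`, `direction`
#'   (`"up"`/`"down"`)
#' @param conflict_fraction in \[0, 0.5\]
#' @param n_reports reports per record
#' @param seed RNG seed (row order only; counts are deterministic)
#' @return trend data.frame: mirna_id, disease, n_up, n_down
#' @export
simulate_trend_table <- function(true_trends, conflict_fraction,
                                 n_reports = 10L, seed = 1L) {
  stopifnot(conflict_fraction >= 0, conflict_fraction <= 0.5,
            all(c("mirna_id", "disease", "direction") %in%
                  names(true_trends)))
  n_opp <- round(conflict_fraction * n_reports)
  n_same <- n_reports - n_opp
  up <- true_trends$direction == "up"
  out <- data.frame(mirna_id = true_trends$mirna_id,
                    disease = true_trends$disease,
                    n_up = ifelse(up, n_same, n_opp),
                    n_down = ifelse(up, n_opp, n_same),
                    stringsAsFactors = FALSE)
  with_seed(seed, out[sample.int(nrow(out)), , drop = FALSE])
}
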