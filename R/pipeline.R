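# End-to-end pipeline: generate (or load) -> filter -> profile -> scan ->
# express -> concord, with deterministic per-stage seeding, a JSON-lines log
# and a digest manifest of every output file.

PIPELINE_KEYS <- c("seed", "outdir", "generate", "inputs", "min_len",
                   "margin_nt", "border_overhang", "detect_threshold",
                   "detect_units", "fc_threshold", "pseudo", "upstream",
                   "downstream", "allow_gu", "exon_mode", "blacklist",
                   "diseases", "contrast", "n_reads_sim")

# stable per-stage seed fan-out from the run seed
stage_seed <- function(seed, stage) {
  (as.integer(seed) + sum(utf8ToInt(stage)) * 131L) %% .Machine$integer.max
}

#' Validate a pipeline run configuration
#'
#' @param config named list (or path to a YAML file) with at least `seed`
#'   and `outdir`; unknown keys are rejected. Either `generate` (TRUE or a
#'   list of [simulation_config()] overrides) or `inputs` (paths: genome,
#'   transcripts, mirna_loci, alignments, counts, trends) must be present.
#' @return validated config list with defaults filled in
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$seed)) stop("config$seed is required")
  if (is.null(config$outdir)) stop("config$outdir is required")
  if (is.null(config$generate) && is.null(config$inputs))
    stop("config needs a generate block or an inputs block")
  defaults <- list(min_len = 17L, margin_nt = 25L, border_overhang = 3L,
                   detect_threshold = 30, detect_units = "cpm",
                   fc_threshold = 5, pseudo = 1.0,
                   upstream = 6L, downstream = 16L, allow_gu = FALSE,
                   exon_mode = FALSE, blacklist = "hsa-miR-6087",
                   diseases = c("diseaseA", "diseaseB"),
                   n_reads_sim = 20000L)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  stopifnot(config$min_len >= 1, config$margin_nt >= 0,
            config$border_overhang >= 1, config$detect_threshold >= 0,
            config$fc_threshold > 1, config$pseudo >= 0,
            config$upstream >= 0, config$downstream >= 0)
  config
}

#' Run the full pipeline
#'
#' Stages run in fixed order: generate (or load), filter, profile, scan,
#' express, concord. Every output file is listed in the returned manifest
#' with an md5 digest; a JSON-lines log in the output directory records
#' parameters, per-filter in/out counts and the seed. A single run seed fans
#' out to stable per-stage seeds so stages are individually reproducible.
#'
#' @param config see [pipeline_config()]
#' @return invisible list with `manifest` (data.frame file/md5), `summary`
#'   (headline numbers per stage) and `results` (in-memory stage outputs)
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$outdir, "run_log.jsonl")
  unlink(log_path)
  logj <- function(stage, ...) {
    rec <- c(list(stage = stage), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE, sep = "")
  }
  outputs <- character(0)
  emit <- function(path) outputs[[length(outputs) + 1L]] <<- path
  logj("init", seed = cfg$seed, params = cfg[setdiff(names(cfg),
                                                     c("seed", "outdir"))])

  ## -- generate or load ------------------------------------------------
  if (!is.null(cfg$generate)) {
    overrides <- if (is.list(cfg$generate)) cfg$generate else list()
    sim_cfg <- do.call(simulation_config,
                       c(list(seed = stage_seed(cfg$seed, "generate")),
                         overrides))
    locus <- make_planted_locus(sim_cfg)
    sim <- simulate_reads(locus$truth, cfg$n_reads_sim,
                          stage_seed(cfg$seed, "reads"),
                          margin_nt = cfg$margin_nt,
                          border_overhang = cfg$border_overhang)
    counts <- simulate_counts(locus$truth, sim_cfg,
                              stage_seed(cfg$seed, "counts"))
    groups <- attr(counts, "groups")
    true_dem <- attr(counts, "true_dem")
    mult <- locus$truth$expression$multipliers
    dem_dir <- ifelse(mult[true_dem, 2L] > mult[true_dem, 1L], "up", "down")
    true_trends <- data.frame(
      mirna_id = rep(true_dem, each = length(cfg$diseases)),
      disease = rep(cfg$diseases, length(true_dem)),
      direction = rep(dem_dir, each = length(cfg$diseases)),
      stringsAsFactors = FALSE)
    trends <- simulate_trend_table(true_trends, sim_cfg$conflict_fraction,
                                   sim_cfg$n_reports,
                                   stage_seed(cfg$seed, "trends"))
    paths <- list(genome = file.path(cfg$outdir, "genome.fa"),
                  transcripts = file.path(cfg$outdir, "transcripts.gff3"),
                  mirna_loci = file.path(cfg$outdir, "mirna_loci.gff3"),
                  alignments = file.path(cfg$outdir, "reads.bed"),
                  counts = file.path(cfg$outdir, "counts.tsv"),
                  trends = file.path(cfg$outdir, "trends.tsv"))
    write_genome(locus$genome, paths$genome)
    write_transcripts(locus$transcripts, paths$transcripts)
    write_mirna_loci(locus$loci, paths$mirna_loci)
    write_alignments(sim$reads, paths$alignments)
    write_counts(counts, paths$counts)
    write_trend_table(trends, paths$trends)
    truth_path <- file.path(cfg$outdir, "labels_truth.tsv")
    utils::write.table(sim$labels, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    groups_path <- file.path(cfg$outdir, "sample_groups.tsv")
    utils::write.table(data.frame(sample = names(groups),
                                  cell_line = unname(groups)),
                       groups_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    for (p in c(unlist(paths), truth_path, groups_path)) emit(p)
    genome <- locus$genome; transcripts <- locus$transcripts
    loci <- locus$loci; reads <- sim$reads
    logj("generate", n_reads = nrow(reads), n_mirnas = nrow(counts),
         n_trend_records = nrow(trends))
  } else {
    inp <- cfg$inputs
    need <- c("genome", "transcripts", "mirna_loci", "alignments",
              "counts", "trends", "groups")
    missing_keys <- setdiff(need, names(inp))
    if (length(missing_keys))
      stop("inputs block missing: ", paste(missing_keys, collapse = ", "))
    genome <- read_genome(inp$genome)
    transcripts <- read_transcripts(inp$transcripts)
    loci <- read_mirna_loci(inp$mirna_loci)
    reads <- read_alignments(inp$alignments,
                             dialect = if (grepl("\\.sam$", inp$alignments))
                               "sam" else "bed")
    counts <- read_counts(inp$counts)
    trends <- read_trend_table(inp$trends)
    gdf <- utils::read.delim(inp$groups, stringsAsFactors = FALSE)
    groups <- stats::setNames(gdf$cell_line, gdf$sample)
    logj("load", n_reads = nrow(reads), n_mirnas = nrow(counts))
  }

  ## -- filter ----------------------------------------------------------
  n_before <- nrow(reads)
  reads <- filter_reads(reads, cfg$min_len)
  logj("filter", n_in = n_before, n_out = nrow(reads),
       n_removed = attr(reads, "n_removed"))

  ## -- profile ---------------------------------------------------------
  contig_lengths <- stats::setNames(Biostrings::width(genome), names(genome))
  prof <- profile_segments(reads, loci, margin_nt = cfg$margin_nt,
                           border_overhang = cfg$border_overhang,
                           contig_lengths = contig_lengths)
  p1 <- file.path(cfg$outdir, "read_classes.tsv")
  utils::write.table(prof$assignments, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p2 <- file.path(cfg$outdir, "segment_profile.tsv")
  utils::write.table(data.frame(mirna_id = rownames(prof$counts),
                                prof$counts, check.names = FALSE),
                     p2, sep = "\t", quote = FALSE, row.names = FALSE)
  emit(p1); emit(p2)
  if (length(prof$class_sets) >= 2L) {
    vp <- venn_partition(prof$class_sets)
    p3 <- file.path(cfg$outdir, "segment_venn.tsv")
    utils::write.table(vp, p3, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p3)
  }
  logj("profile", n_classified = nrow(prof$assignments),
       references = prof$n_references, unique_items = prof$n_unique_items)

  ## -- scan ------------------------------------------------------------
  hits <- scan_junctions(loci, transcripts, genome,
                         upstream = cfg$upstream,
                         downstream = cfg$downstream,
                         allow_gu = cfg$allow_gu,
                         exon_mode = cfg$exon_mode)
  p4 <- file.path(cfg$outdir, "junction_hits.tsv")
  p5 <- file.path(cfg$outdir, "junction_hits.bed")
  write_scan_report(hits, p4, p5)
  emit(p4); emit(p5)
  n_full <- sum(hits$full_complement, na.rm = TRUE)
  logj("scan", n_hits = nrow(hits), n_full_complement = n_full)

  ## -- express ---------------------------------------------------------
  counts_f <- exclude_mirnas(counts, cfg$blacklist)
  logj("exclude", n_dropped = attr(counts_f, "n_dropped"))
  sf <- size_factors(counts_f)
  pooled <- pool_by_group(counts_f, groups)
  det <- detection_sets(pooled, cfg$detect_threshold,
                        units = cfg$detect_units)
  pooled_cpm <- cpm(pooled)
  # fold changes on median-of-ratios-normalized pooled counts: robust to the
  # compositional distortion CPM suffers when dominant species change
  pooled_mor <- sweep(pooled, 2L, size_factors(pooled), "/")
  lines_ <- colnames(pooled)
  contrast <- if (!is.null(cfg$contrast)) cfg$contrast else lines_[c(2L, 1L)]
  dem <- fold_change_dem(pooled_mor, contrast, cfg$fc_threshold, cfg$pseudo)
  top <- top_lists(pooled_cpm, min_reads = 150)
  p6 <- file.path(cfg$outdir, "cpm_pooled.tsv"); write_counts(pooled_cpm, p6)
  p7 <- file.path(cfg$outdir, "dem_table.tsv")
  utils::write.table(dem[order(dem$mirna_id), ], p7, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  p8 <- file.path(cfg$outdir, "detection_venn.tsv")
  utils::write.table(det$venn, p8, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p9 <- file.path(cfg$outdir, "top_list.tsv")
  utils::write.table(top, p9, sep = "\t", quote = FALSE, row.names = FALSE)
  for (p in c(p6, p7, p8, p9)) emit(p)
  logj("express", size_factors = as.list(round(sf, 4)),
       n_detected = length(det$detected_any), n_dem = sum(dem$dem))

  ## -- concord ---------------------------------------------------------
  dem_rows <- dem[dem$dem, c("mirna_id", "direction")]
  conc <- classify_concordance(dem_rows, trends, cfg$diseases)
  p10 <- file.path(cfg$outdir, "concordance_calls.tsv")
  utils::write.table(conc$calls, p10, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p11 <- file.path(cfg$outdir, "concordance_summary.tsv")
  utils::write.table(data.frame(verdict = names(conc$summary),
                                count = as.integer(conc$summary)),
                     p11, sep = "\t", quote = FALSE, row.names = FALSE)
  emit(p10); emit(p11)
  logj("concord", summary = as.list(conc$summary))

  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  mpath <- file.path(cfg$outdir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary <- list(n_reads = nrow(reads),
                  n_classified = nrow(prof$assignments),
                  references = prof$n_references,
                  unique_items = prof$n_unique_items,
                  n_full_complement_hits = n_full,
                  n_detected = length(det$detected_any),
                  n_dem = sum(dem$dem),
                  concordance = as.list(conc$summary))
  invisible(list(manifest = manifest, summary = summary,
                 results = list(profile = prof, hits = hits, dem = dem,
                                detection = det, concordance = conc,
                                size_factors = sf)))
}
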