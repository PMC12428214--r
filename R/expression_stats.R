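# Expression computations: read-length and blacklist filters, CPM and
# median-of-ratios normalization, per-cell-line detection sets with Venn
# partitions, fold-change DEM calls, ranked top-lists, family aggregation,
# and 2^-ddCt qPCR quantitation.

#' Filter reads by minimum length
#'
#' Sequences shorter than `min_len` nucleotides are removed; the number
#' removed is attached as attribute `n_removed`.
#'
#' @param reads alignment data.frame with a `length` column
#' @param min_len minimum retained length in nt (default 17)
#' @return filtered data.frame
#' @export
filter_reads <- function(reads, min_len = 17L) {
  keep <- reads$length >= min_len
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Drop blacklisted miRNAs from a raw count matrix
#'
#' Withdrawn catalog entries (by default hsa-miR-6087) are removed before any
#' normalization, so library totals shrink accordingly. Absent blacklist
#' entries are ignored.
#'
#' @param counts raw count matrix (miRNA rows)
#' @param blacklist character vector of row ids to drop
#' @return count matrix without the blacklisted rows; attribute `n_dropped`
#' @export
exclude_mirnas <- function(counts, blacklist = "hsa-miR-6087") {
  hit <- rownames(counts) %in% blacklist
  out <- counts[!hit, , drop = FALSE]
  attr(out, "n_dropped") <- sum(hit)
  out
}

#' Counts-per-million normalization
#'
#' @param counts raw count matrix; every column total must be positive
#' @return matrix of the same shape; each column sums to 1e6
#' @export
cpm <- function(counts) {
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("zero-total column(s): ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  sweep(counts, 2L, tot, "/") * 1e6
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference rows (rows
#' with all-positive counts) of the ratio of that sample's count to the row's
#' geometric mean across samples.
#'
#' @param counts raw count matrix with at least two samples
#' @return named numeric vector of positive size factors
#' @export
size_factors <- function(counts) {
  if (ncol(counts) < 2L) stop("need >= 2 samples")
  pos <- rowSums(counts <= 0) == 0L
  if (!any(pos))
    stop("no row with all-positive counts; filter low-abundance rows first")
  ref <- counts[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(ref)))
  apply(ref, 2L, function(col) stats::median(col / geo))
}

#' Pool replicate columns by cell-line group
#'
#' @param counts count matrix
#' @param groups character vector (or named vector keyed by sample) giving
#'   the cell-line label of each column
#' @return matrix with one summed column per group
#' @export
pool_by_group <- function(counts, groups) {
  if (!is.null(names(groups))) groups <- groups[colnames(counts)]
  stopifnot(length(groups) == ncol(counts))
  g <- unique(groups)
  out <- vapply(g, function(x)
    rowSums(counts[, groups == x, drop = FALSE]), numeric(nrow(counts)))
  colnames(out) <- g
  out
}

#' Per-cell-line detection sets and their Venn partition
#'
#' A miRNA is detected in a cell line when its pooled value meets
#' `detect_threshold` (in CPM units by default, or raw pooled reads with
#' `units = "reads"`).
#'
#' @param pooled matrix with one pooled raw-count column per cell line
#' @param detect_threshold detection cutoff (default 30)
#' @param units `"cpm"` or `"reads"`
#' @return list with `sets` (per-line id vectors), `venn`
#'   ([venn_partition()] over the lines), `detected_any` (union)
#' @export
detection_sets <- function(pooled, detect_threshold = 30, units = c("cpm", "reads")) {
  units <- match.arg(units)
  vals <- if (units == "cpm") cpm(pooled) else pooled
  sets <- lapply(colnames(vals), function(s)
    rownames(vals)[vals[, s] >= detect_threshold])
  names(sets) <- colnames(vals)
  list(sets = sets,
       venn = venn_partition(sets, universe = rownames(pooled)),
       detected_any = sort(unique(unlist(sets))))
}

#' Fold-change DEM calls between two cell lines
#'
#' fold = (a + pseudo) / (b + pseudo) on pooled normalized values; a miRNA is
#' a DEM when fold >= `fc_threshold` (up) or <= 1/`fc_threshold` (down).
#'
#' @param pooled_norm pooled normalized matrix (e.g. pooled CPM)
#' @param pair length-2 character, the (numerator, denominator) cell lines
#' @param fc_threshold fold-change cutoff (default 5)
#' @param pseudo pseudo-count in normalized units (default 1)
#' @return data.frame: mirna_id, value_a, value_b, fold, direction, dem
#' @export
fold_change_dem <- function(pooled_norm, pair, fc_threshold = 5,
                            pseudo = 1.0) {
  stopifnot(length(pair) == 2L, all(pair %in% colnames(pooled_norm)))
  a <- pooled_norm[, pair[1L]]
  b <- pooled_norm[, pair[2L]]
  fold <- (a + pseudo) / (b + pseudo)
  data.frame(mirna_id = rownames(pooled_norm),
             value_a = unname(a), value_b = unname(b),
             fold = unname(fold),
             direction = ifelse(fold >= 1, "up", "down"),
             dem = fold >= fc_threshold | fold <= 1 / fc_threshold,
             stringsAsFactors = FALSE)
}

#' Ranked top-list of miRNAs by total normalized expression
#'
#' Keeps rows whose total across cell lines meets `min_reads`, ranked by
#' total descending, with each line's percentage share of the row total.
#'
#' @param pooled_norm pooled normalized matrix
#' @param min_reads minimum row total (e.g. 50 or 150 normalized reads)
#' @return data.frame: mirna_id, per-line values, `total`, per-line
#'   `share_<line>` percentages summing to 100 per row
#' @export
top_lists <- function(pooled_norm, min_reads) {
  tot <- rowSums(pooled_norm)
  keep <- tot >= min_reads
  m <- pooled_norm[keep, , drop = FALSE]
  tot <- tot[keep]
  ord <- order(-tot, rownames(m))
  m <- m[ord, , drop = FALSE]; tot <- tot[ord]
  shares <- sweep(m, 1L, tot, "/") * 100
  colnames(shares) <- paste0("share_", colnames(m))
  out <- data.frame(mirna_id = rownames(m), m, total = unname(tot), shares,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Aggregate a miRNA family across cell lines
#'
#' Family labels come from [mirna_family()] applied to row ids. Reports the
#' family total per line, the family's percentage share of all reads in that
#' line, the dominant member per line, and the member composition.
#'
#' @param pooled_norm pooled normalized matrix
#' @param family family name, e.g. `"let-7"`
#' @return list with `members`, `totals`, `share_of_line` (percent),
#'   `dominant_member` (per line), `composition` (member x line matrix);
#'   empty members (with a warning) for an unknown family
#' @export
family_aggregate <- function(pooled_norm, family) {
  fam <- mirna_family(rownames(pooled_norm))
  sel <- fam == family
  if (!any(sel)) {
    warning("no rows for family '", family, "'")
    return(list(members = character(), totals = NULL, share_of_line = NULL,
                dominant_member = NULL, composition = NULL))
  }
  comp <- pooled_norm[sel, , drop = FALSE]
  totals <- colSums(comp)
  line_tot <- colSums(pooled_norm)
  list(members = rownames(comp),
       totals = totals,
       share_of_line = 100 * totals / line_tot,
       dominant_member = rownames(comp)[apply(comp, 2L, which.max)],
       composition = comp)
}

#' Relative qPCR quantitation by the 2^-ddCt method
#'
#' Each record carries replicate Ct values of a target and a reference gene
#' under treated and control conditions. Per condition, dCt = Ct_target -
#' Ct_reference averaged over replicates; ddCt = dCt_treated - dCt_control;
#' fold = 2^-ddCt. The SD is propagated through per-replicate treated folds
#' computed against the mean control dCt.
#'
#' @param records data.frame with columns `target`, `condition`
#'   (`"treated"`/`"control"`), `target_ct`, `ref_ct`; one row per replicate
#' @return data.frame: target, dct_treated, dct_control, ddct, fold, fold_sd
#' @export
delta_delta_ct <- function(records) {
  need <- c("target", "condition", "target_ct", "ref_ct")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  if (anyNA(records$ref_ct)) stop("missing reference Ct")
  out <- lapply(split(records, records$target), function(r) {
    dct <- r$target_ct - r$ref_ct
    tr <- dct[r$condition == "treated"]
    ct <- dct[r$condition == "control"]
    if (length(tr) < 1L || length(ct) < 1L)
      stop("need >= 1 replicate per condition for ", r$target[1L])
    ddct <- mean(tr) - mean(ct)
    rep_folds <- 2^-(tr - mean(ct))
    data.frame(target = r$target[1L],
               dct_treated = mean(tr), dct_control = mean(ct),
               ddct = ddct, fold = 2^-ddct,
               fold_sd = if (length(rep_folds) > 1L) stats::sd(rep_folds)
                         else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
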