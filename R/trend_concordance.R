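# Concordance of cell-line DEM directions with a literature trend table
# (miRCancer-style per-disease up/down report tallies), including the
# conflicted-database rule: a record is conflicted when strictly more than
# 10% of its reports run against the majority direction.

#' Majority direction of a trend record with the conflict rule
#'
#' @param n_up,n_down report counts (vectors allowed); n_up + n_down >= 1
#' @param conflict_fraction records whose minority share strictly exceeds
#'   this fraction are `"conflicted"` (default 0.10); a 50/50 tie is
#'   maximally conflicted
#' @return character vector over `"up"`, `"down"`, `"conflicted"`
#' @export
db_direction <- function(n_up, n_down, conflict_fraction = 0.10) {
  tot <- n_up + n_down
  if (any(tot < 1L)) stop("trend record with no reports")
  minority <- pmin(n_up, n_down) / tot
  ifelse(minority > conflict_fraction, "conflicted",
         ifelse(n_up >= n_down, "up", "down"))
}

CONCORDANCE_VERDICTS <- c("concordant_all", "opposite_all", "opposite_one",
                          "concordant_one_absent_other", "db_conflicted",
                          "absent")

# verdict from per-disease statuses in {concordant, opposite, conflicted, absent}
verdict_from_status <- function(status) {
  if (all(status == "absent")) return("absent")
  if (any(status == "conflicted")) return("db_conflicted")
  n_opp <- sum(status == "opposite")
  n_con <- sum(status == "concordant")
  n_abs <- sum(status == "absent")
  if (n_opp > 0L) {
    if (n_opp == length(status)) "opposite_all" else "opposite_one"
  } else if (n_abs > 0L) {
    "concordant_one_absent_other"
  } else {
    "concordant_all"
  }
}

#' Classify DEM directions against a per-disease trend table
#'
#' Each DEM's cell-line direction is compared with the database direction for
#' every named disease. Per miRNA the verdict is: `absent` (no disease lists
#' it), `db_conflicted` (any listed disease is conflicted under the >10%
#' rule), `opposite_all` (opposite in every disease), `concordant_all`
#' (concordant in every disease), `opposite_one` (opposite in some but not
#' all diseases, or opposite in one with the others absent), or
#' `concordant_one_absent_other` (concordant where listed, absent elsewhere).
#'
#' @param dem_table data.frame with `mirna_id`, `direction` (`"up"`/`"down"`),
#'   typically the DEM rows of [fold_change_dem()]
#' @param trend_db trend table ([read_trend_table()])
#' @param diseases character vector of diseases to score against
#' @param conflict_fraction see [db_direction()]
#' @return list with `calls` (per-miRNA data.frame: db direction per disease,
#'   verdict), `summary` (verdict counts), `venn` (DEM set vs per-disease db
#'   sets, [venn_partition()])
#' @export
classify_concordance <- function(dem_table, trend_db, diseases,
                                 conflict_fraction = 0.10) {
  stopifnot(all(c("mirna_id", "direction") %in% names(dem_table)))
  db <- trend_db[trend_db$disease %in% diseases, , drop = FALSE]
  db$dir <- db_direction(db$n_up, db$n_down, conflict_fraction)
  calls <- lapply(seq_len(nrow(dem_table)), function(i) {
    id <- dem_table$mirna_id[i]
    cell_dir <- dem_table$direction[i]
    status <- vapply(diseases, function(d) {
      row <- db[db$mirna_id == id & db$disease == d, , drop = FALSE]
      if (nrow(row) == 0L) return("absent")
      if (row$dir[1L] == "conflicted") return("conflicted")
      if (row$dir[1L] == cell_dir) "concordant" else "opposite"
    }, character(1))
    dirs <- vapply(diseases, function(d) {
      row <- db[db$mirna_id == id & db$disease == d, , drop = FALSE]
      if (nrow(row) == 0L) "absent" else row$dir[1L]
    }, character(1))
    out <- data.frame(mirna_id = id, cell_direction = cell_dir,
                      verdict = verdict_from_status(status),
                      stringsAsFactors = FALSE)
    for (d in diseases) out[[paste0("db_", d)]] <- dirs[[d]]
    out
  })
  calls <- do.call(rbind, calls)
  calls <- calls[order(calls$mirna_id), , drop = FALSE]
  rownames(calls) <- NULL
  summary <- table(factor(calls$verdict, levels = CONCORDANCE_VERDICTS))
  sets <- c(list(DEM = dem_table$mirna_id),
            lapply(stats::setNames(diseases, diseases), function(d)
              unique(db$mirna_id[db$disease == d])))
  list(calls = calls, summary = summary,
       venn = venn_partition(sets))
}
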