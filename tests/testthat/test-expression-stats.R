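# Filters, normalization laws, detection sets, fold-change calls, top-lists,
# family aggregation and ddCt quantitation.

toy_counts <- function() {
  m <- matrix(c(10, 30, 60,
                20, 60, 120,
                5, 15, 30), nrow = 3,
              dimnames = list(c("hsa-mir-1", "hsa-mir-2", "hsa-miR-6087"),
                              c("s1", "s2", "s3")))
  m
}

test_that("read length filter retains >= 17 nt", {
  reads <- data.frame(read_id = c("a", "b", "c"), length = c(16L, 17L, 18L))
  kept <- filter_reads(reads)
  expect_equal(kept$read_id, c("b", "c"))
  expect_equal(attr(kept, "n_removed"), 1L)
  all17 <- data.frame(read_id = "a", length = 20L)
  expect_equal(nrow(filter_reads(all17)), 1L)
  expect_equal(nrow(filter_reads(reads[0, ])), 0L)
})

test_that("blacklist exclusion precedes normalization and changes CPM", {
  m <- toy_counts()
  ex <- exclude_mirnas(m)
  expect_false("hsa-miR-6087" %in% rownames(ex))
  expect_equal(attr(ex, "n_dropped"), 1L)
  expect_equal(attr(exclude_mirnas(ex), "n_dropped"), 0L)
  # two-order comparison: excluding a nonzero row changes every CPM value
  cpm_then_drop <- cpm(m)[rownames(ex), ]
  drop_then_cpm <- cpm(ex)
  expect_true(all(cpm_then_drop != drop_then_cpm))
})

test_that("CPM columns sum to 1e6, scale-invariantly", {
  m <- toy_counts()
  x <- cpm(m)
  expect_equal(unname(colSums(x)), rep(1e6, 3), tolerance = 1e-9)
  expect_equal(unname(cpm(m)[, 1]), c(10, 30, 60) / 100 * 1e6)
  expect_equal(cpm(2 * m), cpm(m))
  z <- m; z[, 2] <- 0
  expect_error(cpm(z), "s2")
})

test_that("median-of-ratios size factors behave on worked matrices", {
  set.seed(3)
  a <- rpois(5, 100) + 1
  m <- cbind(s1 = a, s2 = a)
  rownames(m) <- paste0("m", 1:5)
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(s1 = a, s2 = 2 * a)
  rownames(m2) <- paste0("m", 1:5)
  sf <- size_factors(m2)
  # ratios (1,2) normalized by their geometric mean sqrt(2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(exp(mean(log(sf))), 1)
  # permutation invariance
  perm <- m2[sample(5), ]
  expect_equal(size_factors(perm), sf)
  # all-zero-containing matrices need a positive reference row
  m3 <- m2; m3[, 1] <- 0
  expect_error(size_factors(m3), "all-positive")
})

test_that("size factors agree with DESeq2 on a toy matrix", {
  skip_if_not_installed("DESeq2")
  set.seed(8)
  # odd row count so the plain ratio-scale median and DESeq2's log-scale
  # median coincide without interpolation differences
  m <- matrix(rpois(66, 50) + 1, nrow = 11,
              dimnames = list(paste0("m", 1:11), paste0("s", 1:6)))
  ours <- size_factors(m)
  theirs <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-8)
})

test_that("detection sets recover generator truth and partition consistently", {
  pooled <- matrix(c(100, 20, 0,
                     40, 35, 10,
                     5, 50, 60), nrow = 3, byrow = TRUE,
                   dimnames = list(c("mA", "mB", "mC"),
                                   c("l1", "l2", "l3")))
  det <- detection_sets(pooled, detect_threshold = 30, units = "reads")
  expect_setequal(det$sets$l1, c("mA", "mB"))
  expect_setequal(det$sets$l2, c("mB", "mC"))
  expect_setequal(det$sets$l3, "mC")
  expect_equal(sum(det$venn$count[det$venn$section != "(none)"]), 3L)
  # threshold 0 detects all nonzero rows everywhere
  det0 <- detection_sets(pooled, detect_threshold = 1e-12, units = "reads")
  expect_setequal(det0$sets$l1, c("mA", "mB", "mC"))
})

test_that("per-line totals equal the sum of their Venn sections", {
  # partition cardinalities mirroring a 3-line detection analysis
  parts <- list(ABC = 74L, AB = 14L, AC = 31L, BC = 84L,
                A = 38L, B = 55L, C = 185L)
  sets <- sets_from_partition(parts)
  vp <- venn_partition(sets)
  tot <- function(g) sum(vp$count[vp[[g]]])
  expect_equal(tot("A"), 74L + 14L + 31L + 38L)
  expect_equal(tot("B"), 74L + 14L + 84L + 55L)
  expect_equal(tot("C"), 74L + 31L + 84L + 185L)
})

test_that("fold-change DEM calls honour the pseudo-count and symmetry", {
  pooled <- matrix(c(500, 100,
                     100, 100,
                     900, 100,
                     10, 300), nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("m", 1:4), c("la", "lb")))
  dem <- fold_change_dem(pooled, c("la", "lb"))
  # (500+1)/(100+1) = 4.9604 -> below the 5-fold cutoff
  expect_equal(dem$fold[1], 501 / 101)
  expect_false(dem$dem[1])
  expect_equal(dem$fold[2], 1)
  expect_false(dem$dem[2])
  expect_true(dem$dem[3])
  expect_equal(dem$direction[3], "up")
  expect_true(dem$dem[4])
  expect_equal(dem$direction[4], "down")
  # swapping the contrast inverts folds and flips directions
  rev <- fold_change_dem(pooled, c("lb", "la"))
  expect_equal(rev$fold, 1 / dem$fold)
  expect_equal(rev$dem, dem$dem)
  flip <- dem$fold != 1
  expect_equal(rev$direction[flip],
               ifelse(dem$direction[flip] == "up", "down", "up"))
})

test_that("top lists rank by total with shares summing to 100", {
  pooled <- matrix(c(100, 60, 0,
                     70, 40, 30,
                     30, 10, 5), nrow = 3, byrow = TRUE,
                   dimnames = list(c("mA", "mB", "mC"), c("l1", "l2", "l3")))
  top <- top_lists(pooled, min_reads = 150)
  expect_equal(top$mirna_id, "mA")  # totals 160, 140, 45 -> only 160 >= 150
  expect_equal(top$total, 160)
  shares <- as.matrix(top[, grep("^share_", names(top))])
  expect_equal(unname(rowSums(shares)), rep(100, nrow(top)),
               tolerance = 1e-9)
  # brute-force filter count at a second threshold
  expect_equal(nrow(top_lists(pooled, 50)), sum(rowSums(pooled) >= 50))
})

test_that("family aggregation totals, shares and dominance", {
  pooled <- matrix(c(50, 10,
                     30, 5,
                     20, 85), nrow = 3, byrow = TRUE,
                   dimnames = list(c("hsa-let-7a", "hsa-let-7c", "hsa-mir-9"),
                                   c("l1", "l2")))
  fam <- family_aggregate(pooled, "let-7")
  expect_setequal(fam$members, c("hsa-let-7a", "hsa-let-7c"))
  expect_equal(unname(fam$totals), c(80, 15))
  expect_equal(unname(fam$share_of_line), c(80, 15))
  expect_equal(unname(fam$dominant_member), c("hsa-let-7a", "hsa-let-7a"))
  single <- family_aggregate(pooled, "mir-9")
  expect_equal(unname(single$totals), unname(pooled["hsa-mir-9", ]))
  expect_true(all(fam$share_of_line >= 0 & fam$share_of_line <= 100))
  expect_warning(none <- family_aggregate(pooled, "mir-404"), "no rows")
  expect_length(none$members, 0L)
})

test_that("ddCt quantitation matches the closed form", {
  # treated dCt equals control dCt -> fold 1
  rec <- data.frame(target = "t1",
                    condition = rep(c("control", "treated"), each = 3),
                    target_ct = c(25, 25.1, 24.9, 24, 24.1, 23.9),
                    ref_ct = c(20, 20.1, 19.9, 19, 19.1, 18.9))
  out <- delta_delta_ct(rec)
  expect_equal(out$fold, 1)
  # ddCt = -1 -> fold 2
  rec2 <- rec
  rec2$target_ct[rec2$condition == "treated"] <-
    rec2$target_ct[rec2$condition == "treated"] - 1
  expect_equal(delta_delta_ct(rec2)$fold, 2)
  # ddCt = -0.585 -> fold ~1.5
  rec3 <- rec
  rec3$target_ct[rec3$condition == "treated"] <-
    rec3$target_ct[rec3$condition == "treated"] - 0.585
  expect_equal(delta_delta_ct(rec3)$fold, 2^0.585)
  expect_equal(delta_delta_ct(rec3)$fold, 1.5, tolerance = 0.01)
  # missing reference Ct is an error
  bad <- rec; bad$ref_ct[1] <- NA
  expect_error(delta_delta_ct(bad), "reference")
})
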