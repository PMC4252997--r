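small_cfg <- function(...) {
  cohortConfig(n_subjects = 6, habitats = "gut", n_weeks = 6, depth = 400,
               n_taxa = 120, n_controls = 2, seed = 7, ...)
}

test_that("generated trees are reproducible with the requested tips", {
  t1 <- generateTree(24, seed = 5)
  t2 <- generateTree(24, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(ape::Ntip(t1), 24)
  expect_identical(t1$tip.label[1], "OTU_0001")
  expect_true(all(t1$edge.length >= 0))
  t3 <- generateTree(24, seed = 6)
  expect_false(identical(ape::write.tree(t1), ape::write.tree(t3)))
})

test_that("cohorts are bit-reproducible and structurally sound", {
  co1 <- generateCohort(small_cfg())
  co2 <- generateCohort(small_cfg())
  expect_identical(counts(co1$table), counts(co2$table))
  expect_identical(co1$metadata, co2$metadata)
  expect_identical(ape::write.tree(co1$tree), ape::write.tree(co2$tree))

  # every sample sums to depth; every phylotype is a tree tip
  expect_true(all(rowSums(counts(co1$table)) == 400))
  expect_true(all(phylotypeIDs(co1$table) %in% co1$tree$tip.label))
  expect_equal(nrow(co1$metadata), 6 * 6)
  expect_setequal(co1$control_ids, c("control.1", "control.2"))
  expect_true(all(co1$control_ids %in% sampleIDs(co1$table)))
  expect_false(any(co1$control_ids %in% co1$metadata$sample_id))
  expect_equal(nrow(co1$truth$subjects), 6)
  expect_true(all(co1$truth$subjects$w >= 0.05 & co1$truth$subjects$w <= 0.6))
  v <- validObject(co1$table)
  expect_true(isTRUE(v) || is(v, "CountTable"))
})

test_that("controls carry the designated contaminants at high abundance", {
  co <- generateCohort(small_cfg())
  ctrl <- counts(co$table)[co$control_ids, , drop = FALSE]
  pooled <- colSums(ctrl) / sum(ctrl)
  expect_true(all(pooled[co$truth$contaminants] >= 0.01))
  removed <- suppressMessages(removeControlContaminants(
    co$table, co$control_ids, 0.005))$removed
  expect_true(all(co$truth$contaminants %in% removed))
})

test_that("turnover limits behave: persistence, transience, monotonicity", {
  # w = 0: support fixed; all phylotypes shared through time
  cfg0 <- cohortConfig(n_subjects = 6, habitats = "gut", n_weeks = 6,
                       depth = 3000, n_taxa = 120, n_controls = 2, seed = 7,
                       w_range = c(0, 0), transient_fraction = c(gut = 0),
                       antibiotic_events = NULL)
  co0 <- generateCohort(cfg0)
  ids <- co0$metadata$sample_id[co0$metadata$subject_id == "S01"]
  tal <- occupancyCounts(co0$table, ids)
  expect_equal(proportionShared(tal), 1.0)
  rec <- variabilityTable(
    co0$table[co0$metadata$sample_id, ], co0$tree,
    suppressMessages(selectTimeSeries(co0$metadata, 6)),
    alphaDiversity(co0$table[co0$metadata$sample_id, ], co0$tree))
  expect_lt(median(rec$median_weighted), 0.05)

  # w = 1 with room for no-return colonization: nothing is ever shared
  cfg1 <- cohortConfig(n_subjects = 2, habitats = "gut", n_weeks = 4,
                       depth = 400, n_taxa = 120, support_size = 20,
                       w_range = c(1, 1), transient_fraction = c(gut = 0),
                       antibiotic_events = NULL, n_controls = 0, seed = 8)
  co1 <- generateCohort(cfg1)
  ids1 <- co1$metadata$sample_id[co1$metadata$subject_id == "S01"]
  m <- counts(co1$table)[ids1, ]
  occ <- colSums(m > 0)
  expect_true(all(occ <= 1))
  expect_equal(proportionShared(occupancyCounts(co1$table, ids1)), 0)

  # expected median unweighted distance is non-decreasing in w
  med_at <- function(w, seed) {
    cfg <- cohortConfig(n_subjects = 4, habitats = "gut", n_weeks = 8,
                        depth = 600, n_taxa = 200,
                        w_range = rep(w, 4), transient_fraction = c(gut = 0),
                        antibiotic_events = NULL, n_controls = 0, seed = seed)
    co <- generateCohort(cfg)
    series <- suppressMessages(selectTimeSeries(co$metadata, 6))
    rec <- variabilityTable(co$table, co$tree, series,
                            alphaDiversity(co$table, co$tree))
    mean(rec$median_unweighted)
  }
  meds <- vapply(c(0.1, 0.3, 0.5), function(w)
    mean(vapply(1:3, function(s) med_at(w, s), 0)), 0)
  expect_true(all(diff(meds) > 0))
})

test_that("antibiotic events perturb the flagged week's community", {
  ev <- data.frame(subject_id = "S01", week = 3L, multiplier = 0.05)
  cfg <- small_cfg(antibiotic_events = ev, w_range = c(0.05, 0.05))
  co <- generateCohort(cfg)
  expect_true(all(
    co$metadata$antibiotic_this_week[co$metadata$subject_id == "S01" &
                                     co$metadata$week == 3]))
  expect_false(any(
    co$metadata$antibiotic_this_week[co$metadata$subject_id != "S01"]))
  sub <- co$metadata[co$metadata$subject_id == "S01", ]
  sub <- sub[order(sub$week), ]
  dm <- as.matrix(pairwiseDistances(co$table[sub$sample_id, ], co$tree,
                                    "weighted_normalized"))
  jump <- dm[sub$sample_id[sub$week == 2], sub$sample_id[sub$week == 3]]
  calm <- dm[sub$sample_id[sub$week == 0], sub$sample_id[sub$week == 1]]
  expect_gt(jump, calm)
})

test_that("planted covariates carry the configured effect; nulls do not", {
  truth <- data.frame(subject_id = sprintf("S%02d", 1:60),
                      w = runif(60, 0.05, 0.6))
  cov0 <- generateCovariates(truth, effect_size = 0, seed = 3)
  expect_lt(abs(cor(cov0$planted, truth$w)), 0.3)
  r2 <- vapply(1:30, function(s) {
    cv <- generateCovariates(truth, effect_size = 0.3, seed = s)
    summary(lm(cv$planted ~ truth$w))$r.squared
  }, 0)
  expect_equal(mean(r2), 0.3, tolerance = 0.1)
  nulls <- vapply(1:30, function(s) {
    cv <- generateCovariates(truth, effect_size = 0.3, seed = s + 100)
    abs(cor(cv$null_01, truth$w, method = "spearman"))
  }, 0)
  expect_gt(mean(nulls < 0.3), 0.9)
})
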