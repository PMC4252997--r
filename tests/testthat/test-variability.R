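dm_from <- function(m, labels) {
  dimnames(m) <- list(labels, labels)
  DistanceMatrix(m, "unweighted")
}

test_that("median intra-individual distance covers all pairs", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.2
  m[1, 3] <- m[3, 1] <- 0.9
  m[2, 3] <- m[3, 2] <- 0.4
  dm <- dm_from(m, c("a", "b", "c"))
  res <- medianIntraIndividualDistance(dm, c("a", "b", "c"))
  expect_equal(res$median, 0.4)
  expect_equal(res$n_pairs, 3L)
  # invariant to sample ordering
  expect_equal(medianIntraIndividualDistance(dm, c("c", "a", "b"))$median, 0.4)
  # constant distances give that constant
  cm <- matrix(0.3, 4, 4); diag(cm) <- 0
  expect_equal(medianIntraIndividualDistance(
    dm_from(cm, letters[1:4]), letters[1:4])$median, 0.3)
  expect_error(medianIntraIndividualDistance(dm, c("a", "zz")), "missing")

  set.seed(41)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- runif(choose(n, 2))
    m <- m + t(m)
    dm <- dm_from(m, paste0("s", 1:n))
    res <- medianIntraIndividualDistance(dm, paste0("s", 1:n))
    expect_equal(res$median, median(sort(m[upper.tri(m)])))  # sort oracle
    expect_equal(res$n_pairs, choose(n, 2))
  }
})

test_that("stability classes split habitats at the quartiles", {
  rec <- data.frame(subject_id = sprintf("S%02d", 1:8), habitat = "gut",
                    median_weighted = (1:8) / 10,
                    median_unweighted = (8:1) / 10)
  out <- assignStabilityClasses(rec, basis = "median_weighted")
  expect_equal(sum(out$stability_class == "stable"), 2)
  expect_equal(sum(out$stability_class == "average"), 4)
  expect_equal(sum(out$stability_class == "variable"), 2)
  expect_equal(out$stability_class[1:2], c("stable", "stable"))
  expect_equal(out$stability_class[7:8], c("variable", "variable"))

  # degenerate spread: everyone is average
  rec$median_weighted <- 0.5
  expect_true(all(assignStabilityClasses(rec)$stability_class == "average"))

  expect_error(assignStabilityClasses(rec[1:3, ]), "fewer than 4")

  set.seed(42)
  rec <- data.frame(subject_id = sprintf("S%04d", 1:1000), habitat = "palm",
                    median_weighted = runif(1000),
                    median_unweighted = runif(1000))
  cls <- table(assignStabilityClasses(rec)$stability_class)
  expect_equal(unname(cls[["stable"]]) / 1000, 0.25, tolerance = 0.01)
  expect_equal(unname(cls[["average"]]) / 1000, 0.50, tolerance = 0.01)
  expect_equal(unname(cls[["variable"]]) / 1000, 0.25, tolerance = 0.01)
})

test_that("cross-habitat correlation matches the Spearman formula", {
  rec <- rbind(
    data.frame(subject_id = sprintf("S%d", 1:6), habitat = "gut",
               median_unweighted = c(.1, .2, .3, .4, .5, .6)),
    data.frame(subject_id = sprintf("S%d", 1:6), habitat = "palm",
               median_unweighted = c(.15, .25, .35, .45, .55, .65)))
  res <- crossHabitatCorrelation(rec, c("gut", "palm"))
  expect_equal(res$rho, 1)
  rec$median_unweighted[rec$habitat == "palm"] <- rev(c(.15, .25, .35, .45, .55, .65))
  expect_equal(crossHabitatCorrelation(rec, c("gut", "palm"))$rho, -1)
  # hand Spearman on small vectors
  x <- c(3, 1, 4, 1.5, 9); y <- c(2.7, 1.8, 2.8, 1.2, 9.9)
  rec2 <- rbind(
    data.frame(subject_id = paste0("T", 1:5), habitat = "gut",
               median_unweighted = x),
    data.frame(subject_id = paste0("T", 1:5), habitat = "tongue",
               median_unweighted = y))
  expect_equal(crossHabitatCorrelation(rec2, c("gut", "tongue"))$rho,
               cor(rank(x), rank(y)))
  expect_error(crossHabitatCorrelation(rec2[-1, ], c("gut", "tongue")),
               "fewer than 5")
})

test_that("time-decay Mantel recovers perfect monotone decay", {
  # irregular weeks so no non-identity permutation preserves the time matrix
  weeks <- c(0, 1, 3, 4, 7, 8, 10, 11)
  ids <- paste0("s", weeks)
  m <- abs(outer(weeks, weeks, "-")) / 20
  dm <- dm_from(m, ids)
  series <- seriesMeta(ids, weeks)
  res <- timeDecayMantel(dm, series, n_permutations = 199, seed = 1)
  expect_equal(res$rho, 1)
  expect_equal(res$p_value, 1 / 200)  # the permutation lower bound
  expect_false(res$degenerate)

  cm <- matrix(0.4, 8, 8); diag(cm) <- 0
  res2 <- timeDecayMantel(dm_from(cm, ids), series, 99, seed = 1)
  expect_true(res2$degenerate)
  expect_error(timeDecayMantel(dm, series[1:3, ], 99, 1), "at least 4")
})

test_that("Mantel Monte Carlo p matches exhaustive enumeration on 4 samples", {
  set.seed(43)
  weeks <- c(0, 2, 3, 7)
  ids <- paste0("s", 1:4)
  m <- matrix(0, 4, 4)
  m[upper.tri(m)] <- runif(6)
  m <- m + t(m)
  dm <- dm_from(m, ids)
  timed <- abs(outer(weeks, weeks, "-"))
  rho_of <- function(perm) {
    mp <- m[perm, perm]
    suppressWarnings(cor(mp[upper.tri(mp)], timed[upper.tri(timed)],
                         method = "spearman"))
  }
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  obs <- rho_of(1:4)
  p_exact <- mean(apply(perms, 1, rho_of) >= obs - 1e-12)
  res <- timeDecayMantel(dm, seriesMeta(ids, weeks), 999, seed = 7)
  expect_equal(res$rho, obs, tolerance = 1e-10)
  se <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 1 / 999)
})

test_that("diversity-stability model finds exact linear relationships", {
  rec <- data.frame(subject_id = sprintf("S%d", 1:6), habitat = "gut",
                    median_shannon = 1:6,
                    median_weighted = seq(0.9, 0.4, by = -0.1),
                    median_unweighted = seq(0.8, 0.3, by = -0.1))
  res <- diversityStabilityModel(rec, "gut", "median_weighted")
  expect_equal(res$slope, -0.1)
  expect_equal(res$rho, -1)
  expect_lt(res$p_value, 0.01)
  rec$median_shannon <- 2
  expect_error(diversityStabilityModel(rec, "gut"), "constant")
  expect_error(diversityStabilityModel(rec[1:4, ], "gut"), "fewer than 5")
})
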