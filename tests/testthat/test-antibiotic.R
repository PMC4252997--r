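adw_fixture <- function(distances, weeks = NULL, abx = NULL,
                        subject = "S01") {
  n <- length(distances) + 1
  if (is.null(weeks)) weeks <- seq_len(n) - 1
  ids <- sprintf("%s.s%d", subject, seq_len(n))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_along(distances)) {
    m[i, i + 1] <- m[i + 1, i] <- distances[i]
  }
  # fill remaining pairs so the matrix is a valid distance table
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (m[i, j] == 0 && j > i + 1) m[i, j] <- m[j, i] <- max(distances) + 1
  dm <- DistanceMatrix(m, "unweighted")
  series <- seriesMeta(ids, weeks, subject = subject, abx = abx)
  adjacentWeekDistances(dm, series)
}

test_that("adjacent-week intervals, flags and ranks follow the conventions", {
  adw <- adw_fixture(c(0.1, 0.5, 0.3), abx = c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(nrow(adw), 3)              # 4-week series -> 3 intervals
  expect_equal(adw$within_subject_rank, c(1, 3, 2))
  # either-endpoint rule: week 2 flagged -> intervals (1,2) and (2,3)
  expect_equal(adw$antibiotic_interval, c(FALSE, TRUE, TRUE))

  tied <- adw_fixture(c(0.2, 0.2, 0.9))
  expect_equal(tied$within_subject_rank, c(1.5, 1.5, 3))
  # unreported flags count as no use
  expect_false(any(adw_fixture(c(.1, .2))$antibiotic_interval))
})

test_that("Monte Carlo rank test tracks the exhaustive permutation null", {
  # 5 ranks, antibiotic group = the two largest -> exact p = 1/10
  adw <- adw_fixture(c(.1, .2, .3, .8, .9),
                     abx = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(adw$antibiotic_interval, c(rep(FALSE, 3), TRUE, TRUE))
  res <- monteCarloRankTest(adw, n_iterations = 2000, seed = 1)
  p_exact <- exhaustiveRankP(adw$within_subject_rank, adw$antibiotic_interval)
  expect_equal(p_exact, 0.1)
  se <- sqrt(p_exact * (1 - p_exact) / 2000)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 1 / 2000)

  # random small instances vs exhaustive enumeration
  set.seed(71)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    d <- runif(n)
    abx_week <- rep(FALSE, n + 1)
    abx_week[sample(2:n, sample(1:2, 1))] <- TRUE
    adw <- adw_fixture(d, abx = abx_week)
    if (!any(adw$antibiotic_interval) || all(adw$antibiotic_interval)) next
    res <- monteCarloRankTest(adw, n_iterations = 1500, seed = i)
    p_exact <- exhaustiveRankP(adw$within_subject_rank,
                               adw$antibiotic_interval)
    se <- sqrt(p_exact * (1 - p_exact) / 1500)
    expect_lt(abs(res$p_value - p_exact), 3 * se + 1 / 1500)
  }
})

test_that("the rank test is one-tailed and rank-based", {
  # antibiotic ranks all smaller than the rest: wrong direction, p near 1
  adw <- adw_fixture(c(.9, .8, .1, .2, .7),
                     abx = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
  res <- monteCarloRankTest(adw, 500, seed = 2)
  expect_gt(res$p_value, 0.8)
  # invariance to monotone transforms of the distances
  adw2 <- adw_fixture(exp(c(.9, .8, .1, .2, .7)),
                      abx = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
  res2 <- monteCarloRankTest(adw2, 500, seed = 2)
  expect_identical(res$p_value, res2$p_value)
  expect_identical(res$t, res2$t)
  # reproducible under a fixed seed
  expect_identical(monteCarloRankTest(adw, 500, seed = 9)$p_value,
                   monteCarloRankTest(adw, 500, seed = 9)$p_value)
  all_abx <- adw
  all_abx$antibiotic_interval <- TRUE
  expect_error(monteCarloRankTest(all_abx, 100, 1),
               "both antibiotic and non-antibiotic")
})

test_that("population-level test matches the exact Mann-Whitney", {
  rec <- data.frame(
    subject_id = sprintf("S%d", 1:6), habitat = "gut",
    median_unweighted = c(.72, .75, .71, .42, .45, .41),
    median_weighted = c(.32, .35, .31, .22, .25, .21),
    antibiotic_user = rep(c(TRUE, FALSE), each = 3))
  res <- populationAntibioticTest(rec, "gut")
  expect_equal(nrow(res), 2)
  ref <- wilcox.test(rec$median_unweighted[1:3], rec$median_unweighted[4:6],
                     exact = FALSE)
  row_u <- res[res$basis == "median_unweighted", ]
  expect_equal(row_u$U, unname(ref$statistic))
  expect_equal(row_u$p_value, ref$p.value)
  expect_false(any(res$flagged))

  # a too-small group yields a flagged row, not an error
  rec2 <- rec; rec2$antibiotic_user <- c(TRUE, rep(FALSE, 5))
  res2 <- populationAntibioticTest(rec2, "gut")
  expect_true(all(res2$flagged))
  expect_true(all(is.na(res2$p_value)))
})
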