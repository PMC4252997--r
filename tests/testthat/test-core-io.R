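test_that("CountTable enforces its invariants", {
  m <- matrix(c(3L, 1L, 0L, 2L), 2, 2,
              dimnames = list(c("s1", "s2"), c("A", "B")))
  ct <- CountTable(m)
  expect_identical(counts(ct), m)
  expect_identical(sampleIDs(ct), c("s1", "s2"))
  expect_identical(phylotypeIDs(ct), c("A", "B"))

  bad <- m; bad[1, 1] <- -1L
  expect_error(CountTable(bad), "negative")
  dup <- m; rownames(dup) <- c("s1", "s1")
  expect_error(CountTable(dup), "duplicated sample")
  expect_error(CountTable(m, c(Z = "k__X")), "subset")
})

test_that("DistanceMatrix enforces symmetry, zero diagonal and labels", {
  v <- matrix(c(0, 0.2, 0.2, 0), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  dm <- DistanceMatrix(v, "unweighted")
  expect_equal(as.matrix(dm), v)
  expect_identical(metricName(dm), "unweighted")

  asym <- v; asym[1, 2] <- 0.3
  expect_error(DistanceMatrix(asym), "symmetric")
  nd <- v; diag(nd) <- 0.1
  expect_error(DistanceMatrix(nd), "diagonal")
})

test_that("classic count-table files round-trip, errors are structured", {
  ct <- CountTable(matrix(c(3L, 1L, 0L, 2L), 2, 2,
                          dimnames = list(c("s1", "s2"), c("A", "B"))))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCountTable(ct, f)
  back <- suppressMessages(readCountTable(f))
  expect_identical(counts(back), counts(ct))

  set.seed(42)
  for (i in 1:50) {
    ct <- randomCountTable(sample(2:6, 1), sample(2:9, 1),
                           with_tax = i %% 2 == 0)
    writeCountTable(ct, f)
    back <- suppressMessages(readCountTable(f))
    expect_identical(counts(back), counts(ct))
    expect_identical(taxonomy(back), taxonomy(ct))
  }

  writeLines(c("#OTU ID\ts1\ts1", "A\t1\t2"), f)
  expect_error(suppressMessages(readCountTable(f)), "duplicated sample ID.*s1")
  writeLines(c("#OTU ID\ts1\ts2", "A\t1\t2", "A\t3\t4"), f)
  expect_error(suppressMessages(readCountTable(f)), "duplicated phylotype ID.*A")
  writeLines(c("#OTU ID\ts1\ts2", "A\t1.5\t2"), f)
  expect_error(suppressMessages(readCountTable(f)), "non-integral.*'A'.*'s1'")
  writeLines(c("#OTU ID\ts1\ts2", "A\t-1\t2"), f)
  expect_error(suppressMessages(readCountTable(f)), "negative")
})

test_that("newick trees round-trip with topology and lengths intact", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):0.5,(C:1,D:1):0.5):0;", f)
  tr <- readTree(f)
  expect_equal(ape::Ntip(tr), 4)
  expect_equal(sum(tr$edge.length), 5.0)

  writeLines("(A:1);", f)
  expect_equal(ape::Ntip(readTree(f)), 1)

  set.seed(7)
  tr <- randomTree(64, labels = sprintf("OTU_%03d", 1:64))
  writeTree(tr, f)
  back <- readTree(f)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  # same topology: identical splits and matching lengths via cophenetic dist
  expect_equal(ape::cophenetic.phylo(back)[tr$tip.label, tr$tip.label],
               ape::cophenetic.phylo(tr), tolerance = 1e-12)
})

test_that("metadata reader validates vocabulary, weeks and uniqueness", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = c("a", "b", "c"), subject_id = "S01",
                   habitat = c("gut", "palm", "tongue"), week = 0:2,
                   bmi = c(21.2, NA, 23.0))
  writeSampleMetadata(df, f)
  back <- readSampleMetadata(f)
  expect_equal(nrow(back), 3)
  expect_identical(back$week, 0:2)
  expect_true(is.na(back$bmi[2]))

  df2 <- df; df2$habitat[1] <- "armpit"
  writeSampleMetadata(df2, f)
  expect_error(readSampleMetadata(f), "armpit.*forehead, gut, palm, tongue")

  df3 <- df; df3$week[2] <- -1
  writeSampleMetadata(df3, f)
  expect_error(readSampleMetadata(f), "non-negative")

  df4 <- df; df4$habitat <- "gut"; df4$week <- c(0L, 0L, 1L)
  writeSampleMetadata(df4, f)
  expect_error(readSampleMetadata(f), "duplicate \\(subject, habitat, week\\)")
})

test_that("distance matrices and TSV outputs round-trip", {
  v <- matrix(c(0, .1, .2, .1, 0, .3, .2, .3, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  dm <- DistanceMatrix(v, "weighted_normalized")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeDistanceMatrix(dm, f)
  back <- readDistanceMatrix(f, "weighted_normalized")
  expect_equal(as.matrix(back), v)

  df <- data.frame(a = 1:3, b = c("x", "y", "z"))
  writeTSV(df, f, config = list(seed = 1))
  expect_match(readLines(f)[1], "^# MicrobiomeStability .* config=")
  expect_equal(readTSV(f), df)
})
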