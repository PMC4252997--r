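# Independent brute-force oracles and random-instance builders. These share
# no code with the package internals: trees are walked by naive recursion on
# the edge table.

# Tip labels descending from each edge's child node.
oracleTipSets <- function(tree) {
  ntip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  desc <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(children[[as.character(node)]], desc), use.names = FALSE)
  }
  lapply(seq_len(nrow(tree$edge)), function(e) desc(tree$edge[e, 2]))
}

# Branch-by-branch UniFrac evaluated from explicit descendant tip sets.
oracleUnifrac <- function(a, b, tree, metric) {
  sets <- oracleTipSets(tree)
  len <- tree$edge.length
  ta <- sum(a); tb <- sum(b)
  num <- den <- 0
  for (e in seq_along(sets)) {
    ca <- sum(a[names(a) %in% sets[[e]]])
    cb <- sum(b[names(b) %in% sets[[e]]])
    if (metric == "unweighted") {
      pa <- ca > 0; pb <- cb > 0
      if (pa || pb) den <- den + len[e]
      if (xor(pa, pb)) num <- num + len[e]
    } else {
      num <- num + len[e] * abs(ca / ta - cb / tb)
      den <- den + len[e] * (ca / ta + cb / tb)
    }
  }
  if (metric == "weighted") return(num)
  if (den == 0) 0 else num / den
}

# Faith's PD as the union of tip-to-root edge paths, summed explicitly.
oraclePD <- function(x, tree) {
  observed <- names(x)[x > 0]
  ntip <- length(tree$tip.label)
  used <- rep(FALSE, nrow(tree$edge))
  for (tip in observed) {
    node <- match(tip, tree$tip.label)
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (length(e) == 0) break
      used[e] <- TRUE
      node <- tree$edge[e, 1]
    }
  }
  sum(tree$edge.length[used])
}

# Random rooted tree with uniform branch lengths, tips t1..tn.
randomTree <- function(n_tips, labels = paste0("t", seq_len(n_tips))) {
  tree <- ape::rtree(n_tips, rooted = TRUE)
  tree$edge.length <- runif(nrow(tree$edge), 0.1, 2)
  tree$tip.label <- labels
  tree
}

# Random non-empty named count vector over the tree's tips.
randomCounts <- function(tree, max_count = 20) {
  n <- length(tree$tip.label)
  x <- rpois(n, 2)
  x[sample.int(n, ceiling(n / 2))] <- 0
  if (sum(x) == 0) x[sample.int(n, 1)] <- max_count
  names(x) <- tree$tip.label
  x
}

# Random CountTable for IO / preprocessing round trips.
randomCountTable <- function(n_samples = 5, n_taxa = 8, with_tax = FALSE) {
  m <- matrix(rpois(n_samples * n_taxa, 5), n_samples, n_taxa,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("OTU_%03d", seq_len(n_taxa))))
  tax <- character(0)
  if (with_tax)
    tax <- setNames(sprintf(
      "k__Bacteria;p__P%d;c__C%d;o__O%d;f__Fam%d;g__;s__",
      seq_len(n_taxa) %% 3, seq_len(n_taxa) %% 3, seq_len(n_taxa) %% 3,
      seq_len(n_taxa) %% 3), colnames(m))
  CountTable(m, tax)
}

# One-habitat metadata for a single subject time series.
seriesMeta <- function(sample_ids, weeks, subject = "S01", habitat = "gut",
                       abx = NULL) {
  df <- data.frame(sample_id = sample_ids, subject_id = subject,
                   habitat = habitat, week = as.integer(weeks),
                   stringsAsFactors = FALSE)
  if (!is.null(abx)) df$antibiotic_this_week <- abx
  df
}

# Exhaustive one-tailed permutation p for the rank t-test: all ways of
# labelling n_abx of the ranks as antibiotic, Welch t, P(t_perm >= t_obs).
exhaustiveRankP <- function(ranks, labels) {
  tstat <- function(x, y) {
    nx <- length(x); ny <- length(y)
    den <- if (nx < 2 || ny < 2) {
      sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2)
      sqrt(sp2 * (1 / nx + 1 / ny))
    } else sqrt(var(x) / nx + var(y) / ny)
    if (den == 0) 0 else (mean(x) - mean(y)) / den
  }
  obs <- tstat(ranks[labels], ranks[!labels])
  combos <- combn(length(ranks), sum(labels))
  ts <- apply(combos, 2, function(idx) {
    g <- seq_along(ranks) %in% idx
    tstat(ranks[g], ranks[!g])
  })
  mean(ts >= obs - 1e-12)
}
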