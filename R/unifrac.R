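# Align two named count vectors into a 2 x taxa matrix over the union of IDs.
pairMatrix <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b)))
    stop("count vectors must be named by phylotype ID")
  ids <- union(names(a), names(b))
  m <- rbind(a = a[match(ids, names(a))], b = b[match(ids, names(b))])
  m[is.na(m)] <- 0
  colnames(m) <- ids
  m
}

# Branch-wise distance between two columns of a branchTotals() result.
unifracFromTotals <- function(bt, i, j, metric) {
  len <- bt$lengths
  switch(metric,
    unweighted = {
      pa <- bt$totals[, i] > 0
      pb <- bt$totals[, j] > 0
      denom <- sum(len[pa | pb])
      if (denom == 0) return(0)
      sum(len[xor(pa, pb)]) / denom
    },
    weighted = ,
    weighted_normalized = {
      wa <- bt$totals[, i] / bt$sample_totals[i]
      wb <- bt$totals[, j] / bt$sample_totals[j]
      raw <- sum(len * abs(wa - wb))
      if (metric == "weighted") return(raw)
      denom <- sum(len * (wa + wb))
      if (denom == 0) 0 else raw / denom
    },
    stop("unknown metric: ", metric)
  )
}

#' Unweighted UniFrac distance between two communities
#'
#' Fraction of branch length unique to exactly one of the two samples'
#' descendant-presence sets, over the branch length present in either.
#' Depends only on presence/absence.
#'
#' @param a,b non-negative count vectors named by phylotype ID, each with
#'   positive total; observed phylotypes must be tips of `tree`.
#' @param tree rooted [ape::phylo] with branch lengths.
#' @return distance in `[0, 1]`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' unweightedUnifrac(c(A = 5), c(A = 1, B = 1), tr)  # 1/3
#' @export
unweightedUnifrac <- function(a, b, tree) {
  if (sum(a) <= 0 || sum(b) <= 0) stop("both samples must be non-empty")
  bt <- branchTotals(pairMatrix(a, b), tree)
  unifracFromTotals(bt, 1, 2, "unweighted")
}

#' Weighted UniFrac distance between two communities
#'
#' Sum over branches of branch length times the absolute difference in the
#' fraction of each sample's reads descending through the branch. The
#' normalized variant divides by `sum(length * (p_a + p_b))`, bounding the
#' distance in `[0, 1]`.
#'
#' @inheritParams unweightedUnifrac
#' @param normalized return the normalized (bounded) variant; default TRUE.
#' @return distance (>= 0; in `[0, 1]` when normalized).
#' @export
weightedUnifrac <- function(a, b, tree, normalized = TRUE) {
  if (sum(a) <= 0 || sum(b) <= 0) stop("both samples must be non-empty")
  bt <- branchTotals(pairMatrix(a, b), tree)
  unifracFromTotals(bt, 1, 2,
                    if (normalized) "weighted_normalized" else "weighted")
}

#' All pairwise UniFrac distances for a count table
#'
#' Computes the branch-wise descendant totals once with a single shared tree
#' traversal, then evaluates every sample pair from them.
#'
#' @param table a [CountTable-class]; every sample must have reads.
#' @param tree rooted [ape::phylo] covering all observed phylotypes.
#' @param metric one of `"unweighted"`, `"weighted_normalized"`, `"weighted"`.
#' @return a [DistanceMatrix-class] over the table's samples.
#' @export
pairwiseDistances <- function(table, tree,
                              metric = c("unweighted", "weighted_normalized",
                                         "weighted")) {
  metric <- match.arg(metric)
  m <- counts(table)
  if (any(rowSums(m) <= 0))
    stop("empty samples: ",
         paste(rownames(m)[rowSums(m) <= 0], collapse = ", "))
  bt <- branchTotals(m, tree)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d[i, j] <- d[j, i] <- unifracFromTotals(bt, i, j, metric)
      }
    }
  }
  DistanceMatrix(d, metric)
}
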