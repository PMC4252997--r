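#' @importFrom stats sd median quantile
NULL

#' Shannon diversity index
#'
#' Shannon entropy of the count composition, in bits (log base 2, the QIIME
#' 1.x convention) by default.
#'
#' @param x non-negative count vector with positive total.
#' @param base logarithm base (2 for bits, `exp(1)` for nats).
#' @return Shannon index; 0 for a single-taxon sample.
#' @examples
#' shannonIndex(c(5, 5, 5, 5))  # log2(4) = 2
#' @export
shannonIndex <- function(x, base = 2) {
  if (any(x < 0)) stop("negative counts")
  tot <- sum(x)
  if (tot <= 0) stop("all-zero count vector")
  p <- x[x > 0] / tot
  -sum(p * log(p, base = base))
}

#' Phylotype richness
#'
#' @param x non-negative count vector.
#' @return number of phylotypes with count > 0.
#' @export
phylotypeRichness <- function(x) {
  if (any(x < 0)) stop("negative counts")
  sum(x > 0)
}

# Branch-wise descendant totals for a set of samples.
#
# m: samples x phylotypes count matrix whose observed columns are tree tips.
# Returns per-branch lengths and a branches x samples matrix of total counts
# descending through each branch (the root edge, if any, is appended last).
branchTotals <- function(m, tree) {
  tips <- tree$tip.label
  observed <- colnames(m)[colSums(m) > 0]
  missing <- setdiff(observed, tips)
  if (length(missing))
    stop("phylotypes absent from tree: ", paste(missing, collapse = ", "))
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tips)
  node_tot <- matrix(0, ntip + tr$Nnode, nrow(m))
  idx <- match(tips, colnames(m))
  have <- which(!is.na(idx))
  if (length(have))
    node_tot[have, ] <- t(m[, idx[have], drop = FALSE])
  for (e in seq_len(nrow(tr$edge))) {
    node_tot[tr$edge[e, 1], ] <-
      node_tot[tr$edge[e, 1], ] + node_tot[tr$edge[e, 2], ]
  }
  lengths <- tr$edge.length
  totals <- node_tot[tr$edge[, 2], , drop = FALSE]
  if (!is.null(tr$root.edge) && tr$root.edge > 0) {
    lengths <- c(lengths, tr$root.edge)
    totals <- rbind(totals, node_tot[ntip + 1, ])
  }
  list(lengths = lengths, totals = totals, sample_totals = rowSums(m))
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal rooted subtree connecting all observed
#' tips to the root (root-inclusive, the QIIME 1.x behaviour).
#'
#' @param x non-negative count vector named by phylotype ID.
#' @param tree rooted [ape::phylo] whose tips cover the observed phylotypes.
#' @return PD in branch-length units.
#' @export
faithPD <- function(x, tree) {
  if (is.null(names(x))) stop("count vector must be named by phylotype ID")
  if (sum(x) <= 0) stop("all-zero count vector")
  bt <- branchTotals(matrix(x, 1, dimnames = list("s", names(x))), tree)
  sum(bt$lengths[bt$totals[, 1] > 0])
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean; the
#' per-individual instability score for alpha diversity.
#'
#' @param x numeric vector, length >= 2, positive mean.
#' @return CV (dimensionless, scale-invariant).
#' @export
coefVariation <- function(x) {
  if (length(x) < 2) stop("need at least 2 values")
  m <- mean(x)
  if (m <= 0) stop("CV undefined for non-positive mean")
  sd(x) / m
}

#' Alpha diversity table for every sample
#'
#' Computes Faith's PD, phylotype richness and the Shannon index for each
#' sample of a count table.
#'
#' @param table a [CountTable-class].
#' @param tree rooted [ape::phylo] covering all observed phylotypes.
#' @param shannon_base logarithm base for the Shannon index.
#' @return data.frame with columns `sample_id`, `PD`, `richness`, `shannon`.
#' @export
alphaDiversity <- function(table, tree, shannon_base = 2) {
  m <- counts(table)
  bt <- branchTotals(m, tree)
  pd <- colSums(bt$lengths * (bt$totals > 0))
  data.frame(
    sample_id = rownames(m),
    PD = pd,
    richness = apply(m, 1, phylotypeRichness),
    shannon = apply(m, 1, shannonIndex, base = shannon_base),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Per-individual CV of alpha diversity
#'
#' For each selected (subject, habitat) series, the coefficient of variation
#' of each alpha metric over the subject's time-ordered samples.
#'
#' @param alpha alpha table from [alphaDiversity()].
#' @param series series list from [selectTimeSeries()].
#' @return data.frame with one row per series: `subject_id`, `habitat`,
#'   `cv_pd`, `cv_richness`, `cv_shannon`, `n_samples`.
#' @export
alphaCVPerIndividual <- function(alpha, series) {
  rows <- lapply(series, function(g) {
    idx <- match(g$sample_id, alpha$sample_id)
    if (anyNA(idx))
      stop("samples missing from alpha table: ",
           paste(g$sample_id[is.na(idx)], collapse = ", "))
    a <- alpha[idx, , drop = FALSE]
    data.frame(
      subject_id = g$subject_id[1], habitat = g$habitat[1],
      cv_pd = coefVariation(a$PD),
      cv_richness = coefVariation(a$richness),
      cv_shannon = coefVariation(a$shannon),
      n_samples = nrow(g), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}
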