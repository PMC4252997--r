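#' @importFrom stats kruskal.test p.adjust pairwise.wilcox.test wilcox.test
NULL

# First five ranks (kingdom..family) of a lineage string, or
# "f__unclassified" when the family rank is empty or absent.
familyOf <- function(lineage) {
  ranks <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  if (length(ranks) < 5 || !nzchar(sub("^f__", "", ranks[5])))
    return("f__unclassified")
  paste(ranks[1:5], collapse = ";")
}

#' Collapse a count table to bacterial families
#'
#' Sums counts over phylotypes sharing the first five lineage ranks
#' (kingdom through family). Phylotypes with no taxonomy or an empty family
#' rank are pooled into `f__unclassified`. Column totals are conserved.
#'
#' @param table a [CountTable-class] with taxonomy for at least one phylotype.
#' @return a [CountTable-class] whose columns are family-level lineages.
#' @export
collapseToFamily <- function(table) {
  tx <- taxonomy(table)
  if (length(tx) == 0) stop("count table carries no taxonomy")
  m <- counts(table)
  fam <- rep("f__unclassified", ncol(m))
  names(fam) <- colnames(m)
  fam[names(tx)] <- vapply(tx, familyOf, "")
  groups <- split(seq_len(ncol(m)), fam)
  out <- vapply(groups, function(idx) rowSums(m[, idx, drop = FALSE]),
                numeric(nrow(m)))
  if (nrow(m) == 1) out <- matrix(out, 1, dimnames = list(rownames(m), names(groups)))
  CountTable(out)
}

#' Per-subject mean relative family abundance
#'
#' Each subject contributes one observation per family: the mean of its
#' weekly relative abundances over the subject's series (avoiding
#' pseudo-replication of weekly samples).
#'
#' @param family_table family-level [CountTable-class] from
#'   [collapseToFamily()].
#' @param series series list from [selectTimeSeries()] (one habitat).
#' @return matrix subjects x families of mean relative abundances.
#' @export
subjectFamilyAbundance <- function(family_table, series) {
  m <- counts(family_table)
  rel <- m / rowSums(m)
  t(vapply(series, function(g) {
    colMeans(rel[g$sample_id, , drop = FALSE])
  }, numeric(ncol(m))))
}

#' Family enrichment across stability classes
#'
#' Keeps families whose class-mean relative abundance exceeds
#' `min_abundance` (default 1%) in any class, rank-transforms abundances
#' across subjects, runs a Kruskal-Wallis test across the stability classes
#' for each family, and corrects p values across families
#' (Benjamini-Hochberg by default; `"bonferroni"` available).
#'
#' @param abundance subjects x families matrix from
#'   [subjectFamilyAbundance()].
#' @param classes stability class per subject (same order as rows).
#' @param min_abundance class-mean abundance threshold (fraction).
#' @param correction `"BH"` (default) or `"bonferroni"`.
#' @return data.frame with one row per tested family: mean abundance per
#'   class, the KW statistic, raw and corrected p, and significance flags at
#'   corrected p <= 0.05 and <= 0.01.
#' @export
classEnrichment <- function(abundance, classes, min_abundance = 0.01,
                            correction = c("BH", "bonferroni")) {
  correction <- match.arg(correction)
  classes <- as.factor(classes)
  if (nlevels(droplevels(classes)) < 2) stop("need at least 2 non-empty classes")
  if (any(table(classes) < 2)) stop("every class needs at least 2 subjects")
  class_means <- apply(abundance, 2, function(a) tapply(a, classes, mean))
  keep <- colnames(abundance)[apply(class_means, 2, max) > min_abundance]
  if (length(keep) == 0)
    return(data.frame(family = character(0)))
  rows <- lapply(keep, function(f) {
    r <- rank(abundance[, f])
    kw <- kruskal.test(r, classes)
    cm <- class_means[, f]
    out <- data.frame(family = f, statistic = unname(kw$statistic),
                      p_raw = kw$p.value, stringsAsFactors = FALSE)
    for (cl in levels(classes)) out[[paste0("mean_", cl)]] <- unname(cm[cl])
    out
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  res$p_corrected <- p.adjust(res$p_raw, method = correction)
  res$significant_05 <- res$p_corrected <= 0.05
  res$significant_01 <- res$p_corrected <= 0.01
  res[order(res$p_corrected, res$family), , drop = FALSE]
}

#' Cross-habitat comparison of alpha-diversity variability
#'
#' For each alpha metric's CV, a Kruskal-Wallis test across body habitats
#' plus all pairwise two-sided Mann-Whitney U tests with the same
#' multiple-testing correction.
#'
#' @param cv_records data.frame from [alphaCVPerIndividual()].
#' @param correction p-adjustment method for the pairwise tests.
#' @return named list per metric (`cv_pd`, `cv_richness`, `cv_shannon`),
#'   each with `kw_p` and the pairwise corrected p matrix.
#' @export
habitatAlphaComparison <- function(cv_records, correction = "BH") {
  habs <- unique(cv_records$habitat)
  if (length(habs) < 2) stop("need at least 2 habitats")
  if (any(table(cv_records$habitat) < 2))
    stop("every habitat needs at least 2 subjects")
  metrics <- c("cv_pd", "cv_richness", "cv_shannon")
  out <- lapply(metrics, function(mt) {
    kw <- kruskal.test(cv_records[[mt]], as.factor(cv_records$habitat))
    pw <- suppressWarnings(
      pairwise.wilcox.test(cv_records[[mt]], cv_records$habitat,
                           p.adjust.method = correction, exact = FALSE))
    list(kw_p = kw$p.value, pairwise_p = pw$p.value)
  })
  names(out) <- metrics
  out
}
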