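#' @importFrom stats cor.test lm coef as.dist
NULL

#' Median intra-individual distance
#'
#' The personalized variability score: the median over all `choose(n, 2)`
#' within-subject pairwise distances of a time series (all pairs, not only
#' adjacent weeks).
#'
#' @param dm a [DistanceMatrix-class] containing the series samples.
#' @param series_ids sample IDs of one subject-habitat series (length >= 2).
#' @return list with `median` and `n_pairs`.
#' @export
medianIntraIndividualDistance <- function(dm, series_ids) {
  m <- as.matrix(dm)
  missing <- setdiff(series_ids, rownames(m))
  if (length(missing))
    stop("series samples missing from distance matrix: ",
         paste(missing, collapse = ", "))
  if (length(series_ids) < 2) stop("need at least 2 samples")
  sub <- m[series_ids, series_ids]
  vals <- sub[upper.tri(sub)]
  list(median = median(vals), n_pairs = length(vals))
}

#' Per-individual variability records
#'
#' For each selected (subject, habitat) series computes the median
#' intra-individual unweighted and weighted (normalized) UniFrac over all
#' sample pairs, the subject's median Shannon index, and whether the subject
#' reported antibiotic use during the series.
#'
#' @param table rarefied [CountTable-class] containing the series samples.
#' @param tree rooted [ape::phylo].
#' @param series series list from [selectTimeSeries()].
#' @param alpha alpha table from [alphaDiversity()].
#' @return data.frame with columns `subject_id`, `habitat`,
#'   `median_unweighted`, `median_weighted`, `median_shannon`, `n_pairs`,
#'   `antibiotic_user` (one row per series).
#' @export
variabilityTable <- function(table, tree, series, alpha) {
  rows <- lapply(series, function(g) {
    sub <- table[g$sample_id, ]
    dm_u <- pairwiseDistances(sub, tree, "unweighted")
    dm_w <- pairwiseDistances(sub, tree, "weighted_normalized")
    mu <- medianIntraIndividualDistance(dm_u, g$sample_id)
    mw <- medianIntraIndividualDistance(dm_w, g$sample_id)
    idx <- match(g$sample_id, alpha$sample_id)
    if (anyNA(idx))
      stop("samples missing from alpha table: ",
           paste(g$sample_id[is.na(idx)], collapse = ", "))
    abx <- g$antibiotic_this_week
    data.frame(
      subject_id = g$subject_id[1], habitat = g$habitat[1],
      median_unweighted = mu$median, median_weighted = mw$median,
      median_shannon = median(alpha$shannon[idx]),
      n_pairs = mu$n_pairs,
      antibiotic_user = if (is.null(abx)) NA else any(abx %in% TRUE),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Assign quartile-based stability classes
#'
#' Within each habitat, subjects at or below the first quartile of the chosen
#' variability score are `stable`, those strictly above the third quartile are
#' `variable`, and the middle two quartiles are `average`. Quartiles use
#' linear-interpolation quantiles. When Q1 equals Q3 (degenerate spread) all
#' subjects are `average`.
#'
#' @param records variability data.frame from [variabilityTable()].
#' @param basis score column: `"median_weighted"` (default, community
#'   structure) or `"median_unweighted"` (membership).
#' @return `records` with a `stability_class` column added.
#' @export
assignStabilityClasses <- function(records,
                                   basis = c("median_weighted",
                                             "median_unweighted")) {
  basis <- match.arg(basis)
  records$stability_class <- NA_character_
  for (h in unique(records$habitat)) {
    idx <- which(records$habitat == h)
    if (length(idx) < 4)
      stop("habitat '", h, "' has fewer than 4 subjects; quartiles undefined")
    v <- records[[basis]][idx]
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    cls <- rep("average", length(v))
    if (q[1] < q[2]) {
      cls[v <= q[1]] <- "stable"
      cls[v > q[2]] <- "variable"
    }
    records$stability_class[idx] <- cls
  }
  records
}

#' Cross-habitat correlation of variability
#'
#' Spearman rank correlation of subjects' variability scores between two body
#' habitats, over subjects with a qualifying series in both.
#'
#' @param records variability data.frame.
#' @param habitat_pair character vector of two habitats.
#' @param basis score column.
#' @return list with `rho`, `p_value`, `n_subjects`.
#' @export
crossHabitatCorrelation <- function(records, habitat_pair,
                                    basis = "median_unweighted") {
  stopifnot(length(habitat_pair) == 2)
  a <- records[records$habitat == habitat_pair[1], ]
  b <- records[records$habitat == habitat_pair[2], ]
  shared <- intersect(a$subject_id, b$subject_id)
  if (length(shared) < 5)
    stop("fewer than 5 subjects shared between ",
         habitat_pair[1], " and ", habitat_pair[2])
  x <- a[[basis]][match(shared, a$subject_id)]
  y <- b[[basis]][match(shared, b$subject_id)]
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_subjects = length(shared))
}

#' Time-decay Mantel test for one series
#'
#' Mantel test (Spearman statistic, permutation p) between a subject's
#' community distance matrix and the Manhattan time-distance matrix
#' `|week_i - week_j|`, asking whether samples farther apart in time are more
#' dissimilar. The permutation machinery is [vegan::mantel()]; p is the
#' one-tailed `(1 + #[permuted rho >= observed]) / (1 + n_permutations)`.
#'
#' @param dm a [DistanceMatrix-class] containing the series samples.
#' @param series one series data.frame (with `sample_id` and `week`).
#' @param n_permutations number of permutations (default 999).
#' @param seed integer seed.
#' @return data.frame with `subject_id`, `habitat`, `rho`, `p_value`,
#'   `n_permutations`, `degenerate` (TRUE when the statistic is undefined,
#'   e.g. a constant distance matrix).
#' @export
timeDecayMantel <- function(dm, series, n_permutations = 999, seed = 1) {
  if (nrow(series) < 4) stop("need at least 4 samples for a Mantel test")
  m <- as.matrix(dm)
  ids <- series$sample_id
  missing <- setdiff(ids, rownames(m))
  if (length(missing))
    stop("series samples missing from distance matrix: ",
         paste(missing, collapse = ", "))
  comm <- as.dist(m[ids, ids])
  timed <- dist(matrix(series$week, ncol = 1), method = "manhattan")
  out <- data.frame(subject_id = series$subject_id[1],
                    habitat = series$habitat[1],
                    rho = NA_real_, p_value = NA_real_,
                    n_permutations = n_permutations, degenerate = TRUE,
                    stringsAsFactors = FALSE)
  if (sd(comm) == 0 || sd(timed) == 0) return(out)
  set.seed(seed)
  mt <- vegan::mantel(comm, timed, method = "spearman",
                      permutations = n_permutations)
  out$rho <- unname(mt$statistic)
  out$p_value <- mt$signif
  out$degenerate <- is.na(mt$statistic)
  out
}

#' Single-factor diversity-stability model
#'
#' Within one habitat, ordinary least squares of the variability score on the
#' subject's median Shannon index, plus the Spearman rank correlation. A
#' negative relationship means more diverse communities are more stable.
#'
#' @param records variability data.frame.
#' @param habitat body habitat to model.
#' @param response score column (`"median_weighted"` or
#'   `"median_unweighted"`).
#' @return list with `slope`, `rho`, `p_value`, `n_subjects`.
#' @export
diversityStabilityModel <- function(records, habitat,
                                    response = c("median_weighted",
                                                 "median_unweighted")) {
  response <- match.arg(response)
  r <- records[records$habitat == habitat, ]
  if (nrow(r) < 5) stop("fewer than 5 subjects in habitat '", habitat, "'")
  if (sd(r$median_shannon) == 0)
    stop("constant median Shannon; model degenerate")
  fit <- lm(r[[response]] ~ r$median_shannon)
  ct <- suppressWarnings(
    cor.test(r$median_shannon, r[[response]], method = "spearman"))
  list(slope = unname(coef(fit)[2]), rho = unname(ct$estimate),
       p_value = ct$p.value, n_subjects = nrow(r))
}
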