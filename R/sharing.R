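#' Phylotype occupancy tally for one series
#'
#' Converts a subject's series to presence/absence, removes singletons, and
#' tallies the remaining phylotypes by the exact number of samples in which
#' each occurs (samples need not be consecutive weeks). Under the default
#' `total_count_1` rule a singleton is a phylotype with exactly one read
#' across the whole series; under `single_sample` it is a phylotype observed
#' in exactly one sample.
#'
#' @param table a [CountTable-class] containing the series samples.
#' @param series_ids sample IDs of one series (length >= 2).
#' @param singleton_rule `"total_count_1"` (default) or `"single_sample"`.
#' @return named integer vector: element `k` is the number of phylotypes
#'   occurring in exactly `k` of the series samples (k = 1..n_samples).
#' @export
occupancyCounts <- function(table, series_ids,
                            singleton_rule = c("total_count_1",
                                               "single_sample")) {
  singleton_rule <- match.arg(singleton_rule)
  if (length(series_ids) == 0) stop("empty series")
  m <- counts(table)[series_ids, , drop = FALSE]
  total <- colSums(m)
  occ <- colSums(m > 0)
  keep <- if (singleton_rule == "total_count_1") total > 1 else occ > 1
  keep <- keep & occ > 0
  k <- seq_along(series_ids)
  out <- vapply(k, function(kk) sum(occ[keep] == kk), 0L)
  names(out) <- k
  out
}

#' Proportion of phylotypes seen more than once
#'
#' Among a series' (singleton-filtered) phylotypes, the fraction observed in
#' at least two samples, i.e. shared with any other point in time.
#'
#' @param counts_by_k occupancy tally from [occupancyCounts()].
#' @return proportion in `[0, 1]`.
#' @examples
#' proportionShared(c(`1` = 85, `2` = 10, `3` = 5))  # 0.15
#' @export
proportionShared <- function(counts_by_k) {
  k <- as.integer(names(counts_by_k))
  total <- sum(counts_by_k[k >= 1])
  if (total == 0) stop("no phylotypes in tally")
  sum(counts_by_k[k >= 2]) / total
}

#' Restrict a series to its most abundant phylotypes
#'
#' Ranks phylotypes by total count across the subject's series (ties broken
#' by phylotype ID, lexicographic) and keeps the top `n` (default 100) or the
#' top `fraction`. Applied before occupancy tallying.
#'
#' @param table a [CountTable-class].
#' @param series_ids sample IDs of one series.
#' @param mode `"top_n"` (default) or `"top_fraction"`.
#' @param n number of phylotypes kept in `top_n` mode.
#' @param fraction fraction kept in `top_fraction` mode (default 0.10).
#' @return a [CountTable-class] restricted to the series samples and the
#'   selected phylotypes.
#' @export
topAbundanceSubset <- function(table, series_ids,
                               mode = c("top_n", "top_fraction"),
                               n = 100, fraction = 0.10) {
  mode <- match.arg(mode)
  m <- counts(table)[series_ids, , drop = FALSE]
  total <- colSums(m)
  pool <- names(total)[total > 0]
  ord <- pool[order(-total[pool], pool)]
  k <- if (mode == "top_n") min(n, length(ord))
       else max(1L, ceiling(fraction * length(ord)))
  table[series_ids, ord[seq_len(k)]]
}

#' Sharing-curve summary across subjects
#'
#' Aggregates per-subject occupancy tallies into a per-habitat curve: for
#' each number of samples `k`, the mean and standard error (SEM) across
#' subjects of the phylotype count at exactly `k` and of the proportion of
#' the subject's phylotypes at exactly `k`.
#'
#' @param tallies named list of occupancy tallies (one per subject series).
#' @param habitat habitat label recorded in the output.
#' @param subset label for the phylotype subset (`"all_nonsingleton"` or
#'   `"top_abundant"`).
#' @return data.frame with columns `habitat`, `subset`, `k`, `mean_count`,
#'   `sem_count`, `mean_proportion`, `sem_proportion`, `n_subjects`.
#' @export
sharingSummary <- function(tallies, habitat = NA_character_,
                           subset = "all_nonsingleton") {
  if (length(tallies) < 2) stop("need at least 2 subjects")
  k_max <- max(vapply(tallies, length, 0L))
  sem <- function(x) sd(x) / sqrt(length(x))
  rows <- lapply(seq_len(k_max), function(kk) {
    cnt <- vapply(tallies, function(t) {
      if (kk <= length(t)) as.numeric(t[[kk]]) else 0
    }, 0)
    prop <- vapply(seq_along(tallies), function(i) {
      tot <- sum(tallies[[i]])
      if (tot == 0) 0 else cnt[i] / tot
    }, 0)
    data.frame(habitat = habitat, subset = subset, k = kk,
               mean_count = mean(cnt), sem_count = sem(cnt),
               mean_proportion = mean(prop), sem_proportion = sem(prop),
               n_subjects = length(tallies), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Pairwise weeks-apart overlap table
#'
#' Companion view of membership turnover: for every within-series sample
#' pair, the Jaccard-style proportion of phylotypes shared, keyed by the
#' number of weeks separating the pair.
#'
#' @param table a [CountTable-class].
#' @param series one series data.frame (with `sample_id`, `week`).
#' @return data.frame with `weeks_apart`, `proportion_shared` per pair.
#' @export
weeksApartOverlap <- function(table, series) {
  m <- counts(table)[series$sample_id, , drop = FALSE] > 0
  n <- nrow(series)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      uni <- sum(m[i, ] | m[j, ])
      rows[[length(rows) + 1]] <- data.frame(
        weeks_apart = abs(series$week[j] - series$week[i]),
        proportion_shared = if (uni == 0) 0 else sum(m[i, ] & m[j, ]) / uni)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
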