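#' Remove phylotypes that are abundant in negative controls
#'
#' Phylotypes whose pooled relative abundance across all control samples is at
#' least `threshold` (default 0.5%) are treated as contaminants and dropped
#' from every sample; the control samples themselves are dropped from the
#' returned table. With `per_control_max = TRUE` the rule uses the maximum
#' per-control relative abundance instead.
#'
#' @param table a [CountTable-class] containing both real and control samples.
#' @param control_sample_ids character vector of control sample IDs.
#' @param threshold contaminant relative-abundance threshold in `[0, 1]`.
#' @param per_control_max use the per-control maximum instead of the pooled
#'   fraction.
#' @return list with `table` (filtered [CountTable-class]) and `removed`
#'   (character vector of dropped phylotype IDs).
#' @export
removeControlContaminants <- function(table, control_sample_ids,
                                      threshold = 0.005,
                                      per_control_max = FALSE) {
  if (length(control_sample_ids) == 0)
    stop("control sample set is empty; contaminant filter undefined")
  m <- counts(table)
  missing <- setdiff(control_sample_ids, rownames(m))
  if (length(missing))
    stop("control samples not in table: ", paste(missing, collapse = ", "))
  ctrl <- m[control_sample_ids, , drop = FALSE]
  if (per_control_max) {
    rel <- ctrl / pmax(rowSums(ctrl), 1)
    frac <- apply(rel, 2, max)
  } else {
    pooled <- colSums(ctrl)
    frac <- pooled / max(sum(pooled), 1)
  }
  removed <- colnames(m)[frac >= threshold]
  keep_s <- setdiff(rownames(m), control_sample_ids)
  keep_p <- setdiff(colnames(m), removed)
  message(sprintf("contaminant filter: removed %d phylotypes, %d controls",
                  length(removed), length(control_sample_ids)))
  list(table = table[keep_s, keep_p], removed = removed)
}

# Deterministic per-sample RNG substream offset derived from the sample ID,
# so rarefying any subset of samples reproduces the full-table result.
sampleSeed <- function(seed, sample_id) {
  (as.integer(seed) + strtoi(strHash(sample_id), 16L)) %% 2147483647L
}

#' Rarefy every sample to a fixed depth
#'
#' Each sample is subsampled uniformly without replacement to exactly `depth`
#' reads; samples with fewer than `depth` total reads are dropped (and
#' reported). Each sample uses an RNG substream derived from `(seed,
#' sample_id)`, so results are reproducible per sample regardless of which
#' other samples are present.
#'
#' @param table a [CountTable-class].
#' @param depth target depth (positive integer).
#' @param seed integer seed.
#' @return a rarefied [CountTable-class].
#' @export
rarefy <- function(table, depth = 10000, seed = 1) {
  stopifnot(depth >= 1)
  m <- counts(table)
  tot <- rowSums(m)
  dropped <- rownames(m)[tot < depth]
  if (length(dropped))
    message(sprintf("rarefy: dropped %d samples below depth %d",
                    length(dropped), depth))
  keep <- rownames(m)[tot >= depth]
  out <- matrix(0L, length(keep), ncol(m),
                dimnames = list(keep, colnames(m)))
  for (s in keep) {
    x <- m[s, ]
    if (sum(x) == depth) {
      out[s, ] <- x
    } else {
      set.seed(sampleSeed(seed, s))
      pool <- rep.int(seq_along(x), x)
      drawn <- sample(pool, depth)
      out[s, ] <- tabulate(drawn, nbins = length(x))
    }
  }
  CountTable(out, taxonomy(table))
}

#' Select qualifying time series
#'
#' Groups samples by `(subject_id, habitat)` and keeps only groups with at
#' least `min_series_length` samples, each ordered by week. Inclusion is
#' decided per habitat independently: a subject can qualify at one body site
#' and not another.
#'
#' @param metadata sample metadata data.frame (see [readSampleMetadata()]).
#' @param min_series_length minimum number of samples per series (default 7).
#' @return named list of per-series data.frames (names `subject|habitat`),
#'   each ordered by week.
#' @export
selectTimeSeries <- function(metadata, min_series_length = 7) {
  if (nrow(metadata) == 0) stop("metadata is empty")
  stopifnot(min_series_length >= 2)
  key <- paste(metadata$subject_id, metadata$habitat, sep = "|")
  groups <- split(metadata, key)
  keep <- groups[vapply(groups, nrow, 0L) >= min_series_length]
  keep <- lapply(keep, function(g) g[order(g$week), , drop = FALSE])
  message(sprintf("selected %d of %d (subject, habitat) series",
                  length(keep), length(groups)))
  keep
}
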