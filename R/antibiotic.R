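#' Adjacent-week distances with within-subject ranks
#'
#' Compiles the distances between consecutive samples of one series (week 1
#' to week 2, week 2 to week 3, and so on), flags each interval as an
#' antibiotic interval when a reported-use flag is set at either endpoint
#' week (or, with `endpoint = "later"`, only the later week), and ranks the
#' distances from smallest to largest within the series (mid-ranks on ties).
#' An unreported flag (`NA`) counts as no use.
#'
#' @param dm a [DistanceMatrix-class] containing the series samples.
#' @param series one series data.frame (columns `sample_id`, `week`, and
#'   optionally `antibiotic_this_week`).
#' @param endpoint which endpoint weeks flag an interval: `"either"`
#'   (default) or `"later"`.
#' @return data.frame with one row per consecutive interval: `subject_id`,
#'   `habitat`, `week_from`, `week_to`, `distance`, `antibiotic_interval`,
#'   `within_subject_rank`.
#' @export
adjacentWeekDistances <- function(dm, series, endpoint = c("either", "later")) {
  endpoint <- match.arg(endpoint)
  if (nrow(series) < 3) stop("need at least 3 samples (2 intervals)")
  m <- as.matrix(dm)
  ids <- series$sample_id
  missing <- setdiff(ids, rownames(m))
  if (length(missing))
    stop("series samples missing from distance matrix: ",
         paste(missing, collapse = ", "))
  abx <- series$antibiotic_this_week
  if (is.null(abx)) abx <- rep(NA, nrow(series))
  abx <- abx %in% TRUE
  n <- nrow(series)
  i <- seq_len(n - 1)
  d <- m[cbind(ids[i], ids[i + 1])]
  flag <- if (endpoint == "either") abx[i] | abx[i + 1] else abx[i + 1]
  data.frame(
    subject_id = series$subject_id[1], habitat = series$habitat[1],
    week_from = series$week[i], week_to = series$week[i + 1],
    distance = d, antibiotic_interval = flag,
    within_subject_rank = rank(d),
    stringsAsFactors = FALSE
  )
}

# Two-sample t statistic, group 1 minus group 2: Welch (unequal-variance)
# form, falling back to the pooled-variance form when a group is a singleton
# (the Welch denominator is undefined at n = 1). The permutation p remains
# valid because the same statistic is used for the observed and null draws.
rankT <- function(x, y) {
  nx <- length(x); ny <- length(y)
  den <- if (nx < 2 || ny < 2) {
    sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2)
    sqrt(sp2 * (1 / nx + 1 / ny))
  } else {
    sqrt(var(x) / nx + var(y) / ny)
  }
  if (den == 0) 0 else (mean(x) - mean(y)) / den
}

#' Within-individual Monte Carlo rank t-test for antibiotic weeks
#'
#' Pools within-subject ranks of adjacent-week distances across individuals,
#' splits them by whether the interval was an antibiotic interval, and tests
#' one-tailed whether antibiotic intervals carry larger ranks (larger
#' community shifts). The observed unequal-variance t statistic is compared
#' with a null built by shuffling the antibiotic labels over the pooled ranks
#' `n_iterations` times; `p = (1 + #[null t >= observed]) / (1 +
#' n_iterations)`. With `stratified = TRUE` labels are shuffled within each
#' subject-habitat instead of over the pooled set.
#'
#' @param distances data.frame from [adjacentWeekDistances()] (rows from many
#'   subjects may be concatenated).
#' @param n_iterations Monte Carlo iterations (default 1000).
#' @param seed integer seed.
#' @param stratified shuffle labels within subjects.
#' @return list with `t`, `p_value`, `n_antibiotic`, `n_other`,
#'   `n_iterations`.
#' @export
monteCarloRankTest <- function(distances, n_iterations = 1000, seed = 1,
                               stratified = FALSE) {
  r <- distances$within_subject_rank
  g <- distances$antibiotic_interval
  if (length(r) < 4) stop("need at least 4 intervals")
  if (!any(g) || all(g)) stop("both antibiotic and non-antibiotic intervals required")
  obs <- rankT(r[g], r[!g])
  strata <- paste(distances$subject_id, distances$habitat, sep = "|")
  set.seed(seed)
  null_t <- vapply(seq_len(n_iterations), function(i) {
    gp <- if (stratified) {
      unsplit(lapply(split(g, strata), sample), strata)
    } else sample(g)
    rankT(r[gp], r[!gp])
  }, 0)
  # tolerance guards permutations whose statistic ties the observed one
  p <- (1 + sum(null_t >= obs - 1e-9)) / (1 + n_iterations)
  list(t = obs, p_value = p, n_antibiotic = sum(g), n_other = sum(!g),
       n_iterations = n_iterations)
}

#' Population-level antibiotic effect on variability
#'
#' Within one habitat, a two-sided Mann-Whitney U test comparing the median
#' UniFrac variability scores of subjects who reported antibiotic use against
#' those who did not, on both the unweighted and the weighted basis.
#'
#' @param records variability data.frame (with `antibiotic_user`).
#' @param habitat body habitat.
#' @return data.frame with one row per basis: `habitat`, `basis`, `U`,
#'   `p_value`, `n_users`, `n_nonusers`, and `flagged` when a group has
#'   fewer than 2 subjects (statistics set to `NA`).
#' @export
populationAntibioticTest <- function(records, habitat) {
  r <- records[records$habitat == habitat & !is.na(records$antibiotic_user), ]
  rows <- lapply(c("median_unweighted", "median_weighted"), function(basis) {
    users <- r[[basis]][r$antibiotic_user]
    non <- r[[basis]][!r$antibiotic_user]
    flagged <- length(users) < 2 || length(non) < 2
    if (flagged) {
      data.frame(habitat = habitat, basis = basis, U = NA_real_,
                 p_value = NA_real_, n_users = length(users),
                 n_nonusers = length(non), flagged = TRUE)
    } else {
      wt <- suppressWarnings(wilcox.test(users, non, exact = FALSE))
      data.frame(habitat = habitat, basis = basis, U = unname(wt$statistic),
                 p_value = wt$p.value, n_users = length(users),
                 n_nonusers = length(non), flagged = FALSE)
    }
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
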