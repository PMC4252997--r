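#' @importFrom stats rgamma rmultinom runif rnorm rexp rbinom
NULL

#' Configuration for the synthetic longitudinal cohort
#'
#' Defaults emulate the targeted study design at test scale: 40 subjects
#' sampled weekly for 10 weeks at all four body habitats, a pool of 300
#' phylotypes, and 1,000 reads per sample (a study-scale run would use depth
#' 10,000; the reduced default keeps simulations fast without changing the
#' statistical structure).
#'
#' Each subject-habitat community occupies a support of `support_size` taxa
#' carrying a fixed Zipf abundance spectrum (rank r has mass proportional to
#' `r^-spectrum_gamma`). The initial support is personalized: taxa are drawn
#' with probabilities from a Dirichlet(`theta` * habitat base weights)
#' preference draw, so subjects of the same habitat share structure but not
#' membership. Temporal turnover is governed by the per-subject rate `w`:
#' each week exactly `round(w * support_size)` support slots are replaced,
#' the departing taxon's rank (and hence abundance) passing to a colonizer
#' drawn uniformly from the pool, excluding taxa hosted within the last
#' `refractory` weeks (departed taxa do not instantly recolonize, which
#' keeps long-lag turnover informative about `w`). `w = 0` is a fully
#' persistent community; `w = 1` is fully transient (colonizers then never
#' return to previously hosted taxa, which requires `n_taxa >=
#' support_size * n_weeks`).
#'
#' A habitat-specific fraction of taxa is transient: any of them present in
#' the week's support is detected only with probability
#' `transient_occupancy`, adding skin-like presence/absence flicker on top
#' of the turnover dynamics. When `diversity_stability_link` is TRUE the
#' support size (and with it alpha diversity) decreases linearly in `w` over
#' `link_support_range`, coupling low diversity to high turnover; when FALSE
#' every subject has the same support size, so diversity and turnover are
#' unlinked by construction.
#'
#' @param n_subjects number of subjects (default 40).
#' @param habitats body habitats to simulate.
#' @param n_weeks weekly samples per subject-habitat (default 10).
#' @param depth reads per sample (default 1000).
#' @param n_taxa phylotype pool size (default 300).
#' @param w_range per-subject turnover: a length-2 sampling range (default
#'   c(0.05, 0.6)) or a length-`n_subjects` vector of fixed rates.
#' @param theta Dirichlet concentration of the personal preference draw
#'   (default 40; smaller = more personalized initial membership).
#' @param support_size taxa per community when the link is off (default 45).
#' @param spectrum_gamma Zipf exponent of the abundance spectrum (default 1).
#' @param refractory number of past weeks whose taxa are excluded from
#'   recolonization (default 3).
#' @param diversity_stability_link couple low diversity to high turnover.
#' @param link_support_range support sizes mapped onto `w_range` when the
#'   link is on (default c(120, 25)).
#' @param transient_fraction named per-habitat fraction of transient taxa.
#' @param transient_occupancy weekly detection probability of a transient
#'   taxon (default 0.5).
#' @param antibiotic_events `"auto"` (default: one event in a random
#'   interior week for 20% of subjects), an explicit data.frame with columns
#'   `subject_id`, `week`, `multiplier`, or NULL for none.
#' @param antibiotic_effect proportion multiplier applied to the perturbed
#'   taxon subset (30% of the support) during an auto event (default 0.02,
#'   a strong transient suppression clearly exceeding baseline weekly
#'   turnover).
#' @param n_controls number of negative-control samples (default 3).
#' @param n_contaminants contaminant phylotypes spiked into controls.
#' @param n_families synthetic family count for the taxonomy (default 20).
#' @param seed RNG seed.
#' @return a `cohortConfig` list.
#' @export
cohortConfig <- function(n_subjects = 40, habitats = HABITATS, n_weeks = 10,
                         depth = 1000, n_taxa = 300,
                         w_range = c(0.05, 0.6),
                         theta = 40, support_size = 45, spectrum_gamma = 1,
                         refractory = 3,
                         diversity_stability_link = FALSE,
                         link_support_range = c(120, 25),
                         transient_fraction = c(forehead = 0.4, gut = 0.05,
                                                palm = 0.4, tongue = 0.1),
                         transient_occupancy = 0.5,
                         antibiotic_events = "auto",
                         antibiotic_effect = 0.02,
                         n_controls = 3, n_contaminants = 5,
                         n_families = 20, seed = 1) {
  stopifnot(depth >= 1, n_taxa >= 2, n_subjects >= 1, n_weeks >= 2,
            all(w_range >= 0), all(w_range <= 1), theta > 0,
            support_size >= 2, support_size <= n_taxa, refractory >= 0,
            transient_occupancy >= 0, transient_occupancy <= 1,
            length(w_range) %in% c(2, n_subjects))
  structure(as.list(environment()), class = "cohortConfig")
}

#' Generate a random phylogeny over the simulated phylotypes
#'
#' Pure-birth (Yule) topology with independent exponential branch lengths
#' (mean 0.1); tips are labelled `OTU_0001`, `OTU_0002`, ...
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed RNG seed.
#' @return an [ape::phylo].
#' @export
generateTree <- function(n_taxa, seed = 1) {
  set.seed(seed)
  generateTreeImpl(n_taxa)
}

generateTreeImpl <- function(n_taxa) {
  stopifnot(n_taxa >= 2)
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tree$edge.length <- rexp(nrow(tree$edge), rate = 10)
  tree$tip.label <- sprintf("OTU_%04d", seq_len(n_taxa))
  tree
}

syntheticTaxonomy <- function(taxa, n_families) {
  fam <- rep(seq_len(n_families), length.out = length(taxa))
  phy <- (fam - 1) %/% 5 + 1
  lineage <- sprintf(
    "k__Bacteria;p__Phy%02d;c__Cls%02d;o__Ord%02d;f__Fam%02d;g__;s__",
    phy, phy, fam, fam)
  setNames(lineage, taxa)
}

#' Generate a synthetic longitudinal cohort
#'
#' Simulates personalized weekly communities per subject and habitat under
#' the support-replacement model described in [cohortConfig()], plus
#' negative-control samples spiked with designated contaminant phylotypes.
#' The entire cohort is a deterministic function of the config seed.
#'
#' @param config a [cohortConfig()] list.
#' @return list with `table` (a [CountTable-class] of real plus control
#'   samples, with taxonomy), `metadata` (sample records for the real
#'   samples, including `antibiotic_this_week`), `tree`, `control_ids`, and
#'   `truth` (list with the per-subject `subjects` data.frame of `w`,
#'   `theta` and `support_size`, the `events` data.frame, and the
#'   `contaminants`).
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "cohortConfig"))
  set.seed(config$seed)
  n_taxa <- config$n_taxa
  tree <- generateTreeImpl(n_taxa)
  taxa <- tree$tip.label
  subjects <- sprintf("S%02d", seq_len(config$n_subjects))

  w <- if (length(config$w_range) == config$n_subjects &&
           config$n_subjects != 2) config$w_range
       else if (length(config$w_range) == 2)
         runif(config$n_subjects, config$w_range[1], config$w_range[2])
       else config$w_range
  if (config$diversity_stability_link) {
    lo <- min(config$w_range); hi <- max(config$w_range)
    frac <- if (hi > lo) (w - lo) / (hi - lo) else rep(0, length(w))
    Ks <- round(config$link_support_range[1] +
                frac * (config$link_support_range[2] -
                        config$link_support_range[1]))
  } else {
    Ks <- rep(config$support_size, config$n_subjects)
  }
  if (any(w >= 1 & n_taxa < Ks * config$n_weeks))
    stop("fully transient subjects need n_taxa >= support_size * n_weeks")
  names(w) <- names(Ks) <- subjects

  base <- lapply(config$habitats, function(h) {
    b <- rgamma(n_taxa, shape = 0.7)
    b / sum(b)
  })
  names(base) <- config$habitats
  transient <- lapply(config$habitats, function(h) {
    frac <- config$transient_fraction[[h]]
    if (is.null(frac) || is.na(frac)) frac <- 0
    sample.int(n_taxa, floor(frac * n_taxa))
  })
  names(transient) <- config$habitats

  events <- config$antibiotic_events
  if (identical(events, "auto")) {
    n_users <- max(0L, round(0.2 * config$n_subjects))
    users <- sample(subjects, n_users)
    events <- if (n_users == 0) NULL else data.frame(
      subject_id = users,
      week = sample(seq(1L, max(1L, config$n_weeks - 2L)), n_users,
                    replace = TRUE),
      multiplier = config$antibiotic_effect,
      stringsAsFactors = FALSE)
  }
  if (is.null(events))
    events <- data.frame(subject_id = character(0), week = integer(0),
                         multiplier = numeric(0))

  n_samples <- config$n_subjects * length(config$habitats) * config$n_weeks
  m <- matrix(0L, n_samples, n_taxa)
  meta <- vector("list", n_samples)
  ids <- character(n_samples)
  row <- 0L
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    K <- Ks[si]
    v <- seq_len(K)^-config$spectrum_gamma
    v <- v / sum(v)
    n_repl <- round(w[si] * K)
    ev_weeks <- events$week[events$subject_id == s]
    ev_mult <- events$multiplier[events$subject_id == s]
    for (h in config$habitats) {
      pref <- rgamma(n_taxa, shape = config$theta * base[[h]])
      pref[pref <= 0] <- 1e-12
      support <- sample.int(n_taxa, K, prob = pref)
      used <- support
      history <- list(support)
      for (t in seq_len(config$n_weeks) - 1L) {
        if (t > 0 && n_repl > 0) {
          repl <- sample.int(K, n_repl)
          kept <- support[-repl]
          cand <- if (w[si] >= 1) {
            setdiff(seq_len(n_taxa), used)
          } else {
            recent <- if (config$refractory == 0) integer(0) else
              unique(unlist(
                history[max(1, length(history) - config$refractory + 1):
                        length(history)]))
            cc <- setdiff(seq_len(n_taxa), union(kept, recent))
            if (length(cc) < n_repl) cc <- setdiff(seq_len(n_taxa), kept)
            cc
          }
          support[repl] <- sample(cand, n_repl)
          used <- union(used, support)
          history[[length(history) + 1L]] <- support
        }
        p <- numeric(n_taxa)
        p[support] <- v
        if (t %in% ev_weeks) {
          hit <- sample(support, max(1L, floor(0.3 * K)))
          p[hit] <- p[hit] * ev_mult[match(t, ev_weeks)]
          p <- p / sum(p)
        }
        tr <- intersect(transient[[h]], support)
        if (length(tr)) {
          off <- tr[runif(length(tr)) > config$transient_occupancy]
          if (length(off) && sum(p[setdiff(support, off)]) > 0) {
            p[off] <- 0
            p <- p / sum(p)
          }
        }
        row <- row + 1L
        ids[row] <- sprintf("%s.%s.%02d", s, h, t)
        m[row, ] <- rmultinom(1, config$depth, p)[, 1]
        meta[[row]] <- data.frame(
          sample_id = ids[row], subject_id = s, habitat = h, week = t,
          antibiotic_this_week = t %in% ev_weeks, stringsAsFactors = FALSE)
      }
    }
  }
  dimnames(m) <- list(ids, taxa)

  contaminants <- sample(taxa, config$n_contaminants)
  control_ids <- character(0)
  if (config$n_controls > 0) {
    control_ids <- sprintf("control.%d", seq_len(config$n_controls))
    cm <- matrix(0L, config$n_controls, n_taxa,
                 dimnames = list(control_ids, taxa))
    for (ci in seq_len(config$n_controls)) {
      pc <- 0.05 * base[[1]]
      pc[match(contaminants, taxa)] <- 0.95 / length(contaminants)
      pc <- pc / sum(pc)
      cm[ci, ] <- rmultinom(1, config$depth, pc)[, 1]
    }
    m <- rbind(m, cm)
  }

  list(
    table = CountTable(m, syntheticTaxonomy(taxa, config$n_families)),
    metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
    tree = tree,
    control_ids = control_ids,
    truth = list(
      subjects = data.frame(subject_id = subjects, w = unname(w),
                            theta = config$theta,
                            support_size = unname(Ks),
                            stringsAsFactors = FALSE),
      events = events,
      contaminants = contaminants
    ),
    config = config
  )
}

#' Generate host covariates with one planted effect
#'
#' Produces subject-level covariates for testing the variability predictors:
#' one planted continuous covariate correlated with the true turnover `w` at
#' a configured effect size (fraction of variance shared), plus `n_null`
#' covariates (alternating continuous and two-level categorical) independent
#' of `w`.
#'
#' @param truth_subjects per-subject truth data.frame (`subject_id`, `w`).
#' @param planted_name name of the planted covariate.
#' @param effect_size fraction of the planted covariate's variance explained
#'   by `w` (0 = independent).
#' @param n_null number of null covariates (default 6).
#' @param seed RNG seed.
#' @return data.frame with `subject_id`, the planted covariate and the null
#'   covariates.
#' @export
generateCovariates <- function(truth_subjects, planted_name = "planted",
                               effect_size = 0.3, n_null = 6, seed = 1) {
  stopifnot(effect_size >= 0, effect_size <= 1)
  set.seed(seed)
  n <- nrow(truth_subjects)
  z <- as.numeric(scale(truth_subjects$w))
  out <- data.frame(subject_id = truth_subjects$subject_id,
                    stringsAsFactors = FALSE)
  out[[planted_name]] <- sqrt(effect_size) * z +
    sqrt(1 - effect_size) * rnorm(n)
  for (i in seq_len(n_null)) {
    out[[sprintf("null_%02d", i)]] <-
      if (i %% 2 == 1) rnorm(n) else sample(c("a", "b"), n, replace = TRUE)
  }
  out
}
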