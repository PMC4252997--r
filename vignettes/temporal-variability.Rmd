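---
title: "Scoring temporal variability in longitudinal microbiome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring temporal variability in longitudinal microbiome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MicrobiomeStability)
```

## The question

Host-associated microbial communities are personalized, but they are not
static: sampled weekly, the same body site of the same person drifts in both
membership (which phylotypes are present) and structure (their relative
abundances). This package treats *the amount of that drift* as the quantity
of interest. Given a phylotype count table, a rooted phylogeny over the
phylotypes, and per-sample metadata (subject, body habitat, week, antibiotic
reports, host covariates), it computes per-individual variability scores,
classifies individuals as stable or variable, and asks which factors —
diversity, antibiotic use, host covariates — explain the differences.

The intended sampling design is a cohort of adults swabbed weekly for about
ten weeks at four body habitats (forehead, gut via feces, palm, tongue),
sequenced deeply enough to rarefy every sample to a common depth.

## Variability scores

Two complementary per-individual scores are computed for every
(subject, habitat) time series that has at least `min_series_length`
samples (default 7, applied per habitat independently):

* **CV of alpha diversity.** For each of Faith's phylogenetic diversity
  (PD), phylotype richness and the Shannon index (log base 2), the
  coefficient of variation CV = sd/mean over the subject's time-ordered
  samples, with the n−1 standard deviation since per-subject series are
  short (7–10 points). The CV is dimensionless and scale-invariant, so the
  three metrics are comparable.
* **Median intra-individual UniFrac.** All `choose(n, 2)` within-subject
  pairwise UniFrac distances — not only adjacent weeks — summarized by
  their median. Unweighted UniFrac (fraction of branch length unique to one
  sample's descendant-presence set) captures membership turnover; weighted
  UniFrac (branch length times the absolute difference of descendant
  abundance fractions) captures structural change. The weighted variant is
  normalized by default, i.e. divided by `sum(length * (p_a + p_b))`, so
  values are bounded in [0, 1] and comparable across sample pairs; the raw
  form is available via `normalized = FALSE`.

Both UniFrac variants and PD are computed from a single shared post-order
traversal of the phylogeny (`branchTotals()`), so a whole distance matrix
reuses one tree pass. PD is root-inclusive: the branches connecting the
observed subtree to the root count, which makes PD of a single-tip sample
equal to that tip's root path length. A zero-length branch contributes
nothing to any metric, so degenerate star trees are legal inputs.

## Preprocessing

Three filters precede every analysis, in this order:

1. **Contaminant removal.** Phylotypes whose pooled relative abundance
   across all negative-control samples is at least 0.5% are removed from
   every sample, and the controls are dropped. "Pooled" means summed over
   all controls before dividing — a per-control maximum rule is available
   behind `per_control_max`. Control counts are used raw (not rarefied):
   controls are typically shallow, and subsampling them would only add
   noise to the filter.
2. **Rarefaction.** Every sample is subsampled without replacement to
   exactly `depth` reads; shallower samples are dropped and reported. Each
   sample's draw uses an RNG substream derived from `(seed, sample_id)`, so
   rarefying any subset of samples reproduces the full-table result
   bit-for-bit. A single seeded draw is used rather than an average over
   draws; at the depths involved the residual subsampling noise is small
   relative to between-week variation.
3. **Series selection.** Only (subject, habitat) series with at least 7
   samples enter the time-series analyses. A subject can qualify at one
   habitat and not another.

## Downstream analyses

* **Stability classes.** Within each habitat, subjects at or below the
  first quartile of the variability score are `stable`, strictly above the
  third quartile `variable`, otherwise `average`. Quartiles use
  linear-interpolation quantiles. Boundary ties go to the more stable class
  at Q1 (≤ Q1 is stable) and to the less extreme class at Q3 (> Q3
  strictly); when Q1 equals Q3 the spread is degenerate and everyone is
  `average`. The default basis is the weighted median (structure); the
  unweighted basis is a parameter.
* **Phylotype sharing.** Per subject, the presence/absence series is
  tallied by the exact number of samples in which each phylotype occurs,
  after removing singletons. A *singleton* defaults to a phylotype with a
  single read across the subject's series (`total_count_1`), the usual
  amplicon usage; "observed in a single sample" is available as
  `single_sample`. The tally is repeated on the subject's most abundant
  phylotypes — default the top 100 (`top_n`), with the top 10% behind
  `top_fraction`, and both reported by the pipeline since either convention
  is defensible. Curves are averaged across subjects with ±1 SEM. A
  companion weeks-apart table (`weeksApartOverlap()`) gives the pairwise
  presence Jaccard by time lag.
* **Taxon enrichment.** Counts are collapsed to bacterial families (first
  five lineage ranks; empty family ranks pool into `f__unclassified`), each
  subject contributes its mean weekly relative abundance (one observation
  per subject, avoiding pseudo-replication), families above 1% mean
  abundance in *any* stability class are kept (this subsumes the stricter
  overall-mean rule), abundances are rank-transformed, and a Kruskal-Wallis
  test compares the classes per family with Benjamini-Hochberg correction
  across families within a habitat (Bonferroni behind a flag).
* **Antibiotic effects**, two views. Population-level: a two-sided
  Mann-Whitney U comparing median UniFrac of reported users vs non-users
  per habitat. Within-individual: adjacent-week distances are ranked within
  each subject (mid-ranks on ties), ranks are pooled across subjects —
  which normalizes away each subject's baseline volatility — split by
  whether the interval touches a reported-antibiotic week (either endpoint
  by default; later-endpoint behind a flag), and compared by a one-tailed
  Monte Carlo t-test (1,000 label shufflings; unequal-variance t, with a
  pooled-variance fallback when a group is a singleton since the Welch
  denominator is undefined at n = 1). Labels are shuffled over the pooled
  ranks by default, matching the pooled construction; a within-subject
  stratified shuffle is available.
* **Time decay.** Per subject, a Mantel test (Spearman statistic, 999
  permutations, one-tailed p = (1 + #[ρ* ≥ ρ]) / (1 + n)) between the
  community distance matrix and the Manhattan time-distance |week_i −
  week_j|. The permutation machinery is vegan's; a constant distance matrix
  yields a flagged (`degenerate`) result rather than an error.
* **Diversity-stability.** Per habitat, an OLS fit of the variability score
  on the subject's median Shannon index plus the Spearman correlation with
  its asymptotic p (a permutation option exists in vegan's machinery but
  the asymptotic p is the default; per-habitat n here is far above the
  small-sample regime where it misleads). The median (not the mean) of the
  weekly Shannon values represents a subject's diversity: it is robust to
  a single perturbed week, e.g. an antibiotic course.
* **Covariate GLMs.** Host covariates are screened for replication
  (categorical levels with fewer than 5 subjects exclude the covariate),
  one-hot-coded with the most frequent level as reference, and continuous
  covariates z-scored so estimates are comparable. A Gaussian identity-link
  model of the variability score is simplified backwards: at each step the
  term with the largest type-II F-test p ≥ 0.05 is removed (ties broken by
  removing the lexicographically later term) until all retained terms are
  significant. Type-II sums of squares make the per-term test invariant to
  term order. A BIC-minimizing mode removes terms greedily while BIC
  decreases. An empty final model is reported as "No good model".

## The synthetic cohort generator

Real cohorts of this design are not redistributable at package scale, so
the generator is a first-class module: it produces cohorts with the
statistical structure the analyses assume, with known ground truth, and all
calibration claims below are claims about these synthetic conditions.

Each subject `i` carries a turnover rate `w_i` (default uniform on
[0.05, 0.6]) shared across habitats. A subject-habitat community occupies a
support of `support_size = 45` phylotypes carrying a fixed Zipf abundance
spectrum (rank r mass ∝ 1/r). The initial support is drawn with
probabilities from a Dirichlet(θ·base) preference draw (θ = 40) around
habitat-specific base weights, giving personalized membership with habitat
structure. Each week, exactly `round(w_i * support_size)` support slots are
replaced; the departing taxon's rank passes to a colonizer drawn uniformly
from the pool, excluding taxa hosted in the last `refractory = 3` weeks so
that long-lag comparisons remain informative about `w`. On top of this, a
habitat-specific fraction of taxa is *transient*: when present in the
support they are detected only with probability 0.5 that week, reproducing
the skin-like occupancy flicker (forehead/palm 0.4 of taxa, tongue 0.1,
gut 0.05). Counts are multinomial at `depth = 1000` per sample (a
test-scale stand-in for study-scale depths; the statistical structure does
not change). Antibiotic events suppress 30% of the support to 2% of its
mass for the event week and set the metadata flag; negative controls carry
five designated contaminant phylotypes at ≥1% plus sparse noise.

An earlier design iterated an autoregressive Dirichlet mixture (week t =
(1−w)·previous + w·fresh Dirichlet draw). It was abandoned for a
measurement-theoretic reason worth recording: at realistic depths the
plug-in Shannon estimator is biased downward for the diffuse mixtures that
high turnover produces, so *measured* diversity correlates negatively with
`w` even when the generative diversity is identical across subjects. That
bias, together with the well-known richness sensitivity of unweighted
UniFrac, manufactures a spurious negative diversity-stability relationship
in cohorts where none exists. The support-replacement model keeps the
latent abundance spectrum — and hence measured diversity — identical
across subjects unless the diversity-stability link is explicitly enabled,
which makes "link disabled" a genuine null.

With the link enabled, the support size falls linearly in `w` from 120 to
25 taxa, so high-turnover subjects host low-diversity communities; with it
disabled, every subject has the same support size. The boundary `w = 1` is
implemented as no-return turnover (colonizers never revisit previously
hosted taxa, requiring `n_taxa ≥ support_size × n_weeks`), so a fully
transient subject shares nothing across weeks, and `w = 0` is full
persistence.

Measured under the default conditions (40 subjects, 10 weeks, depth 1,000,
gut habitat), the Spearman correlation between true `w` and the median
unweighted UniFrac is ≈ 0.93 across seeds; with the link off, spuriously
significant negative diversity-stability correlations occur in none of the
seeds examined; with it on, they are detected essentially always. These
figures are recomputed by the test suite and by `scripts/acceptance.R`, not
asserted.

What the generator does **not** emulate: compositional count correlation
beyond the support constraint, taxon-taxon interactions, read-depth
variation across samples, chimeras or contamination gradients, seasonal or
trend components, and antibiotic pharmacology (class, dose, recovery
trajectories). Passing tests therefore demonstrate correctness of the
estimators and calibration of the tests under these idealized dynamics, not
that real cohorts satisfy the model.

## Numerical and design choices

* Shannon in log base 2 (bits); base e behind a flag.
* Quantile type 7 (R's default linear interpolation) for all quartiles.
* Weighted UniFrac defaults to the normalized variant; pipeline reports
  rest on it, the raw form is a flag.
* Rarefaction substreams: per-sample seeds are derived from a polynomial
  string hash of the sample ID plus the master seed, modulo 2^31 − 1.
* Monte Carlo p values use the add-one form (1 + #extreme)/(1 + n), which
  is never zero; permutations tying the observed statistic count as
  extreme, with a 1e-9 tolerance guarding floating-point ties.
* Stage outputs are TSV with one comment line carrying the package version
  and a hash of the analytic configuration (output paths excluded), and no
  timestamps — reruns with the same seed are byte-identical.
* The pipeline (`runAll()`) is a plain R function over the exported stage
  functions; the package is a library, not a shell tool, so no separate
  command-line binary is shipped.
* Within-subject distance matrices are computed per series rather than one
  cohort-wide matrix: every downstream statistic uses within-subject pairs
  only, and the per-series route keeps the cost linear in subjects.

## Problem sizes

The shipped tests and the acceptance script run, per cohort, 40 subjects ×
10 weeks at depth 1,000 with 300 phylotypes; oracle equivalences use 200
random instances on trees of up to 16 tips; permutation-test calibrations
use 1,000 simulated datasets; the stepwise-GLM calibration uses 200 runs at
n = 60. A study-scale run of the same code (85 subjects, 4 habitats, depth
10,000) is a matter of changing `cohortConfig()`/`pipelineConfig()`
arguments.

## Known limitations

* Unweighted UniFrac retains its intrinsic sensitivity to rarefaction
  depth and rare-taxon detection; cross-study comparisons of absolute
  medians require a common depth.
* Backward stepwise selection inherits the usual caveats of data-driven
  model simplification; the BIC mode is provided precisely because the two
  criteria can disagree, and retained-term p values are not adjusted for
  selection.
* The enrichment module tests families marginally; it does not model
  compositional coupling between families.
* Asymptotic Spearman p values are used for the diversity-stability and
  cross-habitat correlations; with fewer than ~10 subjects per habitat a
  permutation p would be preferable.
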