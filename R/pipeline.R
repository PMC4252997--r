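#' Pipeline configuration
#'
#' Collects every input and tuning knob of the end-to-end analysis. Inputs
#' may be file paths (read with the package readers) or in-memory objects
#' ([CountTable-class], [ape::phylo], metadata data.frame).
#'
#' @param counts count table or path to a classic TSV OTU table.
#' @param tree phylogeny or path to a newick file.
#' @param metadata sample metadata data.frame or path to a TSV.
#' @param controls character vector of control sample IDs, a path to a file
#'   with one ID per line, or NULL to skip the contaminant filter.
#' @param out_dir output directory.
#' @param depth rarefaction depth (default 800, suited to the simulator's
#'   default sequencing depth of 1000 once contaminant reads are removed;
#'   study-scale data would use 10000).
#' @param contaminant_threshold pooled control abundance threshold
#'   (default 0.005).
#' @param min_series_length minimum samples per (subject, habitat) series
#'   (default 7).
#' @param class_basis variability score used for stability classes.
#' @param mantel_permutations permutations per time-decay Mantel test
#'   (default 999).
#' @param mc_iterations Monte Carlo iterations for the antibiotic rank test
#'   (default 1000).
#' @param seed master seed; every stochastic stage derives its stream from
#'   it.
#' @return a `pipelineConfig` list.
#' @export
pipelineConfig <- function(counts, tree, metadata, controls = NULL,
                           out_dir = "pipeline_out", depth = 800,
                           contaminant_threshold = 0.005,
                           min_series_length = 7,
                           class_basis = c("median_weighted",
                                           "median_unweighted"),
                           mantel_permutations = 999,
                           mc_iterations = 1000, seed = 1) {
  class_basis <- match.arg(class_basis)
  structure(as.list(environment()), class = "pipelineConfig")
}

resolveInputs <- function(config) {
  table <- if (is.character(config$counts)) readCountTable(config$counts)
           else config$counts
  tree <- if (is.character(config$tree)) readTree(config$tree)
          else config$tree
  metadata <- if (is.character(config$metadata))
    readSampleMetadata(config$metadata) else validateMetadata(config$metadata)
  controls <- config$controls
  if (is.character(controls) && length(controls) == 1 &&
      file.exists(controls))
    controls <- readLines(controls)
  list(table = table, tree = tree, metadata = metadata, controls = controls)
}

# The hash covers the analytic configuration only: the output directory is
# excluded so the same analysis written to two places is byte-identical.
hashableConfig <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  for (nm in c("counts", "tree", "metadata", "controls"))
    if (!is.character(cfg[[nm]])) cfg[[nm]] <- class(cfg[[nm]])[1]
  cfg
}

#' Run the full temporal-variability analysis
#'
#' Executes every stage on one cohort: contaminant filtering (when controls
#' are given), rarefaction, time-series selection, alpha diversity and its
#' per-subject CV, within-subject UniFrac distances and variability records
#' with stability classes, phylotype-sharing curves, family enrichment
#' across stability classes, both antibiotic tests, per-subject time-decay
#' Mantel tests, diversity-stability models, and the stepwise covariate
#' GLMs. Each stage writes one TSV into `out_dir`; a `manifest.tsv` records
#' the per-stage row counts and the config hash. Outputs are a pure function
#' of (inputs, config, seed): reruns are byte-identical.
#'
#' @param config a [pipelineConfig()] list.
#' @return (invisibly) list with the manifest data.frame and the in-memory
#'   stage results.
#' @export
runAll <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  inp <- resolveInputs(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hcfg <- hashableConfig(config)
  outputs <- list()
  emit <- function(stage, file, df) {
    if (is.null(df)) df <- data.frame(empty = logical(0))
    writeTSV(df, file.path(config$out_dir, file), config = hcfg)
    outputs[[stage]] <<- data.frame(stage = stage, file = file,
                                    n_rows = nrow(df),
                                    stringsAsFactors = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  table <- inp$table
  if (!is.null(inp$controls) && length(inp$controls) > 0) {
    filt <- stage("contaminant_filter",
                  removeControlContaminants(table, inp$controls,
                                            config$contaminant_threshold))
    table <- filt$table
  }
  table <- stage("rarefy", rarefy(table, config$depth, config$seed))
  metadata <- inp$metadata[inp$metadata$sample_id %in% sampleIDs(table), ,
                           drop = FALSE]
  series <- stage("select_series",
                  selectTimeSeries(metadata, config$min_series_length))
  if (length(series) == 0) stop("stage 'select_series' failed: no series")
  used_ids <- unlist(lapply(series, `[[`, "sample_id"), use.names = FALSE)
  table <- table[used_ids, ]

  alpha <- stage("alpha", alphaDiversity(table, inp$tree))
  emit("alpha", "alpha.tsv", alpha)

  cvrec <- stage("alpha_cv", alphaCVPerIndividual(alpha, series))
  emit("alpha_cv", "alpha_cv.tsv", cvrec)

  dms <- stage("unifrac", lapply(series, function(g) {
    sub <- table[g$sample_id, ]
    list(u = pairwiseDistances(sub, inp$tree, "unweighted"),
         w = pairwiseDistances(sub, inp$tree, "weighted_normalized"))
  }))
  records <- stage("variability", {
    rows <- lapply(seq_along(series), function(i) {
      g <- series[[i]]
      mu <- medianIntraIndividualDistance(dms[[i]]$u, g$sample_id)
      mw <- medianIntraIndividualDistance(dms[[i]]$w, g$sample_id)
      idx <- match(g$sample_id, alpha$sample_id)
      abx <- g$antibiotic_this_week
      data.frame(subject_id = g$subject_id[1], habitat = g$habitat[1],
                 median_unweighted = mu$median, median_weighted = mw$median,
                 median_shannon = median(alpha$shannon[idx]),
                 n_pairs = mu$n_pairs,
                 antibiotic_user = if (is.null(abx)) NA else any(abx %in% TRUE),
                 stringsAsFactors = FALSE)
    })
    assignStabilityClasses(do.call(rbind, c(rows, list(make.row.names = FALSE))),
                           basis = config$class_basis)
  })
  emit("variability", "variability.tsv", records)

  habitats <- unique(records$habitat)

  sharing <- stage("sharing", {
    blocks <- lapply(habitats, function(h) {
      hs <- series[vapply(series, function(g) g$habitat[1] == h, TRUE)]
      if (length(hs) < 2) return(NULL)
      tall <- lapply(hs, function(g) occupancyCounts(table, g$sample_id))
      ttop <- lapply(hs, function(g)
        occupancyCounts(topAbundanceSubset(table, g$sample_id), g$sample_id))
      rbind(sharingSummary(tall, h, "all_nonsingleton"),
            sharingSummary(ttop, h, "top_abundant"))
    })
    do.call(rbind, c(blocks, list(make.row.names = FALSE)))
  })
  emit("sharing", "sharing.tsv", sharing)

  enrichment <- stage("enrichment", {
    fam <- collapseToFamily(table)
    blocks <- lapply(habitats, function(h) {
      hs <- series[vapply(series, function(g) g$habitat[1] == h, TRUE)]
      hr <- records[records$habitat == h, ]
      cls <- hr$stability_class[match(
        vapply(hs, function(g) g$subject_id[1], ""), hr$subject_id)]
      res <- tryCatch(
        classEnrichment(subjectFamilyAbundance(fam, hs), cls),
        error = function(e) {
          message("enrichment skipped for ", h, ": ", conditionMessage(e))
          NULL
        })
      if (is.null(res) || nrow(res) == 0) return(NULL)
      cbind(habitat = h, res)
    })
    do.call(rbind, c(blocks, list(make.row.names = FALSE)))
  })
  emit("enrichment", "enrichment.tsv", enrichment)

  ab_pop <- stage("antibiotic_population", do.call(rbind, c(
    lapply(habitats, function(h) populationAntibioticTest(records, h)),
    list(make.row.names = FALSE))))
  emit("antibiotic_population", "antibiotic_population.tsv", ab_pop)

  ab_mc <- stage("antibiotic_mc", {
    blocks <- lapply(habitats, function(h) {
      hi <- which(vapply(series, function(g) g$habitat[1] == h, TRUE))
      build <- function(which_dm) do.call(rbind, c(lapply(hi, function(i)
        adjacentWeekDistances(dms[[i]][[which_dm]], series[[i]])),
        list(make.row.names = FALSE)))
      out <- list()
      for (b in c("u", "w")) {
        adw <- build(b)
        basis <- if (b == "u") "unweighted" else "weighted"
        res <- if (!any(adw$antibiotic_interval) ||
                   all(adw$antibiotic_interval)) {
          data.frame(habitat = h, basis = basis, t = NA_real_,
                     p_value = NA_real_,
                     n_antibiotic = sum(adw$antibiotic_interval),
                     n_other = sum(!adw$antibiotic_interval), flagged = TRUE)
        } else {
          mc <- monteCarloRankTest(adw, config$mc_iterations,
                                   seed = config$seed)
          data.frame(habitat = h, basis = basis, t = mc$t,
                     p_value = mc$p_value, n_antibiotic = mc$n_antibiotic,
                     n_other = mc$n_other, flagged = FALSE)
        }
        out[[b]] <- res
      }
      do.call(rbind, c(out, list(make.row.names = FALSE)))
    })
    do.call(rbind, c(blocks, list(make.row.names = FALSE)))
  })
  emit("antibiotic_mc", "antibiotic_mc.tsv", ab_mc)

  mantel <- stage("mantel", do.call(rbind, c(
    lapply(seq_along(series), function(i) {
      g <- series[[i]]
      u <- timeDecayMantel(dms[[i]]$u, g, config$mantel_permutations,
                           seed = config$seed + i)
      w <- timeDecayMantel(dms[[i]]$w, g, config$mantel_permutations,
                           seed = config$seed + i)
      u$basis <- "unweighted"
      w$basis <- "weighted"
      rbind(u, w)
    }), list(make.row.names = FALSE))))
  emit("mantel", "mantel.tsv", mantel)

  divstab <- stage("diversity_stability", do.call(rbind, c(
    lapply(habitats, function(h) {
      do.call(rbind, c(lapply(c("median_unweighted", "median_weighted"),
        function(resp) {
          ds <- diversityStabilityModel(records, h, resp)
          data.frame(habitat = h, response = resp, slope = ds$slope,
                     rho = ds$rho, p_value = ds$p_value,
                     n_subjects = ds$n_subjects, stringsAsFactors = FALSE)
        }), list(make.row.names = FALSE)))
    }), list(make.row.names = FALSE))))
  emit("diversity_stability", "diversity_stability.tsv", divstab)

  glm_table <- stage("glm", {
    subj_cols <- setdiff(names(metadata),
                         c("sample_id", "subject_id", "habitat", "week",
                           "antibiotic_this_week"))
    subj_cov <- unique(metadata[, c("subject_id", subj_cols), drop = FALSE])
    fits <- list()
    for (h in habitats) {
      hr <- records[records$habitat == h, ]
      cov <- data.frame(subject_id = hr$subject_id,
                        median_shannon = hr$median_shannon,
                        antibiotic_user = ifelse(is.na(hr$antibiotic_user),
                                                 "no_report",
                                                 ifelse(hr$antibiotic_user,
                                                        "yes", "no")),
                        stringsAsFactors = FALSE)
      cov <- merge(cov, subj_cov, by = "subject_id", all.x = TRUE,
                   sort = FALSE)
      cov <- cov[match(hr$subject_id, cov$subject_id), , drop = FALSE]
      for (basis in c("median_unweighted", "median_weighted")) {
        fit <- tryCatch({
          des <- buildDesign(hr, cov)
          stepwiseGLM(des$design, hr[[basis]][des$response_rows])
        }, error = function(e) {
          message("glm skipped for ", h, " ", basis, ": ",
                  conditionMessage(e))
          NULL
        })
        if (!is.null(fit)) fits[[paste(h, basis, sep = ".")]] <- fit
      }
    }
    if (length(fits) == 0) data.frame() else reportPredictorTable(fits)
  })
  emit("glm", "glm_table.tsv", glm_table)

  manifest <- do.call(rbind, c(unname(outputs), list(make.row.names = FALSE)))
  manifest$config_hash <- configHash(hashableConfig(config))
  manifest$seed <- config$seed
  writeTSV(manifest, file.path(config$out_dir, "manifest.tsv"), config = hcfg)
  invisible(list(manifest = manifest, records = records, alpha = alpha,
                 cv = cvrec, sharing = sharing, enrichment = enrichment,
                 antibiotic_population = ab_pop, antibiotic_mc = ab_mc,
                 mantel = mantel, diversity_stability = divstab,
                 glm = glm_table, series = series))
}
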