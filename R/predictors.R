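#' @importFrom stats BIC as.formula update var complete.cases setNames
NULL

#' Build a covariate design for variability prediction
#'
#' Prepares host covariates for the stepwise GLM: categorical covariates
#' become factors with the most frequent level as reference and are excluded
#' entirely when any level has fewer than `replication_floor` subjects
#' (insufficient replication); continuous covariates are z-scored; subjects
#' with missing values in a retained covariate are dropped. Exclusions are
#' reported via messages and in the returned lists.
#'
#' @param records variability data.frame for one habitat.
#' @param covariates data.frame with `subject_id` plus covariate columns
#'   (one row per subject).
#' @param replication_floor minimum subjects per categorical level
#'   (default 5).
#' @return list with `design` (data.frame of predictors, rownames = subject
#'   IDs), `response_rows` (matching row indices into `records`),
#'   `dropped_covariates`, `dropped_subjects`.
#' @export
buildDesign <- function(records, covariates, replication_floor = 5) {
  idx <- match(records$subject_id, covariates$subject_id)
  if (all(is.na(idx))) stop("no covariates for any subject")
  cov <- covariates[idx, setdiff(names(covariates), "subject_id"),
                    drop = FALSE]
  dropped_cov <- character(0)
  keep <- list()
  for (nm in names(cov)) {
    v <- cov[[nm]]
    if (is.numeric(v)) {
      if (var(v, na.rm = TRUE) == 0 || all(is.na(v))) {
        dropped_cov <- c(dropped_cov, nm)
        message("dropping constant covariate: ", nm)
      } else keep[[nm]] <- as.numeric(scale(v))
    } else {
      tab <- table(v)
      if (length(tab) < 2 || any(tab < replication_floor)) {
        dropped_cov <- c(dropped_cov, nm)
        message(sprintf("dropping covariate '%s': level below floor %d",
                        nm, replication_floor))
      } else {
        ref <- names(tab)[which.max(tab)]
        keep[[nm]] <- stats::relevel(factor(v), ref = ref)
      }
    }
  }
  if (length(keep) == 0) stop("empty design: all covariates excluded")
  design <- data.frame(keep, stringsAsFactors = FALSE)
  rownames(design) <- records$subject_id
  ok <- complete.cases(design)
  dropped_subj <- records$subject_id[!ok]
  if (length(dropped_subj))
    message("dropping ", length(dropped_subj), " subjects with missing values")
  list(design = design[ok, , drop = FALSE],
       response_rows = which(ok),
       dropped_covariates = dropped_cov,
       dropped_subjects = dropped_subj)
}

# Per-term type-II F table of an lm fit as a data.frame.
termTable <- function(fit) {
  a <- car::Anova(fit, type = 2)
  a <- a[rownames(a) != "Residuals", , drop = FALSE]
  data.frame(term = rownames(a), sum_sq = a[["Sum Sq"]],
             F_statistic = a[["F value"]], p_value = a[["Pr(>F)"]],
             stringsAsFactors = FALSE)
}

#' Backward-stepwise Gaussian GLM for variability
#'
#' Fits an identity-link Gaussian model of a variability score on the design
#' covariates and simplifies it backwards. In `p_removal` mode (default) the
#' term with the largest type-II F-test p at or above `alpha` is removed and
#' the model refit until every retained term has p below `alpha` (ties in p
#' are broken by removing the lexicographically later term). In `bic_min`
#' mode terms are removed greedily while the model BIC decreases.
#'
#' @param design predictor data.frame (from [buildDesign()]).
#' @param response numeric response (median UniFrac values), same length as
#'   `nrow(design)`.
#' @param alpha retention threshold on per-term p (default 0.05).
#' @param mode `"p_removal"` (default) or `"bic_min"`.
#' @return list of class `GlmFit`: `terms` (data.frame with `term`,
#'   `estimate`, `sum_sq`, `F_statistic`, `p_value`, ordered by F
#'   descending; zero rows when no term survives), `bic`, `r_squared`, `n`,
#'   `candidates`.
#' @export
stepwiseGLM <- function(design, response, alpha = 0.05,
                        mode = c("p_removal", "bic_min")) {
  mode <- match.arg(mode)
  stopifnot(length(response) == nrow(design))
  candidates <- names(design)
  if (nrow(design) < length(candidates) + 5)
    stop("need at least 5 more observations than candidate terms")
  dat <- cbind(.response = response, design)
  fitWith <- function(terms) {
    f <- if (length(terms) == 0) ".response ~ 1"
         else paste(".response ~", paste(terms, collapse = " + "))
    lm(as.formula(f), data = dat)
  }
  terms <- candidates
  fit <- fitWith(terms)
  al <- stats::alias(fit)
  if (!is.null(al$Complete))
    stop("rank-deficient design; aliased terms: ",
         paste(rownames(al$Complete), collapse = ", "))
  if (mode == "p_removal") {
    while (length(terms) > 0) {
      tt <- termTable(fit)
      worst <- max(tt$p_value)
      if (worst < alpha) break
      cand <- sort(tt$term[tt$p_value == worst])
      drop_term <- cand[length(cand)]
      message("removing term '", drop_term, "' (p = ",
              signif(worst, 3), ")")
      terms <- setdiff(terms, drop_term)
      fit <- fitWith(terms)
    }
  } else {
    repeat {
      if (length(terms) == 0) break
      bic0 <- BIC(fit)
      trial <- vapply(terms, function(tm) BIC(fitWith(setdiff(terms, tm))), 0)
      if (min(trial) >= bic0) break
      drop_term <- names(trial)[which.min(trial)]
      terms <- setdiff(terms, drop_term)
      fit <- fitWith(terms)
    }
  }
  if (length(terms) == 0) {
    tt <- data.frame(term = character(0), estimate = numeric(0),
                     sum_sq = numeric(0), F_statistic = numeric(0),
                     p_value = numeric(0))
  } else {
    tt <- termTable(fit)
    cf <- coef(fit)
    tt$estimate <- vapply(tt$term, function(tm) {
      hits <- setdiff(which(startsWith(names(cf), tm)), 1L)
      if (length(hits) == 1) unname(cf[hits]) else NA_real_
    }, 0)
    tt <- tt[order(-tt$F_statistic),
             c("term", "estimate", "sum_sq", "F_statistic", "p_value")]
    rownames(tt) <- NULL
  }
  structure(list(terms = tt, bic = BIC(fit),
                 r_squared = summary(fit)$r.squared, n = nrow(design),
                 candidates = candidates),
            class = "GlmFit")
}

#' @export
print.GlmFit <- function(x, ...) {
  if (nrow(x$terms) == 0) cat("GlmFit: no good model\n")
  else {
    cat(sprintf("GlmFit: %d terms, BIC %.2f, R^2 %.3f\n",
                nrow(x$terms), x$bic, x$r_squared))
    print(x$terms)
  }
  invisible(x)
}

#' Format stepwise fits as a predictor table
#'
#' One block per habitat-by-basis fit: rows ordered by F statistic
#' descending, each carrying the parameter estimate, type-II sum of squares,
#' F, p, model BIC and R-squared. When no term survives the block is a single
#' `"No good model"` row.
#'
#' @param fits named list of `GlmFit` objects; names of the form
#'   `"habitat.basis"` (e.g. `"gut.median_unweighted"`).
#' @return data.frame with columns `habitat`, `basis`, `term`, `estimate`,
#'   `sum_sq`, `F_statistic`, `p_value`, `BIC`, `R2`.
#' @export
reportPredictorTable <- function(fits) {
  if (length(fits) == 0) stop("no fits to report")
  blocks <- lapply(names(fits), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    f <- fits[[nm]]
    if (nrow(f$terms) == 0) {
      data.frame(habitat = parts[1], basis = parts[2], term = "No good model",
                 estimate = NA_real_, sum_sq = NA_real_,
                 F_statistic = NA_real_, p_value = NA_real_,
                 BIC = f$bic, R2 = f$r_squared, stringsAsFactors = FALSE)
    } else {
      data.frame(habitat = parts[1], basis = parts[2], f$terms,
                 BIC = f$bic, R2 = f$r_squared, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, c(blocks, list(make.row.names = FALSE)))
}
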