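#' @importFrom utils read.delim write.table packageVersion
NULL

# Deterministic 31-ary polynomial hash (mod 2^31 - 1), 8 hex digits.
# Stamps outputs with a config fingerprint without external dependencies.
strHash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

configHash <- function(config) {
  strHash(deparse(config[order(names(config))]))
}

#' Write a TSV with a provenance header comment
#'
#' All tabular outputs carry a single `#` comment line recording the package
#' version and a hash of the generating configuration, so that reruns with
#' identical configuration are byte-identical.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param config optional list; hashed into the header.
#' @return `path`, invisibly.
#' @export
writeTSV <- function(df, path, config = NULL) {
  hash <- if (is.null(config)) "none" else configHash(config)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# MicrobiomeStability %s config=%s",
                     as.character(packageVersion("MicrobiomeStability")), hash),
             con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tabular output written by [writeTSV()]
#' @param path file path.
#' @return data.frame.
#' @export
readTSV <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read a phylotype count table
#'
#' The classic dialect is the tab-delimited OTU table: phylotypes as rows,
#' samples as columns, first column the phylotype IDs, an optional trailing
#' `taxonomy` column holding semicolon-delimited lineages. A leading
#' `# Constructed from biom file` comment and a `#OTU ID` header are accepted.
#' The returned [CountTable-class] is oriented samples x phylotypes.
#'
#' @param path file path.
#' @param dialect input dialect; only `"classic_tsv"` is built in.
#' @return A [CountTable-class].
#' @export
readCountTable <- function(path, dialect = c("classic_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^# ", lines)]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  header[1] <- sub("^#OTU ID$", "otu_id", header[1])
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  ncolh <- length(header)
  has_tax <- tolower(header[ncolh]) == "taxonomy"
  sample_ids <- header[seq(2, if (has_tax) ncolh - 1 else ncolh)]
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ID in header: ",
         sample_ids[duplicated(sample_ids)][1])
  otu_ids <- vapply(body, `[`, "", 1)
  if (anyDuplicated(otu_ids))
    stop("duplicated phylotype ID: ", otu_ids[duplicated(otu_ids)][1])
  cells <- lapply(body, function(r) {
    if (length(r) != ncolh)
      stop("row '", r[1], "' has ", length(r), " fields, expected ", ncolh)
    r[seq(2, if (has_tax) ncolh - 1 else ncolh)]
  })
  num <- suppressWarnings(
    matrix(as.numeric(unlist(cells)), nrow = length(body), byrow = TRUE))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-integral or negative count at phylotype '%s', sample '%s'",
                 otu_ids[bad[1, 1]], sample_ids[bad[1, 2]]))
  m <- t(num)
  dimnames(m) <- list(sample_ids, otu_ids)
  tax <- character(0)
  if (has_tax) {
    tax <- vapply(body, `[`, "", ncolh)
    names(tax) <- otu_ids
    tax <- tax[nzchar(tax)]
  }
  message(sprintf("read %d samples x %d phylotypes from %s",
                  nrow(m), ncol(m), path))
  CountTable(m, tax)
}

#' Write a count table in the classic tab-delimited dialect
#'
#' @param table a [CountTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(table, path) {
  m <- counts(table)
  tx <- taxonomy(table)
  df <- data.frame(otu_id = colnames(m), t(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- "#OTU ID"
  if (length(tx))
    df$taxonomy <- ifelse(colnames(m) %in% names(tx), tx[colnames(m)], "")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted newick phylogeny
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' downstream phylogenetic metrics rely on: unique tip labels, non-negative
#' branch lengths (missing lengths become 0, with a message), rooted topology.
#'
#' @param path newick file path.
#' @return an [ape::phylo] tree.
#' @export
readTree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("malformed newick in ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicated tip label: ",
         tree$tip.label[duplicated(tree$tip.label)][1])
  if (is.null(tree$edge.length)) {
    message("tree has no branch lengths; treating all as 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    message(sum(is.na(tree$edge.length)), " missing branch lengths set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in ", path)
  tree
}

#' Write a phylogeny as newick
#' @param tree an [ape::phylo].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Tab-delimited with required columns `sample_id`, `subject_id`, `habitat`
#' and `week`; an optional logical `antibiotic_this_week`; every other column
#' is carried along as a covariate. Habitats are validated against the
#' four-habitat vocabulary (forehead, gut, palm, tongue), weeks must be
#' non-negative integers, and `(subject_id, habitat, week)` must be unique.
#' Blank cells become `NA`; a missing antibiotic flag means "no report",
#' which is distinct from an explicit FALSE.
#'
#' @param path file path.
#' @return data.frame of sample records.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""),
                   check.names = FALSE)
  validateMetadata(df)
}

#' Validate a sample metadata data.frame
#' @param df data.frame with the columns described in [readSampleMetadata()].
#' @return the validated data.frame (week coerced to integer).
#' @export
validateMetadata <- function(df) {
  req <- c("sample_id", "subject_id", "habitat", "week")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  bad_hab <- setdiff(unique(df$habitat), HABITATS)
  if (length(bad_hab))
    stop("unknown habitat '", bad_hab[1], "'; allowed: ",
         paste(HABITATS, collapse = ", "))
  wk <- suppressWarnings(as.numeric(df$week))
  if (any(is.na(wk) | wk < 0 | wk != round(wk)))
    stop("week must be a non-negative integer; offending value: ",
         df$week[which(is.na(wk) | wk < 0 | wk != round(wk))[1]])
  df$week <- as.integer(wk)
  key <- paste(df$subject_id, df$habitat, df$week, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate (subject, habitat, week): (%s, %s, %d)",
                 d$subject_id, d$habitat, d$week))
  }
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id: ", df$sample_id[duplicated(df$sample_id)][1])
  if ("antibiotic_this_week" %in% names(df))
    df$antibiotic_this_week <- as.logical(df$antibiotic_this_week)
  df
}

#' Write sample metadata as TSV
#' @param df metadata data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSampleMetadata <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read / write a labelled square distance matrix
#'
#' The TSV dialect is square: a labelled header row, labels in the first
#' column, distances in the body.
#'
#' @param path file path.
#' @param metric metric name to attach on read.
#' @return [readDistanceMatrix()]: a [DistanceMatrix-class].
#' @export
readDistanceMatrix <- function(path, metric = NA_character_) {
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  colnames(m) <- colnames(df)
  DistanceMatrix(m, metric)
}

#' @rdname readDistanceMatrix
#' @param dm a [DistanceMatrix-class].
#' @export
writeDistanceMatrix <- function(dm, path) {
  m <- as.matrix(dm)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
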