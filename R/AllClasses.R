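#' @import methods
NULL

HABITATS <- c("forehead", "gut", "palm", "tongue")

#' CountTable: a sample-by-phylotype count matrix
#'
#' The central input container: a non-negative integer matrix with samples as
#' rows and phylotypes (OTUs) as columns, plus an optional taxonomy map from
#' phylotype ID to a seven-rank semicolon-delimited Greengenes-style lineage
#' (`k__;p__;c__;o__;f__;g__;s__`).
#'
#' @slot counts integer matrix, samples x phylotypes, with unique dimnames.
#' @slot taxonomy named character vector; names are a subset of the phylotype
#'   IDs, values are lineage strings. May be empty.
#'
#' @seealso [CountTable()], [readCountTable()], [counts()], [taxonomy()]
#' @export
setClass("CountTable",
  representation(counts = "matrix", taxonomy = "character"),
  prototype(counts = matrix(integer(0), 0, 0), taxonomy = character(0))
)

setValidity("CountTable", function(object) {
  m <- object@counts
  msg <- character(0)
  if ((nrow(m) > 0 && is.null(rownames(m))) ||
      (ncol(m) > 0 && is.null(colnames(m))))
    msg <- c(msg, "counts must have sample (row) and phylotype (column) names")
  else {
    if (!is.null(rownames(m)) && anyDuplicated(rownames(m)))
      msg <- c(msg, sprintf("duplicated sample ID: %s",
                            rownames(m)[duplicated(rownames(m))][1]))
    if (!is.null(colnames(m)) && anyDuplicated(colnames(m)))
      msg <- c(msg, sprintf("duplicated phylotype ID: %s",
                            colnames(m)[duplicated(colnames(m))][1]))
  }
  if (!is.numeric(m))
    msg <- c(msg, "counts must be numeric")
  else {
    if (any(is.na(m))) msg <- c(msg, "counts contain NA")
    else {
      if (any(m < 0)) msg <- c(msg, "counts contain negative values")
      if (any(m != round(m))) msg <- c(msg, "counts must be integers")
    }
  }
  tx <- object@taxonomy
  if (length(tx) && !all(names(tx) %in% colnames(m)))
    msg <- c(msg, "taxonomy names must be a subset of phylotype IDs")
  if (length(msg)) msg else TRUE
})

#' Construct a CountTable
#'
#' @param counts numeric matrix of non-negative integer counts
#'   (samples x phylotypes) with dimnames.
#' @param taxonomy optional named character vector of lineage strings.
#' @return A [CountTable-class] object.
#' @examples
#' m <- matrix(c(3L, 1L, 0L, 2L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("OTU_1", "OTU_2")))
#' CountTable(m)
#' @export
CountTable <- function(counts, taxonomy = character(0)) {
  storage.mode(counts) <- "integer"
  new("CountTable", counts = counts, taxonomy = taxonomy)
}

setMethod("show", "CountTable", function(object) {
  cat(sprintf("CountTable: %d samples x %d phylotypes\n",
              nrow(object@counts), ncol(object@counts)))
  cat(sprintf("  taxonomy: %d phylotypes annotated\n", length(object@taxonomy)))
})

#' DistanceMatrix: labelled symmetric community distances
#'
#' A square symmetric matrix of non-negative pairwise community distances with
#' a zero diagonal, tagged with the metric that produced it.
#'
#' @slot values numeric matrix with identical row/column names.
#' @slot metric character scalar naming the distance metric.
#' @seealso [DistanceMatrix()], [pairwiseDistances()]
#' @export
setClass("DistanceMatrix",
  representation(values = "matrix", metric = "character"),
  prototype(values = matrix(numeric(0), 0, 0), metric = NA_character_)
)

setValidity("DistanceMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "row and column labels must be present and identical")
  if (nrow(v) > 0) {
    if (any(v < 0)) msg <- c(msg, "distances must be non-negative")
    if (any(abs(diag(v)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
    if (max(abs(v - t(v))) > 1e-12) msg <- c(msg, "matrix must be symmetric")
  }
  if (length(object@metric) != 1) msg <- c(msg, "metric must be a scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a DistanceMatrix
#'
#' @param values square symmetric numeric matrix with matching dimnames.
#' @param metric name of the distance metric.
#' @return A [DistanceMatrix-class] object.
#' @export
DistanceMatrix <- function(values, metric = NA_character_) {
  new("DistanceMatrix", values = values, metric = metric)
}

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix (%s): %d samples\n",
              object@metric, nrow(object@values)))
})

#' @describeIn CountTable-class number of samples
#' @param x,object a `CountTable` or `DistanceMatrix`
#' @export
setMethod("nrow", "CountTable", function(x) nrow(x@counts))

#' @describeIn CountTable-class number of phylotypes
#' @export
setMethod("ncol", "CountTable", function(x) ncol(x@counts))

#' Accessors for CountTable and DistanceMatrix
#'
#' `counts()` returns the sample-by-phylotype integer matrix; `sampleIDs()`
#' and `phylotypeIDs()` its dimnames; `taxonomy()` the lineage map;
#' `metricName()` the metric behind a `DistanceMatrix`.
#'
#' @param object a [CountTable-class] or [DistanceMatrix-class]
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
#' @rdname accessors
#' @export
setMethod("counts", "CountTable", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setMethod("sampleIDs", "CountTable", function(object) rownames(object@counts))
#' @rdname accessors
#' @export
setMethod("sampleIDs", "DistanceMatrix", function(object) rownames(object@values))

#' @rdname accessors
#' @export
setGeneric("phylotypeIDs", function(object) standardGeneric("phylotypeIDs"))
#' @rdname accessors
#' @export
setMethod("phylotypeIDs", "CountTable", function(object) colnames(object@counts))

#' @rdname accessors
#' @export
setGeneric("taxonomy", function(object) standardGeneric("taxonomy"))
#' @rdname accessors
#' @export
setMethod("taxonomy", "CountTable", function(object) object@taxonomy)

#' @rdname accessors
#' @export
setGeneric("metricName", function(object) standardGeneric("metricName"))
#' @rdname accessors
#' @export
setMethod("metricName", "DistanceMatrix", function(object) object@metric)

#' @export
#' @describeIn DistanceMatrix-class coerce to a base matrix
#' @param x a `DistanceMatrix`
#' @param ... ignored
setMethod("as.matrix", "DistanceMatrix", function(x, ...) x@values)

#' Subset a CountTable by samples and/or phylotypes
#'
#' @param x a [CountTable-class]
#' @param i sample indices or IDs
#' @param j phylotype indices or IDs
#' @param ...,drop ignored
#' @return a [CountTable-class]
#' @export
setMethod("[", "CountTable", function(x, i, j, ..., drop = FALSE) {
  m <- x@counts
  if (!missing(i)) m <- m[i, , drop = FALSE]
  if (!missing(j)) m <- m[, j, drop = FALSE]
  tx <- x@taxonomy[names(x@taxonomy) %in% colnames(m)]
  CountTable(m, tx)
})
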