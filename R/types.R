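# Core S3 containers. The algebra objects are dimnamed matrices wrapped in
# light classes; every derived report in the package is a tibble.

CONTINUOUS_KINDS <- c("EXPR", "CNV")
BINARY_KINDS <- c("MUT", "CHEM", "TRGT", "KEGG")
FEATURE_KINDS <- c(CONTINUOUS_KINDS, BINARY_KINDS)

#' Construct a cell line by drug response matrix
#'
#' Wraps a labelled numeric matrix of log IC50 values. `NA` entries mark
#' unobserved cell line-drug pairs; the observed-entry mask is derived from
#' them and carried alongside the values.
#'
#' @param values Numeric matrix with unique row names (cell lines) and
#'   column names (drugs). `NA` marks an unknown response.
#' @return A `response_matrix` object: list with `values` (matrix) and
#'   `observed` (logical matrix of the same shape).
#' @export
response_matrix <- function(values) {
  values <- as_labelled_matrix(values, "response matrix")
  obs <- !is.na(values)
  if (!all(is.finite(values[obs]))) {
    stop("response matrix contains non-finite observed entries", call. = FALSE)
  }
  structure(list(values = values, observed = obs), class = "response_matrix")
}

#' Construct a labelled feature table
#'
#' @param values Numeric matrix, entities in rows, features in columns, with
#'   unique dimnames. `NA` marks a missing measurement.
#' @param kind Feature kind: `"EXPR"` or `"CNV"` (continuous) or one of
#'   `"MUT"`, `"CHEM"`, `"TRGT"`, `"KEGG"` (binary).
#' @return A `feature_table` object with fields `values` and `kind`.
#' @export
feature_table <- function(values, kind) {
  kind <- match.arg(kind, FEATURE_KINDS)
  values <- as_labelled_matrix(values, sprintf("%s feature table", kind))
  if (kind == "EXPR" && anyNA(values)) {
    stop("expression tables must be fully observed", call. = FALSE)
  }
  if (kind %in% BINARY_KINDS) {
    ok <- is.na(values) | values %in% c(0, 1)
    if (!all(ok)) {
      bad <- which(!ok, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "binary feature table '%s' has non-binary value at [%s, %s]",
        kind, rownames(values)[bad[1]], colnames(values)[bad[2]]
      ), call. = FALSE)
    }
  }
  structure(list(values = values, kind = kind), class = "feature_table")
}

#' Construct a similarity matrix
#'
#' @param values Square symmetric numeric matrix with matching, unique
#'   row/column names.
#' @param kind Feature kind the similarity derives from.
#' @param normalized Logical; `TRUE` once the symmetric normalized Laplacian
#'   transform of [normalize_similarity()] has been applied.
#' @return A `similarity_matrix` object.
#' @export
similarity_matrix <- function(values, kind, normalized = FALSE) {
  kind <- match.arg(kind, FEATURE_KINDS)
  values <- as_labelled_matrix(values, "similarity matrix")
  if (nrow(values) != ncol(values) ||
      !identical(rownames(values), colnames(values))) {
    stop("similarity matrix must be square with matching dimnames", call. = FALSE)
  }
  if (anyNA(values)) stop("similarity matrix has missing entries", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-10) {
    stop("similarity matrix is not symmetric (tolerance 1e-10)", call. = FALSE)
  }
  if (!normalized) {
    rng <- range(values)
    lo <- if (kind %in% BINARY_KINDS) 0 else -1
    if (rng[1] < lo - 1e-12 || rng[2] > 1 + 1e-12) {
      stop(sprintf("raw %s similarities outside [%g, 1]", kind, lo), call. = FALSE)
    }
  }
  structure(
    list(values = values, kind = kind, normalized = normalized),
    class = "similarity_matrix"
  )
}

#' Construct a gene set collection
#'
#' @param sets Named list of character vectors (pathway name -> genes).
#' @return A `gene_set_collection`: named list of unique gene vectors.
#' @export
gene_set_collection <- function(sets) {
  nm <- names(sets)
  if (length(sets) > 0 && (is.null(nm) || anyDuplicated(nm) || any(nm == ""))) {
    stop("gene sets must have unique non-empty names", call. = FALSE)
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0)) stop("gene sets must be non-empty", call. = FALSE)
  structure(sets, class = "gene_set_collection")
}

#' Construct a cell line to tissue annotation
#'
#' @param cell Character vector of unique cell line labels.
#' @param tissue Character vector of tissue labels, recycled against `cell`.
#' @return A tibble with columns `cell` and `tissue`, class `tissue_annotation`.
#' @export
tissue_annotation <- function(cell, tissue) {
  cell <- as.character(cell)
  tissue <- as.character(tissue)
  if (anyDuplicated(cell)) stop("cell labels must be unique", call. = FALSE)
  if (any(is.na(tissue) | tissue == "")) {
    stop("tissue labels must be non-empty", call. = FALSE)
  }
  out <- tibble::tibble(cell = cell, tissue = tissue)
  class(out) <- c("tissue_annotation", class(out))
  out
}

# Coerce to a numeric matrix with unique dimnames.
as_labelled_matrix <- function(values, what) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop(sprintf("%s must be a numeric matrix", what), call. = FALSE)
  }
  rn <- rownames(values)
  cn <- colnames(values)
  if (is.null(rn) || is.null(cn)) {
    stop(sprintf("%s must have row and column names", what), call. = FALSE)
  }
  if (anyDuplicated(rn) || anyDuplicated(cn)) {
    stop(sprintf("%s has duplicate labels", what), call. = FALSE)
  }
  values
}

# Pull the numeric matrix out of any wrapped container (or pass one through).
values_of <- function(x) {
  if (inherits(x, c("response_matrix", "feature_table", "similarity_matrix"))) {
    return(x$values)
  }
  as_labelled_matrix(x, "input")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf(
    "<response_matrix> %d cell lines x %d drugs, %d/%d observed\n",
    nrow(x$values), ncol(x$values), sum(x$observed), length(x$observed)
  ))
  invisible(x)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table:%s> %d entities x %d features, %d missing\n",
    x$kind, nrow(x$values), ncol(x$values), sum(is.na(x$values))
  ))
  invisible(x)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf(
    "<similarity_matrix:%s%s> %d x %d\n",
    x$kind, if (x$normalized) " (normalized)" else "", nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}
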