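# Missing-data filtering and expression-distance-weighted KNN imputation.
#
# The neighbour weights follow the method's printed definition exactly:
# alpha_i = D(c, c_i) / sum_j D(c, c_j) over the neighbour set, i.e.
# proportional to the (squared Euclidean) expression distance. That makes
# farther neighbours weigh more; `neighbor_weighting` exposes the
# inverse-distance and uniform alternatives without changing the default.

#' Imputation configuration
#'
#' @param n_neighbors Number of nearest cell lines used per imputation
#'   (default 10); clipped to `n - 1` on small datasets.
#' @param feature_drop_fraction Drop a feature missing in strictly more than
#'   this fraction of entities (default 0.5).
#' @param sample_drop_fraction Then drop an entity missing strictly more than
#'   this fraction of the surviving features (default 0.5).
#' @param neighbor_weighting `"as_printed"` (distance-proportional weights,
#'   the default), `"inverse_distance"`, or `"uniform"`.
#' @return A list of validated settings, class `imputation_config`.
#' @export
imputation_config <- function(n_neighbors = 10,
                              feature_drop_fraction = 0.5,
                              sample_drop_fraction = 0.5,
                              neighbor_weighting = c("as_printed",
                                                     "inverse_distance",
                                                     "uniform")) {
  stopifnot(n_neighbors >= 1,
            feature_drop_fraction > 0, feature_drop_fraction <= 1,
            sample_drop_fraction > 0, sample_drop_fraction <= 1)
  structure(list(
    n_neighbors = as.integer(n_neighbors),
    feature_drop_fraction = feature_drop_fraction,
    sample_drop_fraction = sample_drop_fraction,
    neighbor_weighting = match.arg(neighbor_weighting)
  ), class = "imputation_config")
}

#' Drop heavily missing features, then heavily missing entities
#'
#' Features missing in strictly more than `feature_drop_fraction` of entities
#' are removed first; entities missing strictly more than
#' `sample_drop_fraction` of the remaining features are removed second.
#' Label order is preserved.
#'
#' @param table A [feature_table()].
#' @param config An [imputation_config()].
#' @return The filtered [feature_table()].
#' @export
filter_missing <- function(table, config = imputation_config()) {
  stopifnot(inherits(table, "feature_table"))
  v <- table$values
  keep_f <- colMeans(is.na(v)) <= config$feature_drop_fraction
  if (!any(keep_f)) stop("all features dropped by missingness filter", call. = FALSE)
  v <- v[, keep_f, drop = FALSE]
  keep_e <- rowMeans(is.na(v)) <= config$sample_drop_fraction
  feature_table(v[keep_e, , drop = FALSE], table$kind)
}

#' Squared Euclidean distance between two expression profiles
#'
#' @param expr A fully observed `EXPR` [feature_table()].
#' @param cell_a,cell_b Cell line labels present in `expr`.
#' @return Nonnegative scalar, the squared L2 norm of the profile difference.
#' @export
expression_distance <- function(expr, cell_a, cell_b) {
  stopifnot(inherits(expr, "feature_table"), expr$kind == "EXPR")
  e <- expr$values
  for (lab in c(cell_a, cell_b)) {
    if (!lab %in% rownames(e)) {
      stop(sprintf("unknown cell line '%s'", lab), call. = FALSE)
    }
  }
  sum((e[cell_a, ] - e[cell_b, ])^2)
}

# Pairwise squared L2 distances between rows of a matrix.
squared_distances <- function(e) {
  g <- tcrossprod(e)
  sq <- diag(g)
  d <- outer(sq, sq, `+`) - 2 * g
  d[d < 0] <- 0
  d
}

# For every cell, the ordered labels of its n_neighbors nearest cells by
# squared expression distance (ties broken by input label order) plus the
# matching distances. Computed once and reused across all imputed columns.
neighbor_sets <- function(expr_values, n_neighbors) {
  n <- nrow(expr_values)
  k <- min(n_neighbors, n - 1L)
  d <- squared_distances(expr_values)
  labs <- rownames(expr_values)
  sets <- lapply(seq_len(n), function(i) {
    ord <- order(d[i, -i])  # stable: ties keep input label order
    others <- setdiff(seq_len(n), i)[ord][seq_len(k)]
    list(labels = labs[others], dist = d[i, others])
  })
  names(sets) <- labs
  sets
}

# alpha weights over usable neighbours under the configured scheme.
neighbor_weights <- function(dist, weighting) {
  if (weighting == "uniform" || all(dist == 0)) {
    return(rep(1 / length(dist), length(dist)))
  }
  w <- switch(weighting,
    as_printed = dist,
    inverse_distance = 1 / pmax(dist, .Machine$double.eps)
  )
  if (sum(w) == 0) return(rep(1 / length(dist), length(dist)))
  w / sum(w)
}

impute_matrix <- function(values, expr, config, combine) {
  e <- expr$values
  if (!all(rownames(values) %in% rownames(e))) {
    missing <- setdiff(rownames(values), rownames(e))
    stop(sprintf("cell line '%s' absent from expression table", missing[1]),
         call. = FALSE)
  }
  if (nrow(e) < 2) stop("imputation needs at least 2 cell lines", call. = FALSE)
  nn <- neighbor_sets(e, config$n_neighbors)
  out <- values
  for (i in seq_len(nrow(values))) {
    miss_cols <- which(is.na(values[i, ]))
    if (length(miss_cols) == 0) next
    set <- nn[[rownames(values)[i]]]
    nb_rows <- values[set$labels, , drop = FALSE]
    for (j in miss_cols) {
      usable <- which(!is.na(nb_rows[, j]))
      if (length(usable) == 0) {
        stop(sprintf(
          "no usable neighbours to impute entry [%s, %s]",
          rownames(values)[i], colnames(values)[j]
        ), call. = FALSE)
      }
      out[i, j] <- combine(nb_rows[usable, j], set$dist[usable], config)
    }
  }
  out
}

#' Impute missing continuous values by weighted nearest neighbours
#'
#' Each missing entry is replaced by a weighted mean of the same column over
#' the cell's nearest neighbours in expression space, skipping neighbours
#' whose own entry is missing and renormalizing the weights. Works on a
#' response matrix (log IC50) or a continuous `CNV` feature table.
#'
#' @param target A [response_matrix()] or `CNV` [feature_table()] with rows
#'   indexed by cell line.
#' @param expr A fully observed `EXPR` [feature_table()] covering all cells
#'   in `target`.
#' @param config An [imputation_config()].
#' @return `target` with every entry observed (same class as the input).
#' @export
impute_continuous <- function(target, expr, config = imputation_config()) {
  stopifnot(inherits(expr, "feature_table"), expr$kind == "EXPR")
  combine <- function(vals, dist, cfg) {
    sum(neighbor_weights(dist, cfg$neighbor_weighting) * vals)
  }
  if (inherits(target, "response_matrix")) {
    v <- target$values
    v[!target$observed] <- NA_real_
    response_matrix(impute_matrix(v, expr, config, combine))
  } else {
    stopifnot(inherits(target, "feature_table"),
              target$kind %in% CONTINUOUS_KINDS)
    feature_table(impute_matrix(target$values, expr, config, combine),
                  target$kind)
  }
}

#' Impute missing mutation calls by neighbour majority vote
#'
#' A missing status becomes 1 iff mutated neighbours strictly outnumber
#' wild-type neighbours among the cell's nearest expression neighbours with
#' an observed status; ties give 0.
#'
#' @param target A binary `MUT` [feature_table()].
#' @inheritParams impute_continuous
#' @return A fully observed `MUT` [feature_table()].
#' @export
impute_binary <- function(target, expr, config = imputation_config()) {
  stopifnot(inherits(target, "feature_table"), target$kind %in% BINARY_KINDS,
            inherits(expr, "feature_table"), expr$kind == "EXPR")
  combine <- function(vals, dist, cfg) {
    as.numeric(sum(vals) > sum(1 - vals))
  }
  feature_table(impute_matrix(target$values, expr, config, combine),
                target$kind)
}
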