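# Pairwise similarity matrices from feature tables, and the symmetric
# normalized Laplacian transform used to scale them before factorization.

#' Pearson correlation of two numeric vectors
#'
#' @param x,y Numeric vectors of equal length >= 2 with nonzero variance.
#' @return Scalar correlation in \[-1, 1\].
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("pcc needs two vectors of equal length >= 2", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("pcc undefined for a zero-variance vector", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Jaccard index of two binary vectors
#'
#' `|intersection| / |union|` of the supports.
#'
#' @param x,y Binary (0/1) vectors of equal length, not both all-zero.
#' @return Scalar in \[0, 1\].
#' @export
jaccard <- function(x, y) {
  if (length(x) != length(y)) stop("jaccard needs equal lengths", call. = FALSE)
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1))) {
    stop("jaccard needs binary vectors", call. = FALSE)
  }
  inter <- sum(x * y)
  union <- sum(x + y) - inter
  if (union == 0) stop("jaccard undefined for two all-zero vectors", call. = FALSE)
  inter / union
}

#' Build a raw similarity matrix from a feature table
#'
#' Continuous kinds (`EXPR`, `CNV`) use Pearson correlation between entity
#' profiles; binary kinds (`MUT`, `CHEM`, `TRGT`, `KEGG`) use the Jaccard
#' index. Degenerate profiles (zero variance for the continuous kinds,
#' all-zero for the binary ones) are an error naming the entity.
#'
#' @param features A fully observed [feature_table()] with >= 2 entities.
#' @return A raw [similarity_matrix()] over the entity labels.
#' @export
build_similarity <- function(features) {
  stopifnot(inherits(features, "feature_table"))
  v <- features$values
  if (anyNA(v)) stop("feature table must be fully observed", call. = FALSE)
  if (nrow(v) < 2) stop("similarity needs >= 2 entities", call. = FALSE)
  if (features$kind %in% CONTINUOUS_KINDS) {
    degen <- which(apply(v, 1, stats::var) == 0)
    if (length(degen) > 0) {
      stop(sprintf("entity '%s' has a constant profile (PCC undefined)",
                   rownames(v)[degen[1]]), call. = FALSE)
    }
    s <- stats::cor(t(v))
  } else {
    support <- rowSums(v)
    if (any(support == 0)) {
      stop(sprintf("entity '%s' has an all-zero profile (Jaccard undefined)",
                   rownames(v)[which(support == 0)[1]]), call. = FALSE)
    }
    inter <- tcrossprod(v)
    union <- outer(support, support, `+`) - inter
    s <- inter / union
  }
  s <- (s + t(s)) / 2  # remove numeric asymmetry
  diag(s) <- 1
  similarity_matrix(s, features$kind, normalized = FALSE)
}

#' Normalize a similarity matrix by its symmetric normalized Laplacian
#'
#' For raw similarity `S` with degree matrix `D` (`D_ii = sum_j S_ij`),
#' returns `D^{-1/2} (D - S) D^{-1/2}`. Row sums must be strictly positive;
#' a zero or negative degree (possible when correlation similarities are
#' predominantly negative) is a hard error.
#'
#' @param S A raw [similarity_matrix()].
#' @return The normalized [similarity_matrix()] (`normalized = TRUE`).
#' @export
normalize_similarity <- function(S) {
  stopifnot(inherits(S, "similarity_matrix"))
  if (S$normalized) stop("similarity is already normalized", call. = FALSE)
  v <- S$values
  deg <- rowSums(v)
  if (any(deg == 0)) {
    stop(sprintf("zero row sum for entity '%s': Laplacian scaling undefined",
                 rownames(v)[which(deg == 0)[1]]), call. = FALSE)
  }
  if (any(deg < 0)) {
    stop(sprintf("negative row sum for entity '%s': D^{-1/2} undefined",
                 rownames(v)[which(deg < 0)[1]]), call. = FALSE)
  }
  inv_sqrt <- 1 / sqrt(deg)
  lap <- diag(deg, nrow = length(deg)) - v
  out <- inv_sqrt * lap * rep(inv_sqrt, each = length(deg))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(v)
  similarity_matrix(out, S$kind, normalized = TRUE)
}
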