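# Seeded generator of pipeline-shaped datasets with known ground truth.
# Cells sharing a tissue cluster draw their latent rows around a shared
# centre, so tissue-wise redundancy removal and the similarity constraints
# have real structure to find; expression is a strictly positive (exponated)
# linear image of the cell latents, so pathway activity scoring applies.

#' Simulate a full drug-response dataset with known ground truth
#'
#' Generates latent factors `P` (cells, clustered by tissue) and `Q`
#' (drugs), a response matrix `P Q^T` plus Gaussian noise with a random
#' missing mask, strictly positive expression and continuous copy-number
#' tables driven by the cell latents, binary mutation and drug feature
#' tables (thresholded latent images with guaranteed nonzero support), a
#' tissue annotation matching the latent clusters, and random gene sets.
#'
#' @param n,m Numbers of cell lines and drugs (defaults 100 and 20).
#' @param n_genes Number of genes in the expression/CNV/mutation tables
#'   (default 200).
#' @param k True latent rank (default 5).
#' @param sigma Response noise standard deviation (default 0.1).
#' @param missing_fraction Fraction of response entries masked (default 0.2).
#' @param n_tissues Number of tissue clusters (default 8).
#' @param n_drug_features Length of each binary drug feature vector
#'   (default 60).
#' @param n_pathways Number of simulated gene sets (default 15).
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of it.
#' @return A `synthetic_dataset`: list with `truth_P`, `truth_Q`,
#'   `response` ([response_matrix()]), `expr`, `cnv`, `mut`
#'   ([feature_table()]s), `chem`, `trgt`, `kegg` (binary drug
#'   [feature_table()]s), `tissues` ([tissue_annotation()]), `gene_sets`
#'   ([gene_set_collection()]) and `params`.
#' @export
simulate_dataset <- function(n = 100, m = 20, n_genes = 200, k = 5,
                             sigma = 0.1, missing_fraction = 0.2,
                             n_tissues = 8, n_drug_features = 60,
                             n_pathways = 15, seed = 1L) {
  stopifnot(n >= 2, m >= 2, k >= 1, k <= min(n, m), sigma >= 0,
            missing_fraction >= 0, missing_fraction < 1, n_tissues >= 1)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)

  cells <- sprintf("cell%03d", seq_len(n))
  drugs <- sprintf("drug%02d", seq_len(m))
  genes <- sprintf("g%04d", seq_len(n_genes))

  tissue_of <- sort(rep_len(seq_len(n_tissues), n))
  centres <- matrix(stats::rnorm(n_tissues * k, sd = 1), n_tissues, k)
  truth_P <- centres[tissue_of, , drop = FALSE] +
    matrix(stats::rnorm(n * k, sd = 0.35), n, k)
  truth_Q <- matrix(stats::rnorm(m * k, sd = 1), m, k)
  rownames(truth_P) <- cells
  rownames(truth_Q) <- drugs

  resp <- tcrossprod(truth_P, truth_Q) +
    matrix(stats::rnorm(n * m, sd = sigma), n, m)
  dimnames(resp) <- list(cells, drugs)
  n_mask <- round(missing_fraction * n * m)
  if (n_mask > 0) resp[sample(n * m, n_mask)] <- NA_real_

  # Expression: per-gene baselines shared by all cells plus a latent image,
  # exponentiated so values are strictly positive. The baselines dominate,
  # so cell-cell expression correlations are high and positive, as they are
  # for real transcriptomes (and as the Laplacian scaling requires).
  base_e <- stats::rnorm(n_genes, sd = 2)
  W_e <- matrix(stats::rnorm(k * n_genes, sd = 0.35), k, n_genes)
  expr <- exp(rep(base_e, each = n) + truth_P %*% W_e +
                matrix(stats::rnorm(n * n_genes, sd = 0.25), n, n_genes))
  dimnames(expr) <- list(cells, genes)

  # CNV: same structure on the raw scale (shared per-gene baseline keeps
  # between-cell correlations predominantly positive).
  base_c <- stats::rnorm(n_genes, sd = 2)
  W_c <- matrix(stats::rnorm(k * n_genes, sd = 0.35), k, n_genes)
  cnv <- rep(base_c, each = n) + truth_P %*% W_c +
    matrix(stats::rnorm(n * n_genes, sd = 0.25), n, n_genes)
  dimnames(cnv) <- list(cells, genes)

  W_m <- matrix(stats::rnorm(k * n_genes, sd = 1), k, n_genes)
  mut_latent <- truth_P %*% W_m
  mut <- (mut_latent > stats::quantile(mut_latent, 0.85)) * 1
  dimnames(mut) <- list(cells, genes)
  mut <- ensure_support(mut, mut_latent)

  drug_feature <- function(sd_w, density) {
    W <- matrix(stats::rnorm(k * n_drug_features, sd = sd_w),
                k, n_drug_features)
    latent <- truth_Q %*% W
    f <- (latent > stats::quantile(latent, 1 - density)) * 1
    dimnames(f) <- list(drugs, sprintf("f%03d", seq_len(n_drug_features)))
    ensure_support(f, latent)
  }
  chem <- drug_feature(1, 0.10)
  trgt <- drug_feature(0.8, 0.10)
  kegg <- drug_feature(1.2, 0.10)

  gene_sets <- gene_set_collection(stats::setNames(
    lapply(seq_len(n_pathways), function(i) {
      sample(genes, sample(5:15, 1))
    }),
    sprintf("PW%02d", seq_len(n_pathways))
  ))

  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  structure(list(
    truth_P = truth_P, truth_Q = truth_Q,
    response = response_matrix(resp),
    expr = feature_table(expr, "EXPR"),
    cnv = feature_table(cnv, "CNV"),
    mut = feature_table(mut, "MUT"),
    chem = feature_table(chem, "CHEM"),
    trgt = feature_table(trgt, "TRGT"),
    kegg = feature_table(kegg, "KEGG"),
    tissues = tissue_annotation(cells, sprintf("tissue%02d", tissue_of)),
    gene_sets = gene_sets,
    params = list(n = n, m = m, n_genes = n_genes, k = k, sigma = sigma,
                  missing_fraction = missing_fraction, n_tissues = n_tissues,
                  seed = seed)
  ), class = "synthetic_dataset")
}

# Guarantee every row of a binary matrix has nonzero support by switching on
# the entry with the largest latent signal where needed (Jaccard stays
# defined for every entity).
ensure_support <- function(bin, latent) {
  empty <- which(rowSums(bin) == 0)
  for (i in empty) bin[i, which.max(latent[i, ])] <- 1
  bin
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<synthetic_dataset> %d cells x %d drugs (rank %d, sigma %g, %.0f%% masked, seed %d)\n",
    p$n, p$m, p$k, p$sigma, 100 * p$missing_fraction, p$seed
  ))
  invisible(x)
}

#' Mask a random fraction of a feature table
#'
#' @param table A [feature_table()]; `EXPR` tables are refused (the pipeline
#'   assumes complete expression).
#' @param fraction Fraction of entries to mask, in `[0, 1)`.
#' @param seed Integer seed.
#' @return The table with `round(fraction * length)` entries set missing.
#' @export
inject_missing <- function(table, fraction, seed = 1L) {
  stopifnot(inherits(table, "feature_table"),
            fraction >= 0, fraction < 1)
  if (table$kind == "EXPR") {
    stop("refusing to inject missingness into an expression table", call. = FALSE)
  }
  if (fraction == 0) return(table)
  v <- table$values
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  idx <- sample(length(v), round(fraction * length(v)))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  v[idx] <- NA_real_
  feature_table(v, table$kind)
}
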