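# In-code fixtures shared across the suite.

# Labelled matrix with deterministic content.
lab_matrix <- function(n, m, prefix = c("r", "c"), fill = NULL, seed = 1) {
  set.seed(seed)
  v <- if (is.null(fill)) matrix(rnorm(n * m), n, m) else matrix(fill, n, m)
  dimnames(v) <- list(paste0(prefix[1], seq_len(n)), paste0(prefix[2], seq_len(m)))
  v
}

# Small strictly positive expression table.
toy_expr <- function(n = 6, g = 8, seed = 1) {
  set.seed(seed)
  v <- matrix(exp(rnorm(n * g, sd = 0.5)), n, g,
              dimnames = list(paste0("c", seq_len(n)), paste0("g", seq_len(g))))
  feature_table(v, "EXPR")
}

# Binary table with guaranteed nonzero row support.
toy_binary <- function(n = 5, f = 10, kind = "MUT", seed = 2) {
  set.seed(seed)
  v <- matrix(rbinom(n * f, 1, 0.3), n, f,
              dimnames = list(paste0("e", seq_len(n)), paste0("f", seq_len(f))))
  empty <- rowSums(v) == 0
  v[empty, 1] <- 1
  feature_table(v, kind)
}

# Reference Pearson correlation written from the covariance formula directly
# (oracle, independent of stats::cor).
pcc_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    (sqrt(sum((x - mean(x))^2)) * sqrt(sum((y - mean(y))^2)))
}

# Brute-force similarity matrix by double loop.
similarity_oracle <- function(ft) {
  v <- ft$values
  fun <- if (ft$kind %in% c("EXPR", "CNV")) pcc_oracle else
    function(a, b) sum(a * b) / (sum(a + b) - sum(a * b))
  n <- nrow(v)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(n)) for (j in seq_len(n)) out[i, j] <- fun(v[i, ], v[j, ])
  out
}

# Loss evaluated by literal summation loops (oracle for mf_loss and for
# finite-difference gradient checks).
loss_oracle <- function(values, mask, P, Q, sc, sdm, mu, lambda) {
  acc <- 0
  for (i in seq_len(nrow(values))) for (j in seq_len(ncol(values))) {
    if (mask[i, j]) acc <- acc + 0.5 * (values[i, j] - sum(P[i, ] * Q[j, ]))^2
  }
  acc <- acc + mu / 2 * (sum(P^2) + sum(Q^2))
  man <- function(X, S) {
    tot <- 0
    for (i in seq_len(nrow(X))) for (j in seq_len(nrow(X))) {
      tot <- tot + sum((X[i, ] - X[j, ])^2) * S[i, j]
    }
    tot
  }
  acc + lambda / 2 * (man(P, sc) + man(Q, sdm))
}

# Small response matrix + aligned raw similarities for factorization tests.
toy_problem <- function(n = 12, m = 6, k = 2, sigma = 0.05,
                        missing_fraction = 0.15, seed = 3) {
  d <- simulate_dataset(n = n, m = m, n_genes = 40, k = k, sigma = sigma,
                        missing_fraction = missing_fraction, n_tissues = 3,
                        n_drug_features = 20, n_pathways = 4, seed = seed)
  list(d = d,
       simC = build_similarity(d$expr),
       simD = build_similarity(d$chem))
}

# Oracle: literal rule evaluation for redundancy removal.
redundancy_oracle <- function(sim, tissues, theta) {
  removed <- character(0)
  for (t in unique(tissues$tissue)) {
    cells <- tissues$cell[tissues$tissue == t]
    if (length(cells) < 2) next
    pairs <- c()
    for (a in seq_along(cells)) for (b in seq_along(cells)) {
      if (a < b) pairs <- c(pairs, sim[cells[a], cells[b]])
    }
    q3 <- quantile(pairs, 0.75, type = 7, names = FALSE)
    for (cc in cells) {
      cnt <- sum(vapply(setdiff(cells, cc),
                        function(o) sim[cc, o] > q3, logical(1)))
      if (cnt > theta * length(cells)) removed <- c(removed, cc)
    }
  }
  removed
}

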