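test_that("the loss matches a literal summation oracle, masked entries excluded", {
  p <- toy_problem(seed = 41)
  v <- p$d$response$values
  mask <- p$d$response$observed
  k <- 3
  set.seed(5)
  P <- matrix(rnorm(nrow(v) * k), nrow(v), k)
  Q <- matrix(rnorm(ncol(v) * k), ncol(v), k)
  sc <- p$simC$values; sdm <- p$simD$values
  expect_equal(mf_loss(p$d$response, P, Q, sc, sdm, mu = 0.7, lambda = 0.3),
               loss_oracle(v, mask, P, Q, sc, sdm, 0.7, 0.3),
               tolerance = 1e-10)
  # hand case: R=[[2]], P=Q=[[1]], mu=2, lambda=0 -> 1/2 + 1*(1+1) = 2.5
  r1 <- response_matrix(matrix(2, 1, 1, dimnames = list("c1", "d1")))
  one <- matrix(1, 1, 1, dimnames = list("c1", "c1"))
  expect_equal(mf_loss(r1, matrix(1), matrix(1), one, one, mu = 2, lambda = 0), 2.5)
  expect_equal(mf_loss(r1, matrix(2), matrix(1), one, one, mu = 0, lambda = 0), 0)
  # identical latent rows null the manifold term
  Pc <- matrix(1, nrow(v), k); Qc <- matrix(1, ncol(v), k)
  expect_equal(mf_loss(p$d$response, Pc, Qc, sc, sdm, 0, 5),
               mf_loss(p$d$response, Pc, Qc, sc, sdm, 0, 0))
})

test_that("block gradients match central finite differences of the loss", {
  p <- toy_problem(seed = 43)
  v <- p$d$response$values; mask <- p$d$response$observed
  k <- 2
  set.seed(7)
  P <- matrix(rnorm(nrow(v) * k), nrow(v), k)
  Q <- matrix(rnorm(ncol(v) * k), ncol(v), k)
  sc <- p$simC$values; sdm <- p$simD$values
  s_sym <- respmf:::sym_offdiag(sc)
  mu <- 0.9; lambda <- 0.4
  delta <- 1e-6
  for (i in c(1, 5, nrow(v))) {
    gh <- respmf:::block_gradient_hessian(P[i, ], i, v[i, ], which(mask[i, ]),
                                          Q, P, s_sym, mu, lambda)
    for (dim_ in 1:k) {
      Pp <- P; Pp[i, dim_] <- P[i, dim_] + delta
      Pm <- P; Pm[i, dim_] <- P[i, dim_] - delta
      num <- (loss_oracle(v, mask, Pp, Q, sc, sdm, mu, lambda) -
                loss_oracle(v, mask, Pm, Q, sc, sdm, mu, lambda)) / (2 * delta)
      expect_equal(gh$gradient[dim_], num, tolerance = 1e-5)
    }
    # lambda = 0, full mask: Hessian reduces to Q^T Q + mu I
    gh0 <- respmf:::block_gradient_hessian(P[i, ], i, v[i, ], seq_len(ncol(v)),
                                           Q, P, s_sym, mu, 0)
    expect_equal(gh0$hessian, crossprod(Q) + mu * diag(k), tolerance = 1e-12)
  }
})

test_that("one block update lands on the exact row minimizer", {
  p <- toy_problem(seed = 47)
  v <- p$d$response$values; mask <- p$d$response$observed
  k <- 2
  set.seed(9)
  P <- matrix(rnorm(nrow(v) * k), nrow(v), k)
  Q <- matrix(rnorm(ncol(v) * k), ncol(v), k)
  s_sym <- respmf:::sym_offdiag(p$simC$values)
  v0 <- v; v0[!mask] <- 0
  newP <- respmf:::update_factor(P, Q, v0, mask, s_sym, 0.8, 0.3, "derived")
  # the sweep is Gauss-Seidel, so exact stationarity holds for the last row,
  # whose update saw every other row in its final state
  i <- nrow(v)
  gh <- respmf:::block_gradient_hessian(newP[i, ], i, v[i, ], which(mask[i, ]),
                                        Q, newP, s_sym, 0.8, 0.3)
  expect_lt(sqrt(sum(gh$gradient^2)), 1e-8)
  # lambda = 0 reduces to row-wise ridge least squares
  ridge <- respmf:::update_factor(P, Q, v0, mask, s_sym, 0.8, 0, "derived")
  for (i in seq_len(nrow(v))) {
    obs <- which(mask[i, ])
    Qo <- Q[obs, , drop = FALSE]
    expect_equal(ridge[i, ],
                 solve(crossprod(Qo) + 0.8 * diag(k),
                       as.numeric(crossprod(Qo, v[i, obs]))),
                 tolerance = 1e-10)
  }
})

test_that("derived updates never increase the loss on seeded random instances", {
  # raw (nonnegative) similarities keep every block Hessian PD
  n_bad <- 0
  for (seed in 1:100) {
    set.seed(seed)
    n <- 8; m <- 5; k <- 2
    v <- lab_matrix(n, m, prefix = c("c", "d"), seed = seed)
    mask <- matrix(runif(n * m) > 0.2, n, m)
    mask[cbind(seq_len(n), sample(m, n, replace = TRUE))] <- TRUE
    v[!mask] <- NA
    R <- response_matrix(v)
    sc <- build_similarity(toy_binary(n, 12, "MUT", seed = seed))$values
    sdm <- build_similarity(toy_binary(m, 12, "CHEM", seed = seed + 500))$values
    dimnames(sc) <- list(rownames(v), rownames(v))
    dimnames(sdm) <- list(colnames(v), colnames(v))
    h <- mf_hyperparams(k_percent = 40, mu = 0.5, lambda = 0.5, seed = seed,
                        use_normalized_similarity = FALSE, max_iter = 6,
                        epsilon = 1e-9)
    fit <- fit_manifold(R, sc, sdm, h)
    if (any(diff(fit$loss_trace) > 1e-8)) n_bad <- n_bad + 1
  }
  expect_equal(n_bad, 0)
})

test_that("exact factorization regime reproduces the matrix to 1e-6", {
  # lambda = mu = 0, full mask, k = min(n, m)
  set.seed(13)
  v <- lab_matrix(9, 4, prefix = c("c", "d"), seed = 13)
  R <- response_matrix(v)
  sc <- diag(9); dimnames(sc) <- list(rownames(v), rownames(v))
  sdm <- diag(4); dimnames(sdm) <- list(colnames(v), colnames(v))
  h <- mf_hyperparams(k_percent = 100, mu = 0, lambda = 0, seed = 17,
                      use_normalized_similarity = FALSE, epsilon = 1e-10,
                      max_iter = 100)
  fit <- fit_manifold(R, sc, sdm, h)
  rel <- sqrt(sum((v - predict(fit))^2)) / sqrt(sum(v^2))
  expect_lt(rel, 1e-6)

  # rank-1 case with a whisper of ridge
  r1 <- response_matrix(matrix(c(1, 2, 2, 4), 2, 2,
                               dimnames = list(c("c1", "c2"), c("d1", "d2"))))
  e2 <- diag(2)
  h1 <- mf_hyperparams(k_percent = 50, mu = 1e-6, lambda = 0, seed = 3,
                       use_normalized_similarity = FALSE, epsilon = 1e-8,
                       max_iter = 200)
  f1 <- fit_manifold(r1, `dimnames<-`(e2, list(c("c1", "c2"), c("c1", "c2"))),
                     `dimnames<-`(e2, list(c("d1", "d2"), c("d1", "d2"))), h1)
  expect_equal(f1$k, 1)
  expect_lt(sqrt(sum((r1$values - predict(f1))^2)), 1e-3)
})

test_that("fitting is bit-deterministic under a fixed seed", {
  p <- toy_problem(seed = 51)
  h <- mf_hyperparams(k_percent = 50, mu = 8, lambda = 2, seed = 23)
  f1 <- fit_manifold(p$d$response, p$simC, p$simD, h)
  f2 <- fit_manifold(p$d$response, p$simC, p$simD, h)
  expect_identical(f1$P, f2$P)
  expect_identical(f1$Q, f2$Q)
  expect_identical(f1$loss_trace, f2$loss_trace)
  pr1 <- predict_dual(p$d$response, p$simC, p$simD, h)
  pr2 <- predict_dual(p$d$response, p$simC, p$simD, h)
  expect_identical(pr1$combined, pr2$combined)
})

test_that("the dual run averages forward and re-oriented transpose predictions", {
  p <- toy_problem(seed = 53)
  h <- mf_hyperparams(k_percent = 50, mu = 8, lambda = 2, seed = 29)
  pr <- predict_dual(p$d$response, p$simC, p$simD, h)
  expect_equal(pr$combined, 0.5 * (pr$forward + pr$reverse))
  expect_identical(dim(pr$combined), dim(p$d$response$values))
  # predictions exist for unobserved pairs too
  expect_true(all(is.finite(pr$combined)))
  # transpose run starts from the forward run's swapped factors
  expect_identical(pr$fit_reverse$P |> dim(), pr$fit_forward$Q |> dim())
})

test_that("combined predictions are usually at least as good as either run", {
  wins <- 0
  for (seed in 1:30) {
    d <- simulate_dataset(n = 16, m = 8, n_genes = 30, k = 2, sigma = 0.1,
                          missing_fraction = 0.2, n_tissues = 3,
                          n_drug_features = 16, n_pathways = 3, seed = seed)
    sc <- build_similarity(d$expr); sdm <- build_similarity(d$chem)
    h <- mf_hyperparams(k_percent = 40, mu = 8, lambda = 1, seed = seed)
    pr <- predict_dual(d$response, sc, sdm, h)
    truth <- tcrossprod(d$truth_P, d$truth_Q)
    held <- !d$response$observed
    err <- function(m_) rmse(truth[held], m_[held])
    if (err(pr$combined) <= max(err(pr$forward), err(pr$reverse)) + 1e-9) {
      wins <- wins + 1
    }
  }
  expect_gte(wins / 30, 0.9)
})

test_that("noisy masked low-rank structure is recovered on held-out entries", {
  d <- simulate_dataset(n = 60, m = 12, n_genes = 60, k = 3, sigma = 0,
                        missing_fraction = 0.2, n_tissues = 4,
                        n_drug_features = 24, n_pathways = 3, seed = 61)
  sc <- build_similarity(d$expr); sdm <- build_similarity(d$chem)
  h <- mf_hyperparams(k_percent = 50, mu = 1, lambda = 0.125, seed = 11)
  pr <- predict_dual(d$response, sc, sdm, h)
  truth <- tcrossprod(d$truth_P, d$truth_Q)
  held <- !d$response$observed
  expect_gt(pcc(truth[held], pr$combined[held]), 0.95)
})

test_that("misaligned similarity labels are rejected", {
  p <- toy_problem(seed = 63)
  bad <- p$simC$values[1:5, 1:5]
  expect_error(fit_manifold(p$d$response, bad, p$simD, mf_hyperparams()),
               "does not cover")
})

test_that("tidiers expose factors and fit diagnostics", {
  p <- toy_problem(seed = 65)
  h <- mf_hyperparams(k_percent = 50, mu = 8, lambda = 1, seed = 2)
  fit <- fit_manifold(p$d$response, p$simC, p$simD, h)
  td <- tidy(fit)
  expect_setequal(unique(td$side), c("cell", "drug"))
  expect_equal(nrow(td), (nrow(fit$P) + nrow(fit$Q)) * fit$k)
  gl <- glance(fit)
  expect_equal(gl$k, fit$k)
  expect_s3_class(autoplot(fit), "ggplot")
})
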