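# Similarity-constrained low-rank factorization of the masked response
# matrix R ~ P Q^T by alternating exact block-Newton updates, plus the dual
# transpose-factorization average used for prediction.
#
# Objective (masked reconstruction over observed pairs only):
#   L = 1/2 sum_{(i,j) obs} (r_ij - p_i q_j^T)^2
#     + mu/2 (sum_i ||p_i||^2 + sum_j ||q_j||^2)
#     + lambda/2 (sum_{i,j} ||p_i - p_j||^2 SimC_ij
#               + sum_{i,j} ||q_i - q_j||^2 SimD_ij)
#
# Each row subproblem is quadratic, so the Newton step from any point is the
# exact block minimizer:
#   [Q_obs^T Q_obs + mu I + lambda c_i I] p_i^T
#     = sum_{j obs} r_ij q_j^T + lambda sum_{j != i} s_ij p_j^T
# with s_ij = SimC(i,j) + SimC(j,i) and c_i = sum_{j != i} s_ij. The
# "as_printed" variant keeps the current row p_i in place of the neighbour
# rows p_j in the right-hand side.

#' Hyperparameters for the manifold-regularized factorization
#'
#' @param k_percent Latent dimension as a percentage of `min(n, m)`
#'   (default 70); `k = round(k_percent/100 * min(n, m))`, at least 1.
#' @param mu Ridge regularization coefficient (default `2^3`).
#' @param lambda Similarity-conservation coefficient (default `2^2`).
#' @param epsilon Convergence tolerance on the Frobenius norm of the change
#'   in the predicted matrix between iterations (default 0.01).
#' @param max_iter Iteration cap (default 200).
#' @param seed Integer seed for the random initialization.
#' @param use_normalized_similarity If `TRUE` (default), raw similarity
#'   inputs are passed through [normalize_similarity()] before fitting.
#' @param update_variant `"derived"` (exact zero-gradient block update, the
#'   default) or `"as_printed"` (current-row numerator).
#' @param treat_mask_as_full If `TRUE`, the reconstruction term runs over
#'   every entry rather than only the observed ones (requires a fully
#'   observed matrix to be meaningful; default `FALSE`).
#' @return A validated list of settings, class `mf_hyperparams`.
#' @export
mf_hyperparams <- function(k_percent = 70, mu = 2^3, lambda = 2^2,
                           epsilon = 0.01, max_iter = 200, seed = 1L,
                           use_normalized_similarity = TRUE,
                           update_variant = c("derived", "as_printed"),
                           treat_mask_as_full = FALSE) {
  stopifnot(k_percent > 0, k_percent <= 100, mu >= 0, lambda >= 0,
            epsilon > 0, max_iter >= 1)
  structure(list(
    k_percent = k_percent, mu = mu, lambda = lambda, epsilon = epsilon,
    max_iter = as.integer(max_iter), seed = as.integer(seed),
    use_normalized_similarity = use_normalized_similarity,
    update_variant = match.arg(update_variant),
    treat_mask_as_full = treat_mask_as_full
  ), class = "mf_hyperparams")
}

latent_dim <- function(k_percent, n, m) {
  max(1L, as.integer(round(k_percent / 100 * min(n, m))))
}

# Symmetrized off-diagonal similarity s_ij = S(i,j) + S(j,i) with zero
# diagonal (self-pairs contribute nothing to gradient or Hessian).
sym_offdiag <- function(S) {
  s <- S + t(S)
  diag(s) <- 0
  s
}

#' Evaluate the factorization loss
#'
#' @param R A [response_matrix()].
#' @param P,Q Latent factor matrices (`n x k` and `m x k`).
#' @param simC,simD Similarity matrices (raw or normalized) over cells and
#'   drugs, aligned to `R`'s labels; plain matrices are accepted.
#' @param mu,lambda Regularization and similarity-conservation coefficients.
#' @param treat_mask_as_full Sum reconstruction error over all entries
#'   instead of observed ones.
#' @return Scalar loss.
#' @export
mf_loss <- function(R, P, Q, simC, simD, mu, lambda,
                    treat_mask_as_full = FALSE) {
  stopifnot(inherits(R, "response_matrix"))
  sc <- values_of(simC); sd_ <- values_of(simD)
  v <- R$values
  mask <- if (treat_mask_as_full) array(TRUE, dim(v)) else R$observed
  if (nrow(P) != nrow(v) || nrow(Q) != ncol(v) || ncol(P) != ncol(Q)) {
    stop("factor shapes inconsistent with the response matrix", call. = FALSE)
  }
  pred <- tcrossprod(P, Q)
  resid <- (v - pred)[mask]
  manifold <- function(X, S) {
    # sum_{i,j} ||x_i - x_j||^2 S_ij via the Laplacian-style identity
    sq <- rowSums(X^2)
    sum(outer(sq, sq, `+`) * S) - 2 * sum((S %*% X) * X)
  }
  0.5 * sum(resid^2, na.rm = FALSE) +
    mu / 2 * (sum(P^2) + sum(Q^2)) +
    lambda / 2 * (manifold(P, sc) + manifold(Q, sd_))
}

# Gradient and Hessian of the loss wrt one row of P (or of Q when called
# with transposed roles). `obs` indexes the observed columns for this row.
block_gradient_hessian <- function(p_i, i, r_row, obs, Q, P, s_sym, mu, lambda) {
  k <- length(p_i)
  Qo <- Q[obs, , drop = FALSE]
  c_i <- sum(s_sym[i, ])
  grad <- as.numeric(crossprod(Qo, Qo %*% p_i - r_row[obs])) + mu * p_i +
    lambda * (c_i * p_i - as.numeric(s_sym[i, ] %*% P))
  hess <- crossprod(Qo) + (mu + lambda * c_i) * diag(k)
  list(gradient = grad, hessian = hess)
}

# Solve H x = b with a ridge safeguard when H is (numerically) not PD.
# Cholesky doubles as the definiteness test; a pivot below sqrt(1e-10) marks
# a near-singular block (possible when Laplacian-normalized similarities make
# the lambda term negative).
safeguarded_solve <- function(H, b) {
  k <- ncol(H)
  ch <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(ch) || min(diag(ch))^2 <= 1e-10) {
    ridge <- 1e-8 * (1 + abs(sum(diag(H))) / k)
    warning("non-positive-definite block Hessian; ridge jitter added",
            call. = FALSE)
    repeat {
      ch <- tryCatch(chol(H + ridge * diag(k)), error = function(e) NULL)
      if (!is.null(ch) && min(diag(ch))^2 > 1e-10) break
      ridge <- ridge * 10
      if (ridge > 1e8) stop("block Hessian could not be regularized", call. = FALSE)
    }
  }
  backsolve(ch, forwardsolve(t(ch), b))
}

# One full pass of row updates on P (Q held fixed). X_other = Q, sim = cell
# similarity. Used for both sides via role symmetry.
update_factor <- function(P, Q, values, mask, s_sym, mu, lambda, variant) {
  k <- ncol(P)
  newP <- P
  cs <- rowSums(s_sym)
  for (i in seq_len(nrow(P))) {
    obs <- which(mask[i, ])
    Qo <- Q[obs, , drop = FALSE]
    H <- crossprod(Qo) + (mu + lambda * cs[i]) * diag(k)
    neighbour_term <- if (variant == "derived") {
      as.numeric(s_sym[i, ] %*% newP)
    } else {
      cs[i] * newP[i, ]
    }
    rhs <- as.numeric(crossprod(Qo, values[i, obs])) + lambda * neighbour_term
    newP[i, ] <- safeguarded_solve(H, rhs)
  }
  newP
}

resolve_similarity <- function(sim, ids, hyper, what) {
  if (inherits(sim, "similarity_matrix")) {
    if (hyper$use_normalized_similarity && !sim$normalized) {
      sim <- normalize_similarity(sim)
    }
    v <- sim$values
  } else {
    v <- values_of(sim)
  }
  if (!all(ids %in% rownames(v))) {
    stop(sprintf("%s similarity does not cover all %s labels", what, what),
         call. = FALSE)
  }
  v[ids, ids]
}

#' Fit the similarity-constrained factorization
#'
#' Initializes `P` and `Q` from a seeded uniform draw on `[0, 1)/sqrt(k)`
#' (unless explicit `init` factors are supplied) and alternates exact block
#' updates of `P` then `Q` until the Frobenius norm of the change in the
#' predicted matrix `P Q^T` falls below `epsilon` or `max_iter` is reached.
#'
#' @param R A [response_matrix()]; every row and column should have at least
#'   one observed entry (a warning is raised otherwise).
#' @param simC,simD [similarity_matrix()] objects (or plain matrices) over
#'   the cell and drug labels of `R`. Raw similarities are Laplacian-
#'   normalized first when `use_normalized_similarity` is set.
#' @param hyper An [mf_hyperparams()].
#' @param init Optional list with elements `P` and `Q` used as the starting
#'   point (used by the transpose run of [predict_dual()]).
#' @return An object of class `manifold_fit` with elements `P`, `Q`
#'   (dimnamed), `hyper`, `n_iterations`, `loss_trace`, `converged`.
#' @export
fit_manifold <- function(R, simC, simD, hyper = mf_hyperparams(), init = NULL) {
  stopifnot(inherits(R, "response_matrix"), inherits(hyper, "mf_hyperparams"))
  v <- R$values
  mask <- if (hyper$treat_mask_as_full) array(TRUE, dim(v)) else R$observed
  v0 <- v
  v0[!mask] <- 0  # only masked-out entries; never read through the mask
  n <- nrow(v); m <- ncol(v)
  if (any(rowSums(mask) == 0) || any(colSums(mask) == 0)) {
    warning("response matrix has an empty row or column in the training mask",
            call. = FALSE)
  }
  sc <- resolve_similarity(simC, rownames(v), hyper, "cell")
  sd_ <- resolve_similarity(simD, colnames(v), hyper, "drug")
  k <- latent_dim(hyper$k_percent, n, m)
  if (is.null(init)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(hyper$seed)
    P <- matrix(stats::runif(n * k) / sqrt(k), n, k)
    Q <- matrix(stats::runif(m * k) / sqrt(k), m, k)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  } else {
    P <- init$P; Q <- init$Q
    stopifnot(nrow(P) == n, nrow(Q) == m, ncol(P) == k, ncol(Q) == k)
  }
  sc_sym <- sym_offdiag(sc)
  sd_sym <- sym_offdiag(sd_)
  Rm <- response_matrix_from_mask(v, mask)
  trace <- mf_loss(Rm, P, Q, sc, sd_, hyper$mu, hyper$lambda)
  pred <- tcrossprod(P, Q)
  converged <- FALSE
  iter <- 0L
  for (t in seq_len(hyper$max_iter)) {
    P <- update_factor(P, Q, v0, mask, sc_sym, hyper$mu, hyper$lambda,
                       hyper$update_variant)
    Q <- update_factor(Q, P, t(v0), t(mask), sd_sym, hyper$mu, hyper$lambda,
                       hyper$update_variant)
    iter <- t
    loss_t <- mf_loss(Rm, P, Q, sc, sd_, hyper$mu, hyper$lambda)
    if (!is.finite(loss_t)) stop("non-finite loss during fitting", call. = FALSE)
    trace <- c(trace, loss_t)
    new_pred <- tcrossprod(P, Q)
    delta <- sqrt(sum((new_pred - pred)^2))
    pred <- new_pred
    if (delta < hyper$epsilon) {
      converged <- TRUE
      break
    }
  }
  rownames(P) <- rownames(v); rownames(Q) <- colnames(v)
  colnames(P) <- colnames(Q) <- paste0("dim", seq_len(k))
  structure(list(P = P, Q = Q, hyper = hyper, k = k,
                 n_iterations = iter, loss_trace = trace,
                 converged = converged),
            class = "manifold_fit")
}

# Internal: rebuild a response_matrix carrying an explicit mask.
response_matrix_from_mask <- function(values, mask) {
  v <- values
  v[!mask] <- NA_real_
  response_matrix(v)
}

#' Predict the response matrix from a fitted factorization
#'
#' @param object A `manifold_fit`.
#' @param ... Unused.
#' @return The `n x m` predicted matrix `P Q^T` with the response labels.
#' @export
predict.manifold_fit <- function(object, ...) {
  tcrossprod(object$P, object$Q)
}

#' Dual-run prediction: forward and transpose factorization, averaged
#'
#' Fits `R` with `(simC, simD)`, then fits `R^T` with `(simD, simC)` using
#' the first run's final `Q` and `P` as the starting factors, and averages
#' the two predictions. Predictions are produced for every cell of the
#' matrix, including unobserved pairs.
#'
#' @inheritParams fit_manifold
#' @return A list of class `mf_prediction`: `forward`, `reverse`, `combined`
#'   (`n x m` matrices), plus both `manifold_fit` objects (`fit_forward`,
#'   `fit_reverse`).
#' @export
predict_dual <- function(R, simC, simD, hyper = mf_hyperparams()) {
  fit1 <- fit_manifold(R, simC, simD, hyper)
  forward <- predict(fit1)
  Rt <- response_matrix(t(structure(R$values, dimnames = dimnames(R$values))))
  fit2 <- fit_manifold(Rt, simD, simC, hyper,
                       init = list(P = fit1$Q, Q = fit1$P))
  reverse <- t(predict(fit2))
  combined <- 0.5 * (forward + reverse)
  structure(list(forward = forward, reverse = reverse, combined = combined,
                 fit_forward = fit1, fit_reverse = fit2),
            class = "mf_prediction")
}

#' @export
print.manifold_fit <- function(x, ...) {
  cat(sprintf(
    "<manifold_fit> k=%d, mu=%g, lambda=%g; %d iterations (%s), final loss %.6g\n",
    x$k, x$hyper$mu, x$hyper$lambda, x$n_iterations,
    if (x$converged) "converged" else "max_iter reached",
    utils::tail(x$loss_trace, 1)
  ))
  invisible(x)
}

#' Tidy a fitted factorization into a long tibble of latent loadings
#'
#' @param x A `manifold_fit`.
#' @param ... Unused.
#' @return A tibble with columns `entity`, `side` (`"cell"`/`"drug"`),
#'   `dimension`, `loading`.
#' @export
tidy.manifold_fit <- function(x, ...) {
  one <- function(M, side) {
    tibble::as_tibble(M, rownames = "entity") |>
      tidyr::pivot_longer(-"entity", names_to = "dimension",
                          values_to = "loading") |>
      dplyr::mutate(side = side, .after = "entity")
  }
  dplyr::bind_rows(one(x$P, "cell"), one(x$Q, "drug"))
}

#' One-row fit summary
#'
#' @param x A `manifold_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `mu`, `lambda`, `n_iterations`,
#'   `converged`, `final_loss`.
#' @method glance manifold_fit
#' @export
glance.manifold_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, mu = x$hyper$mu, lambda = x$hyper$lambda,
    n_iterations = x$n_iterations, converged = x$converged,
    final_loss = utils::tail(x$loss_trace, 1)
  )
}
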