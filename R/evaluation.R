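# Cross-validation on cell line-drug pairs, metrics, fitness, grid search,
# per-drug correlation, and the nearest-neighbour baseline.

#' Root mean square error
#'
#' @param real_values,predicted Equal-length nonempty numeric vectors.
#' @return Nonnegative scalar.
#' @export
rmse <- function(real_values, predicted) {
  if (length(real_values) != length(predicted) || length(real_values) == 0) {
    stop("rmse needs two nonempty vectors of equal length", call. = FALSE)
  }
  sqrt(mean((real_values - predicted)^2))
}

#' Coefficient of determination
#'
#' `1 - SSE/SST` with the total sum of squares centred on the mean of the
#' observed values; can be negative for worse-than-mean predictions.
#'
#' @inheritParams rmse
#' @return Scalar `<= 1`.
#' @export
r_squared <- function(real_values, predicted) {
  if (length(real_values) != length(predicted) || length(real_values) == 0) {
    stop("r_squared needs two nonempty vectors of equal length", call. = FALSE)
  }
  sst <- sum((real_values - mean(real_values))^2)
  if (sst == 0) stop("r_squared undefined for constant observed values", call. = FALSE)
  1 - sum((real_values - predicted)^2) / sst
}

#' Pearson correlation between observed and predicted responses
#'
#' @inheritParams rmse
#' @return Scalar in \[-1, 1\].
#' @export
pcc_metric <- function(real_values, predicted) {
  pcc(real_values, predicted)
}

#' Fitness score combining the three criteria
#'
#' `fitness = R^2 + PCC - RMSE`; higher is better, 2 for a perfect
#' prediction.
#'
#' @param r2,pcc,rmse_value The three aggregate criteria.
#' @return Scalar fitness.
#' @export
fitness <- function(r2, pcc, rmse_value) {
  r2 + pcc - rmse_value
}

#' Assign observed pairs to cross-validation folds
#'
#' @param n_pairs Number of observed cell line-drug pairs.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold labels in `1..n_folds`, one per pair;
#'   fold sizes differ by at most 1.
#' @export
make_folds <- function(n_pairs, n_folds = 5, seed = 1L) {
  if (n_pairs < n_folds) stop("fewer pairs than folds", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  folds <- sample(rep(seq_len(n_folds), length.out = n_pairs))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  folds
}

hold_out <- function(R, idx) {
  v <- R$values
  v[idx] <- NA_real_
  response_matrix(v)
}

fold_metrics <- function(truth, pred) {
  tibble::tibble(
    n_test = length(truth),
    rmse = rmse(truth, pred),
    r2 = r_squared(truth, pred),
    pcc = pcc_metric(truth, pred)
  )
}

#' Repeated k-fold cross-validation of the dual-run factorization
#'
#' Observed pairs are partitioned into `n_folds` folds; each fold is masked
#' out of the training matrix in turn, [predict_dual()] is fitted on the
#' rest, and RMSE, R-squared and Pearson correlation are computed on the
#' held-out pairs only. Metrics are computed per fold and then averaged over
#' all folds of all repeats; fitness is formed from the aggregate means.
#' Repeat seeds derive deterministically from `seed` (`seed + repeat - 1`).
#'
#' @inheritParams fit_manifold
#' @param n_folds Number of folds (default 5).
#' @param n_repeats Number of repetitions of the whole CV (default 30).
#' @param seed Master seed for fold assignment.
#' @return An `eval_report`: list with `per_fold` (tibble: `repeat_id`,
#'   `fold`, `n_test`, `rmse`, `r2`, `pcc`, `n_iterations_forward`),
#'   `aggregate` (one-row tibble), `fitness`, `per_drug_pcc` (tibble),
#'   `n_folds`, `n_repeats`, `seed`.
#' @export
cross_validate <- function(R, simC, simD, hyper = mf_hyperparams(),
                           n_folds = 5, n_repeats = 30, seed = 1L) {
  stopifnot(inherits(R, "response_matrix"))
  obs_idx <- which(R$observed)
  if (length(obs_idx) < n_folds) stop("fewer observed pairs than folds", call. = FALSE)
  # similarities fixed across folds; normalize once up front
  hyper_run <- hyper
  if (hyper$use_normalized_similarity) {
    if (inherits(simC, "similarity_matrix") && !simC$normalized) {
      simC <- normalize_similarity(simC)
    }
    if (inherits(simD, "similarity_matrix") && !simD$normalized) {
      simD <- normalize_similarity(simD)
    }
  }
  per_fold <- list()
  drug_tabs <- list()
  for (rep_i in seq_len(n_repeats)) {
    folds <- make_folds(length(obs_idx), n_folds, seed + rep_i - 1L)
    pooled_pred <- rep(NA_real_, length(obs_idx))
    for (f in seq_len(n_folds)) {
      test_idx <- obs_idx[folds == f]
      R_train <- hold_out(R, test_idx)
      pred <- predict_dual(R_train, simC, simD, hyper_run)
      truth <- R$values[test_idx]
      est <- pred$combined[test_idx]
      pooled_pred[folds == f] <- est
      per_fold[[length(per_fold) + 1L]] <- dplyr::mutate(
        fold_metrics(truth, est),
        repeat_id = rep_i, fold = f,
        n_iterations_forward = pred$fit_forward$n_iterations,
        .before = 1
      )
    }
    pred_full <- R$values
    pred_full[] <- NA_real_
    pred_full[obs_idx] <- pooled_pred
    drug_tabs[[rep_i]] <- suppressWarnings(
      drugwise_pcc(R, pred_full)
    ) |> dplyr::mutate(repeat_id = rep_i)
  }
  per_fold <- dplyr::bind_rows(per_fold)
  aggregate <- dplyr::summarise(
    per_fold,
    rmse = mean(.data$rmse), r2 = mean(.data$r2), pcc = mean(.data$pcc)
  )
  per_drug <- dplyr::bind_rows(drug_tabs) |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(pcc = mean(.data$pcc), n_obs = .data$n_obs[1])
  structure(list(
    per_fold = per_fold,
    aggregate = aggregate,
    fitness = fitness(aggregate$r2, aggregate$pcc, aggregate$rmse),
    per_drug_pcc = per_drug,
    n_folds = n_folds, n_repeats = n_repeats, seed = seed
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %d-fold CV x %d repeats: RMSE %.4f, R2 %.4f, PCC %.4f, fitness %.4f\n",
    x$n_folds, x$n_repeats, x$aggregate$rmse, x$aggregate$r2,
    x$aggregate$pcc, x$fitness
  ))
  invisible(x)
}

#' Tidy per-fold cross-validation metrics
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return The per-fold tibble.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$per_fold

#' One-row cross-validation summary
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One-row tibble with aggregate `rmse`, `r2`, `pcc`, `fitness`,
#'   `n_folds`, `n_repeats`.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  dplyr::mutate(x$aggregate, fitness = x$fitness,
                n_folds = x$n_folds, n_repeats = x$n_repeats)
}

#' Hyperparameter grid specification
#'
#' Defaults are the standard tuning grid: latent dimension 10-90% in steps
#' of 10, and both coefficients over `2^-3 .. 2^3`.
#'
#' @param k_percents,mus,lambdas Nonempty numeric vectors of candidate
#'   values.
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(k_percents = seq(10, 90, by = 10),
                      mus = 2^(-3:3), lambdas = 2^(-3:3)) {
  stopifnot(length(k_percents) > 0, length(mus) > 0, length(lambdas) > 0)
  structure(list(k_percents = k_percents, mus = mus, lambdas = lambdas),
            class = "grid_spec")
}

#' Grid search over factorization hyperparameters
#'
#' Runs [cross_validate()] for every `(k_percent, mu, lambda)` combination
#' and returns the combination with the highest fitness together with the
#' full fitness table.
#'
#' @inheritParams cross_validate
#' @param grid A [grid_spec()].
#' @param base_hyper Template [mf_hyperparams()] providing the non-gridded
#'   settings.
#' @return List with `best` (an [mf_hyperparams()]) and `table` (tibble:
#'   `k_percent`, `mu`, `lambda`, `rmse`, `r2`, `pcc`, `fitness`).
#' @export
grid_search <- function(R, simC, simD, grid = grid_spec(), n_folds = 5,
                        n_repeats = 1, seed = 1L,
                        base_hyper = mf_hyperparams()) {
  stopifnot(inherits(grid, "grid_spec"))
  combos <- tidyr::expand_grid(
    k_percent = grid$k_percents, mu = grid$mus, lambda = grid$lambdas
  )
  rows <- purrr::pmap(combos, function(k_percent, mu, lambda) {
    hyper <- base_hyper
    hyper$k_percent <- k_percent; hyper$mu <- mu; hyper$lambda <- lambda
    # a diverging combination (non-finite loss) scores -Inf rather than
    # aborting the search
    rep_ <- tryCatch(
      cross_validate(R, simC, simD, hyper, n_folds = n_folds,
                     n_repeats = n_repeats, seed = seed),
      error = function(e) NULL
    )
    if (is.null(rep_)) {
      return(tibble::tibble(k_percent = k_percent, mu = mu, lambda = lambda,
                            rmse = NA_real_, r2 = NA_real_, pcc = NA_real_,
                            fitness = -Inf))
    }
    dplyr::mutate(rep_$aggregate, k_percent = k_percent, mu = mu,
                  lambda = lambda, fitness = rep_$fitness, .before = 1)
  })
  table <- dplyr::bind_rows(rows)
  best_row <- table[which.max(table$fitness), ]
  best <- base_hyper
  best$k_percent <- best_row$k_percent
  best$mu <- best_row$mu
  best$lambda <- best_row$lambda
  list(best = best, table = table)
}

#' Per-drug correlation between observed and predicted responses
#'
#' @param real A [response_matrix()].
#' @param predicted An `n x m` numeric matrix aligned with `real`.
#' @return Tibble with `drug`, `pcc`, `n_obs`; drugs with fewer than 2
#'   observed cells are omitted with a warning.
#' @export
drugwise_pcc <- function(real, predicted) {
  stopifnot(inherits(real, "response_matrix"))
  drugs <- colnames(real$values)
  rows <- purrr::map(drugs, function(d) {
    ok <- real$observed[, d] & !is.na(predicted[, d])
    if (sum(ok) < 2) return(NULL)
    tibble::tibble(drug = d,
                   pcc = pcc_metric(real$values[ok, d], predicted[ok, d]),
                   n_obs = sum(ok))
  })
  dropped <- drugs[vapply(rows, is.null, logical(1))]
  if (length(dropped) > 0) {
    warning(sprintf("omitting %d drug(s) with < 2 observed cells",
                    length(dropped)), call. = FALSE)
  }
  dplyr::bind_rows(rows)
}

#' Nearest-neighbour baseline over similarity-profile features
#'
#' Each pair `(cell i, drug j)` is described by the concatenation of row `i`
#' of the cell similarity matrix and column `j` of the drug similarity
#' matrix; a test pair's response is the mean observed response of its
#' `k_neighbors` nearest training pairs under Euclidean distance in that
#' feature space (default `k = 1`).
#'
#' @param R A [response_matrix()]; its observed pairs minus `test_pairs`
#'   form the training set.
#' @param simC,simD Similarity matrices over `R`'s cells and drugs (raw, as
#'   used for the feature vectors).
#' @param test_pairs Two-column matrix or data frame of (cell, drug) labels.
#' @param k_neighbors Number of neighbours (default 1).
#' @return Numeric vector of predictions, one per test pair.
#' @export
knn_baseline <- function(R, simC, simD, test_pairs, k_neighbors = 1) {
  stopifnot(inherits(R, "response_matrix"))
  sc <- values_of(simC); sd_ <- values_of(simD)
  v <- R$values
  tp <- as.matrix(test_pairs)
  test_lin <- cbind(match(tp[, 1], rownames(v)), match(tp[, 2], colnames(v)))
  if (anyNA(test_lin)) stop("test pair label not found in response matrix", call. = FALSE)
  test_idx <- (test_lin[, 2] - 1L) * nrow(v) + test_lin[, 1]
  train_idx <- setdiff(which(R$observed), test_idx)
  if (length(train_idx) == 0) stop("no training pairs", call. = FALSE)
  k_neighbors <- min(k_neighbors, length(train_idx))
  tr <- arrayInd(train_idx, dim(v))
  # feature = [simC row of the cell, simD column of the drug]
  feats_train <- cbind(sc[tr[, 1], , drop = FALSE],
                       t(sd_)[tr[, 2], , drop = FALSE])
  feats_test <- cbind(sc[test_lin[, 1], , drop = FALSE],
                      t(sd_)[test_lin[, 2], , drop = FALSE])
  resp_train <- v[train_idx]
  unname(apply(feats_test, 1, function(f) {
    d <- colSums((t(feats_train) - f)^2)
    mean(resp_train[order(d)[seq_len(k_neighbors)]])
  }))
}
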