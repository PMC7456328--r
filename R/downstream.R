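# Benchmark purification by tissue-wise redundancy removal, pathway activity
# scoring with drug-pathway association, and quartile-based
# sensitive/resistant calling.

# Off-diagonal upper-triangle similarities among a set of cells.
within_tissue_sims <- function(v, cells) {
  sub <- v[cells, cells, drop = FALSE]
  sub[upper.tri(sub)]
}

#' Within-tissue similarity quantiles
#'
#' For every tissue with at least two annotated cells, the minimum (Q0),
#' quartiles (Q1-Q3) and maximum (Q4) of the pairwise similarities among its
#' cells (off-diagonal upper triangle, linear interpolation between order
#' statistics). Singleton tissues are omitted.
#'
#' @param S A raw [similarity_matrix()] covering all annotated cells.
#' @param tissues A [tissue_annotation()].
#' @return Tibble with columns `tissue`, `n_cells`, `q0`..`q4`.
#' @export
tissue_similarity_quantiles <- function(S, tissues) {
  v <- values_of(S)
  missing <- setdiff(tissues$cell, rownames(v))
  if (length(missing) > 0) {
    stop(sprintf("annotated cell '%s' absent from similarity matrix", missing[1]),
         call. = FALSE)
  }
  tissues |>
    dplyr::group_by(.data$tissue) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      tibble::as_tibble_row(stats::setNames(
        stats::quantile(within_tissue_sims(v, .data$cell), probs = 0:4 / 4,
                        type = 7, names = FALSE),
        paste0("q", 0:4)
      ))
    )
}

#' Remove redundant cell lines tissue by tissue
#'
#' Within each tissue `t`, let `Q3(t)` be the third quartile of the pairwise
#' similarities among its cells. A cell is removed iff its similarity
#' exceeds `Q3(t)` with strictly more than `theta * n_t` of the *other*
#' cells in the tissue (`n_t` = tissue size). All removals are decided
#' simultaneously from the original tissue composition; singleton tissues
#' are always kept.
#'
#' @param S A raw [similarity_matrix()] (copy-number similarity in the
#'   standard protocol) covering all annotated cells.
#' @param tissues A [tissue_annotation()].
#' @param theta Strictness threshold in (0, 1); default 0.20.
#' @return A `redundancy_report`: list with `kept` and `removed` cell label
#'   vectors, `per_tissue_quantiles` (tibble), `theta` and
#'   `similarity_kind`.
#' @export
remove_redundant <- function(S, tissues, theta = 0.20) {
  stopifnot(theta > 0, theta < 1)
  v <- values_of(S)
  missing <- setdiff(tissues$cell, rownames(v))
  if (length(missing) > 0) {
    stop(sprintf("cell '%s' has no similarity entry", missing[1]), call. = FALSE)
  }
  quant <- tissue_similarity_quantiles(S, tissues)
  removed <- character(0)
  for (t in unique(tissues$tissue)) {
    cells <- tissues$cell[tissues$tissue == t]
    n_t <- length(cells)
    if (n_t < 2) next
    q3 <- quant$q3[quant$tissue == t]
    sub <- v[cells, cells, drop = FALSE]
    diag(sub) <- -Inf  # never count a cell against itself
    over <- rowSums(sub > q3)
    removed <- c(removed, cells[over > theta * n_t])
  }
  kept <- setdiff(tissues$cell, removed)
  kind <- if (inherits(S, "similarity_matrix")) S$kind else NA_character_
  structure(list(kept = kept, removed = removed,
                 per_tissue_quantiles = quant, theta = theta,
                 similarity_kind = kind),
            class = "redundancy_report")
}

#' @export
print.redundancy_report <- function(x, ...) {
  cat(sprintf(
    "<redundancy_report> theta=%.2g (%s similarity): kept %d, removed %d\n",
    x$theta, x$similarity_kind, length(x$kept), length(x$removed)
  ))
  invisible(x)
}

#' Sweep the redundancy-removal strictness threshold
#'
#' @inheritParams remove_redundant
#' @param thetas Nonempty vector of thresholds in (0, 1).
#' @return Tibble with columns `theta` and `n_kept`; `n_kept` is monotone
#'   non-decreasing in `theta`.
#' @export
threshold_sweep <- function(S, tissues, thetas) {
  stopifnot(length(thetas) > 0)
  purrr::map(thetas, function(th) {
    tibble::tibble(theta = th,
                   n_kept = length(remove_redundant(S, tissues, th)$kept))
  }) |> dplyr::bind_rows()
}

#' Pathway activity scores from expression fold changes
#'
#' The activity of pathway `p` in cell `c` is the sum over the pathway's
#' genes of `log(EXPR(c, g) / median_c EXPR(c, g))` (natural log; the
#' median taken over all cells). Pathways with more than
#' `max_missing_fraction` of their genes absent from the expression table
#' are dropped; the remaining absent genes are skipped in the sum.
#'
#' @param expr A strictly positive, fully observed `EXPR`
#'   [feature_table()].
#' @param sets A [gene_set_collection()].
#' @param max_missing_fraction Gene-coverage tolerance (default 0.10).
#' @param pseudo_count Optional nonnegative constant added to every
#'   expression value before taking logs (default 0: nonpositive values are
#'   an error).
#' @return An `activity_scores` object: list with `scores` (cells x
#'   retained pathways matrix) and `retained_pathways`.
#' @export
pathway_activity <- function(expr, sets, max_missing_fraction = 0.10,
                             pseudo_count = 0) {
  stopifnot(inherits(expr, "feature_table"), expr$kind == "EXPR")
  e <- expr$values + pseudo_count
  if (any(e <= 0)) {
    bad <- which(e <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "nonpositive expression for cell '%s', gene '%s' (log fold change undefined)",
      rownames(e)[bad[1]], colnames(e)[bad[2]]
    ), call. = FALSE)
  }
  genes <- colnames(e)
  retained <- names(sets)[vapply(sets, function(g) {
    mean(!g %in% genes) <= max_missing_fraction
  }, logical(1))]
  lfc <- log(e / rep(apply(e, 2, stats::median), each = nrow(e)))
  scores <- vapply(retained, function(p) {
    g <- intersect(sets[[p]], genes)
    rowSums(lfc[, g, drop = FALSE])
  }, numeric(nrow(e)))
  scores <- matrix(scores, nrow = nrow(e),
                   dimnames = list(rownames(e), retained))
  structure(list(scores = scores, retained_pathways = retained),
            class = "activity_scores")
}

#' Correlate predicted drug responses with pathway activities
#'
#' Entry `(drug, pathway)` is the Pearson correlation, over the cells common
#' to both inputs, between the drug's predicted response vector and the
#' pathway's activity vector. Constant columns give `NA` with a warning.
#'
#' @param predicted `n x m` predicted response matrix (cells x drugs, with
#'   dimnames).
#' @param activity An `activity_scores` object from [pathway_activity()].
#' @return Numeric drugs x pathways matrix of correlations.
#' @export
drug_pathway_association <- function(predicted, activity) {
  stopifnot(inherits(activity, "activity_scores"))
  as_ <- activity$scores
  cells <- intersect(rownames(predicted), rownames(as_))
  if (length(cells) < 2) stop("need >= 2 common cells", call. = FALSE)
  pm <- predicted[cells, , drop = FALSE]
  am <- as_[cells, , drop = FALSE]
  const_d <- apply(pm, 2, stats::var) == 0
  const_p <- apply(am, 2, stats::var) == 0
  if (any(const_d) || any(const_p)) {
    warning("constant prediction or activity column: association set to NA",
            call. = FALSE)
  }
  out <- suppressWarnings(t(stats::cor(pm, am)))
  out <- t(out)  # drugs x pathways
  out[const_d, ] <- NA_real_
  out[, const_p] <- NA_real_
  out
}

#' Call sensitive and resistant cell lines from predicted responses
#'
#' Per drug, the cells whose response is unobserved are ranked by predicted
#' log IC50 (ascending, ties broken by cell label) and split into four
#' near-equal groups; the lowest group is called sensitive, the highest
#' resistant. When the count is not divisible by four, the more extreme
#' groups receive the extra members (in order: lowest, highest, second,
#' third). Drugs with fewer than 4 unobserved cells yield no calls, with a
#' warning.
#'
#' @param predicted `n x m` predicted response matrix with dimnames.
#' @param observed_mask `n x m` logical matrix (`TRUE` = response known).
#' @return Tibble with columns `drug`, `cell`, `predicted`, `call`
#'   (`"sensitive"`/`"resistant"`).
#' @export
call_sensitivity <- function(predicted, observed_mask) {
  stopifnot(identical(dim(predicted), dim(observed_mask)))
  drugs <- colnames(predicted)
  skipped <- character(0)
  rows <- purrr::map(drugs, function(d) {
    unknown <- rownames(predicted)[!observed_mask[, d]]
    if (length(unknown) < 4) {
      skipped <<- c(skipped, d)
      return(NULL)
    }
    vals <- predicted[unknown, d]
    ord <- unknown[order(vals, unknown)]
    n <- length(ord)
    base <- n %/% 4L
    extra <- n %% 4L
    sizes <- rep(base, 4)
    if (extra > 0) sizes[c(1, 4, 2)[seq_len(extra)]] <-
      sizes[c(1, 4, 2)[seq_len(extra)]] + 1L
    grp <- rep(1:4, times = sizes)
    tibble::tibble(
      drug = d,
      cell = ord[grp %in% c(1, 4)],
      predicted = predicted[ord[grp %in% c(1, 4)], d],
      call = ifelse(grp[grp %in% c(1, 4)] == 1, "sensitive", "resistant")
    )
  })
  if (length(skipped) > 0) {
    warning(sprintf("%d drug(s) with < 4 unobserved cells: no calls",
                    length(skipped)), call. = FALSE)
  }
  dplyr::bind_rows(rows)
}
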