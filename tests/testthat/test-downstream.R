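toy_tissue_sim <- function(seed = 1, n = 18, n_tissues = 3) {
  d <- simulate_dataset(n = n, m = 4, n_genes = 40, k = 2, sigma = 0.1,
                        missing_fraction = 0, n_tissues = n_tissues,
                        n_drug_features = 12, n_pathways = 3, seed = seed)
  list(sim = build_similarity(d$cnv), tissues = d$tissues)
}

test_that("within-tissue quantiles match sort-and-interpolate on the pair list", {
  tt <- toy_tissue_sim(seed = 5)
  q <- tissue_similarity_quantiles(tt$sim, tt$tissues)
  for (r in seq_len(nrow(q))) {
    cells <- tt$tissues$cell[tt$tissues$tissue == q$tissue[r]]
    pairs <- tt$sim$values[cells, cells][upper.tri(diag(length(cells)))]
    expect_equal(unlist(q[r, paste0("q", 0:4)], use.names = FALSE),
                 quantile(pairs, 0:4 / 4, type = 7, names = FALSE))
    expect_equal(q$q0[r], min(pairs))
    expect_equal(q$q4[r], max(pairs))
  }
  # constant similarities collapse all five quantiles
  v <- matrix(0.4, 3, 3); diag(v) <- 1
  dimnames(v) <- list(paste0("c", 1:3), paste0("c", 1:3))
  qc <- tissue_similarity_quantiles(similarity_matrix(v, "CNV"),
                                    tissue_annotation(paste0("c", 1:3), "t"))
  expect_equal(unlist(qc[1, paste0("q", 0:4)], use.names = FALSE), rep(0.4, 5))
  # singleton tissues are absent from the table
  tt1 <- tissue_annotation(c("c1", "c2", "c3"), c("t1", "t1", "solo"))
  q1 <- tissue_similarity_quantiles(similarity_matrix(v, "CNV"), tt1)
  expect_false("solo" %in% q1$tissue)
})

test_that("redundancy removal equals the exhaustive rule oracle", {
  for (seed in c(2, 7, 11)) {
    tt <- toy_tissue_sim(seed = seed)
    for (theta in c(0.1, 0.2, 0.4)) {
      rep_ <- remove_redundant(tt$sim, tt$tissues, theta)
      expect_setequal(rep_$removed,
                      redundancy_oracle(tt$sim$values, tt$tissues, theta))
      expect_setequal(c(rep_$kept, rep_$removed), tt$tissues$cell)
      expect_length(intersect(rep_$kept, rep_$removed), 0)
    }
  }
})

test_that("a cell similar to many peers above Q3 is removed; theta near 1 removes none", {
  # 5-cell tissue engineered so one cell exceeds Q3 with 2 others (2 > 0.2*5)
  v <- diag(5)
  v[lower.tri(v)] <- c(0.50, 0.52, 0.54, 0.30,
                       0.56, 0.58, 0.31,
                       0.60, 0.32,
                       0.33)
  v <- v + t(v); diag(v) <- 1
  dimnames(v) <- list(paste0("c", 1:5), paste0("c", 1:5))
  tis <- tissue_annotation(paste0("c", 1:5), "t")
  s <- similarity_matrix(v, "CNV")
  rep_ <- remove_redundant(s, tis, 0.2)
  expect_setequal(rep_$removed, redundancy_oracle(v, tis, 0.2))
  expect_gt(length(rep_$removed), 0)
  expect_length(remove_redundant(s, tis, 0.999)$removed, 0)
  # singleton tissues are always kept
  tis2 <- tissue_annotation(paste0("c", 1:5), c("t", "t", "t", "t", "solo"))
  expect_true("c5" %in% remove_redundant(s, tis2, 0.2)$kept)
  # unannotated cells are fine; annotated cells missing from S are not
  tis3 <- tissue_annotation(c(paste0("c", 1:5), "ghost"), "t")
  expect_error(remove_redundant(s, tis3, 0.2), "ghost")
})

test_that("threshold sweep is monotone and matches repeated removal", {
  tt <- toy_tissue_sim(seed = 13)
  thetas <- c(0.01, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3, 0.35)
  sweep <- threshold_sweep(tt$sim, tt$tissues, thetas)
  expect_equal(nrow(sweep), 8)
  expect_true(all(diff(sweep$n_kept) >= 0))
  for (r in seq_len(nrow(sweep))) {
    expect_equal(sweep$n_kept[r],
                 length(remove_redundant(tt$sim, tt$tissues, sweep$theta[r])$kept))
  }
})

test_that("pathway activity sums per-gene log fold changes about the median", {
  v <- cbind(gA = c(1, 2, 4), gB = c(2, 2, 2) + c(0.5, 0, -0.5))
  rownames(v) <- paste0("c", 1:3)
  expr <- feature_table(v, "EXPR")
  sets <- gene_set_collection(list(single = "gA", both = c("gA", "gB")))
  act <- pathway_activity(expr, sets, max_missing_fraction = 0)
  expect_equal(unname(act$scores[, "single"]), c(log(0.5), 0, log(2)))
  # additivity over disjoint sets
  solo_b <- pathway_activity(expr, gene_set_collection(list(b = "gB")), 0)
  expect_equal(act$scores[, "both"],
               act$scores[, "single"] + solo_b$scores[, "b"])
  # a cell at every per-gene median scores zero
  expect_equal(unname(act$scores["c2", ]), c(0, 0))
})

test_that("pathway coverage filtering and positivity are enforced", {
  expr <- toy_expr(n = 4, g = 10, seed = 17)
  sets <- gene_set_collection(list(
    ok = paste0("g", 1:5),                        # full coverage
    dropped = c(paste0("g", 1:4), "absent_gene"), # 20% missing > 10%
    edge = c(paste0("g", 1:9), "absent_gene")     # exactly 10%: retained
  ))
  act <- pathway_activity(expr, sets, max_missing_fraction = 0.10)
  expect_setequal(act$retained_pathways, c("ok", "edge"))
  neg <- expr
  neg$values[1, 1] <- 0
  expect_error(pathway_activity(neg, sets), "nonpositive")
  # pseudo-count rescues zeros
  expect_silent(pathway_activity(neg, sets, pseudo_count = 1))
})

test_that("drug-pathway association is columnwise correlation over shared cells", {
  p <- toy_problem(n = 10, m = 4, seed = 19)
  pred <- tcrossprod(p$d$truth_P, p$d$truth_Q)
  dimnames(pred) <- dimnames(p$d$response$values)
  act <- pathway_activity(p$d$expr, p$d$gene_sets, max_missing_fraction = 1)
  assoc <- drug_pathway_association(pred, act)
  expect_equal(dim(assoc), c(ncol(pred), length(act$retained_pathways)))
  for (d in colnames(pred)) for (pw in act$retained_pathways) {
    expect_equal(assoc[d, pw], pcc_oracle(pred[, d], act$scores[, pw]),
                 tolerance = 1e-12)
  }
  # an activity vector equal to a drug's prediction correlates at exactly 1
  act2 <- act
  act2$scores[, 1] <- pred[, 2]
  expect_equal(drug_pathway_association(pred, act2)[2, 1], 1)
  act2$scores[, 2] <- -pred[, 3]
  expect_equal(drug_pathway_association(pred, act2)[3, 2], -1)
  # constant columns go NA with a warning
  act3 <- act
  act3$scores[, 1] <- 5
  expect_warning(a3 <- drug_pathway_association(pred, act3), "constant")
  expect_true(all(is.na(a3[, 1])))
})

test_that("sensitivity calling splits unknown cells into disjoint extreme quartiles", {
  set.seed(23)
  pred <- lab_matrix(12, 3, prefix = c("c", "d"), seed = 23)
  mask <- matrix(FALSE, 12, 3, dimnames = dimnames(pred))
  mask[, 2] <- TRUE          # drug d2 fully observed -> no calls
  mask[1:4, 1] <- TRUE       # drug d1 has 8 unknown cells -> 2 + 2 calls
  expect_warning(calls <- call_sensitivity(pred, mask), "< 4 unobserved")
  d1 <- calls[calls$drug == "d1", ]
  expect_equal(sum(d1$call == "sensitive"), 2)
  expect_equal(sum(d1$call == "resistant"), 2)
  unknown1 <- rownames(pred)[!mask[, 1]]
  expect_setequal(d1$cell[d1$call == "sensitive"],
                  unknown1[order(pred[unknown1, 1])][1:2])
  expect_setequal(d1$cell[d1$call == "resistant"],
                  unknown1[order(pred[unknown1, 1])][7:8])
  expect_false("d2" %in% calls$drug)
  expect_length(intersect(d1$cell[d1$call == "sensitive"],
                          d1$cell[d1$call == "resistant"]), 0)
  # remainder handling: 10 unknowns -> quartile sizes differ by at most 1
  d3 <- calls[calls$drug == "d3", ]
  expect_equal(nrow(d3), sum(d3$call == "sensitive") + sum(d3$call == "resistant"))
  expect_lte(abs(sum(d3$call == "sensitive") - sum(d3$call == "resistant")), 1)
})
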