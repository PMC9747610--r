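# small labeled compendium with an optional informative gene
make_labeled_data <- function(n = 40, n_genes = 60, signal = 0, seed = 1) {
  set.seed(seed)
  part <- sprintf("P%03d", seq_len(n))
  meta <- make_meta(paste0(part, "_d0"), participant = part)
  y <- rep(c("high", "low"), length.out = n)
  expr <- matrix(rnorm(n_genes * n, 6, 1), n_genes, n,
                 dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                 meta$sample_id))
  expr["G001", ] <- expr["G001", ] + signal * (y == "high")
  resp <- data.frame(participant_id = part, study_id = "studyA",
                     vaccine = "influenza", mfc = 2, log2_mfc = 1,
                     responder = y, stringsAsFactors = FALSE)
  list(comp = make_compendium(expr, meta = meta), resp = resp)
}

test_that("feature selection ranks by variance with deterministic ties", {
  meta <- make_meta(c("P1_d0", "P2_d0", "P3_d0", "P1_d7"),
                    participant = c("P1", "P2", "P3", "P1"),
                    day = c(0L, 0L, 0L, 7L))
  expr <- rbind(FLAT = c(1, 1, 1, 99), MID = c(1, 2, 3, 99),
                BIG = c(1, 3, 5, 99))
  colnames(expr) <- meta$sample_id
  comp <- make_compendium(expr, meta = meta)
  resp <- data.frame(participant_id = c("P1", "P2", "P3"), study_id = "s",
                     vaccine = "flu", mfc = 2, log2_mfc = 1,
                     responder = c("high", "low", "high"),
                     stringsAsFactors = FALSE)
  expect_equal(select_features(comp, resp, n = 2), c("BIG", "MID"))
  # the day-7 column is excluded: its wild values must not matter
  expr2 <- expr; expr2[, "P1_d7"] <- 0
  comp2 <- make_compendium(expr2, meta = meta)
  expect_equal(select_features(comp2, resp, n = 2),
               select_features(comp, resp, n = 2))
  # ties broken lexicographically
  expr3 <- rbind(B = c(1, 2, 3, 0), A = c(3, 2, 1, 0), C = c(1, 1, 1, 0))
  colnames(expr3) <- meta$sample_id
  comp3 <- make_compendium(expr3, meta = meta)
  expect_equal(select_features(comp3, resp, n = 2), c("A", "B"))
  expect_warning(all3 <- select_features(comp3, resp, n = 5), "fewer than")
  expect_length(all3, 3)
})

test_that("scaled importances follow the min-max convention with a strict threshold", {
  rep <- structure(list(importance = c(g1 = 0, g2 = 2, g3 = 4)),
                   class = "classifier_report")
  expect_equal(scaled_importance(rep, 50), "g3")
  expect_setequal(scaled_importance(rep, 0), c("g2", "g3"))
  expect_length(scaled_importance(rep, 100), 0)
  # monotone: higher threshold never grows the list
  lens <- vapply(c(0, 25, 50, 75, 100),
                 function(t) length(scaled_importance(rep, t)), numeric(1))
  expect_true(all(diff(lens) <= 0))
  rep0 <- structure(list(importance = c(g1 = 0, g2 = 0)),
                    class = "classifier_report")
  expect_warning(out <- scaled_importance(rep0, 0), "zero")
  expect_length(out, 0)
})

test_that("signature scoring separates classes and reports enumeration-scale p-values", {
  d <- make_labeled_data(n = 30, signal = 50, seed = 2)
  sig <- gene_signature("up-only", up_genes = "G001")
  r <- signature_auroc(d$comp, d$resp, sig, n_perm = 199, seed = 3)
  expect_equal(r$auroc, 1)
  expect_equal(r$p_value, 1 / 200)
  # empty down side: score equals the mean of the up genes
  expect_equal(unname(r$scores),
               unname(d$comp$expression["G001", d$resp$participant_id |>
                                          paste0("_d0")]))
  # up minus down arithmetic
  sig2 <- gene_signature("both", up_genes = c("G001", "G002"),
                         down_genes = "G003")
  r2 <- signature_auroc(d$comp, d$resp, sig2, n_perm = 199, seed = 3)
  e <- d$comp$expression
  expect_equal(unname(r2$scores),
               unname(colMeans(e[c("G001", "G002"), ]) - e["G003", ]))
  expect_error(signature_auroc(d$comp, d$resp,
                               gene_signature("none", "NOT_A_GENE")),
               "NOT_A_GENE")
  expect_error(gene_signature("bad", "G1", "G1"), "overlap")
})

test_that("cross-validated training is deterministic and near-perfect on a strong signal", {
  d <- make_labeled_data(n = 40, n_genes = 50, signal = 4, seed = 5)
  r1 <- train_evaluate(d$comp, d$resp, rownames(d$comp$expression),
                       n_folds = 5, seed = 11, n_trees = 100, n_perm = 199)
  r2 <- train_evaluate(d$comp, d$resp, rownames(d$comp$expression),
                       n_folds = 5, seed = 11, n_trees = 100, n_perm = 199)
  expect_identical(r1$predictions$prob, r2$predictions$prob)
  expect_identical(r1$metrics, r2$metrics)
  expect_gte(r1$metrics["auroc"], 0.95)
  expect_lt(r1$auroc_p, 0.05)
  # every sample in exactly one test fold, folds stratified
  expect_equal(sort(unique(r1$predictions$fold)), 1:5)
  expect_equal(as.vector(table(r1$predictions$fold)), rep(8L, 5))
  # pooled auROC equals the rank-sum oracle on the same predictions
  expect_equal(unname(r1$metrics["auroc"]),
               pairwise_auroc(r1$predictions$prob, r1$predictions$label),
               tolerance = 1e-12)
  # Brier definition
  expect_equal(unname(r1$metrics["brier"]),
               mean((r1$predictions$prob - r1$predictions$label)^2),
               tolerance = 1e-12)
  expect_error(train_evaluate(d$comp, d$resp, rownames(d$comp$expression),
                              n_folds = 25, seed = 1), "fewer members")
})

test_that("duplicating every sample leaves the pooled auROC within tolerance", {
  d <- make_labeled_data(n = 30, n_genes = 40, signal = 3, seed = 6)
  r <- train_evaluate(d$comp, d$resp, rownames(d$comp$expression),
                      n_folds = 5, seed = 2, n_trees = 100, n_perm = 99)
  part2 <- sprintf("Q%03d", 1:30)
  meta2 <- make_meta(paste0(part2, "_d0"), participant = part2)
  expr2 <- d$comp$expression
  colnames(expr2) <- meta2$sample_id
  comp.dup <- make_compendium(cbind(d$comp$expression, expr2),
                              meta = rbind(d$comp$samples, meta2))
  resp2 <- d$resp; resp2$participant_id <- part2
  r.dup <- train_evaluate(comp.dup, rbind(d$resp, resp2),
                          rownames(d$comp$expression),
                          n_folds = 5, seed = 2, n_trees = 100, n_perm = 99)
  expect_lte(abs(r.dup$metrics["auroc"] - r$metrics["auroc"]), 0.05)
})
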