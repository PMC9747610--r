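#' @title Pre-vaccination response classifier and signature scoring
#' @description A random-forest classifier of high vs low responders trained
#'   on pre-vaccination expression of the top-variance genes, evaluated by
#'   stratified 10-fold cross-validation on pooled out-of-fold predictions
#'   (auROC, accuracy, PPV, NPV, sensitivity, specificity, Brier score), with
#'   per-split feature count tuned inside each training fold by out-of-bag
#'   auROC. Feature importances are min-max scaled to \[0, 100\]. Fixed gene
#'   signatures are scored as mean(up) - mean(down) log2 expression and
#'   assessed by auROC with label-permutation significance.
#' @name classifier
NULL

# one pre-vaccination sample per responding participant: day 0 preferred,
# day -7 fallback; returns list(x = samples x genes matrix, y = logical
# high, meta = per-row participant/vaccine)
classifier_design <- function(x, responses, features = rownames(x$expression)) {
  keep <- responses[responses$responder %in% c("high", "low"), , drop = FALSE]
  pre <- x$samples[is_prevax(x$samples$day) &
                     x$samples$participant_id %in% keep$participant_id, ,
                   drop = FALSE]
  pre <- pre[order(pre$participant_id, -pre$day), , drop = FALSE]  # day 0 first
  pre <- pre[!duplicated(pre$participant_id), , drop = FALSE]
  m <- merge(pre, keep[, c("participant_id", "vaccine", "responder")],
             by = "participant_id", suffixes = c("", ".resp"))
  if (!nrow(m)) stop("no pre-vaccination sample with a high/low response label")
  feats <- intersect(features, rownames(x$expression))
  list(x = t(x$expression[feats, m$sample_id, drop = FALSE]),
       y = m$responder == "high",
       meta = data.frame(participant_id = m$participant_id,
                         vaccine = m$vaccine, sample_id = m$sample_id,
                         stringsAsFactors = FALSE))
}

#' Select the top-variance genes
#'
#' Genes ranked by variance across pre-vaccination samples of participants
#' with available antibody-response data; ties broken by gene symbol
#' (lexicographic), so selection is deterministic.
#'
#' @param x a [compendium()].
#' @param responses a `response_table` (participants with an MFC).
#' @param n number of genes to return (default 500).
#' @return Character vector of gene symbols.
#' @export
select_features <- function(x, responses, n = 500L) {
  pre <- x$samples[is_prevax(x$samples$day) &
                     x$samples$participant_id %in% responses$participant_id, ,
                   drop = FALSE]
  if (!nrow(pre)) stop("no qualifying pre-vaccination sample")
  expr <- x$expression[, pre$sample_id, drop = FALSE]
  v <- apply(expr, 1, stats::var)
  ord <- order(-v, rownames(expr))
  genes <- rownames(expr)[ord]
  if (length(genes) < n) {
    warning("fewer than ", n, " genes available; returning all ",
            length(genes))
    return(genes)
  }
  genes[seq_len(n)]
}

oob_auroc <- function(fit, y) {
  votes <- fit$votes[, "TRUE"]
  auroc(votes, y)
}

#' Train and evaluate the high-vs-low responder classifier
#'
#' Outer stratified `n_folds`-fold cross-validation; within each training
#' fold the per-split feature count (`mtry` over sqrt(p), p/10, p/3) is
#' selected by the forest's out-of-bag auROC; the report is computed on the
#' pooled out-of-fold predicted probabilities. A final forest on all samples
#' (same tuning) provides the feature importances. A label-permutation null
#' on the pooled out-of-fold predictions gives the auROC p-value. Fully
#' deterministic for a fixed seed (single-threaded).
#'
#' @param x a [compendium()] (batch-corrected pre-vaccination expression).
#' @param responses a `response_table` with `responder` classes; moderate
#'   responders are excluded.
#' @param features gene symbols to use, e.g. from [select_features()].
#' @param n_folds outer folds (default 10).
#' @param seed integer seed.
#' @param n_trees trees per forest (default 500).
#' @param n_perm label permutations for the auROC null (default 1000).
#' @return Object of class `classifier_report`.
#' @export
train_evaluate <- function(x, responses, features, n_folds = 10L, seed = 1L,
                           n_trees = 500L, n_perm = 1000L) {
  des <- classifier_design(x, responses, features)
  y <- des$y
  if (length(unique(y)) < 2L) stop("need both classes present")
  if (min(table(y)) < n_folds) {
    stop("smallest class (", min(table(y)), ") has fewer members than folds (",
         n_folds, ")")
  }
  p <- ncol(des$x)
  mtry.grid <- sort(unique(pmax(1L, floor(c(sqrt(p), p / 10, p / 3)))))

  # stratified fold assignment
  fold <- integer(length(y))
  fold[] <- NA_integer_
  fold <- with_seed(seed, {
    f <- integer(length(y))
    for (cls in c(TRUE, FALSE)) {
      i <- which(y == cls)
      f[i] <- sample(rep_len(seq_len(n_folds), length(i)))
    }
    f
  })

  prob <- numeric(length(y))
  tuning <- list()
  for (k in seq_len(n_folds)) {
    tr <- fold != k; te <- fold == k
    scores <- vapply(seq_along(mtry.grid), function(j) {
      fit <- with_seed(seed + 1000L * k + j, randomForest::randomForest(
        x = des$x[tr, , drop = FALSE], y = factor(y[tr], levels = c(FALSE, TRUE)),
        ntree = n_trees, mtry = mtry.grid[j]))
      oob_auroc(fit, y[tr])
    }, numeric(1))
    best <- mtry.grid[which.max(scores)]
    fit <- with_seed(seed + 1000L * k + 500L, randomForest::randomForest(
      x = des$x[tr, , drop = FALSE], y = factor(y[tr], levels = c(FALSE, TRUE)),
      ntree = n_trees, mtry = best))
    prob[te] <- stats::predict(fit, des$x[te, , drop = FALSE],
                               type = "prob")[, "TRUE"]
    tuning[[k]] <- data.frame(fold = k, mtry = mtry.grid, oob_auroc = scores,
                              chosen = mtry.grid == best)
  }

  # final forest on all data for importances (tuned the same way)
  final.scores <- vapply(seq_along(mtry.grid), function(j) {
    fit <- with_seed(seed + 77L + j, randomForest::randomForest(
      x = des$x, y = factor(y, levels = c(FALSE, TRUE)),
      ntree = n_trees, mtry = mtry.grid[j]))
    oob_auroc(fit, y)
  }, numeric(1))
  final <- with_seed(seed + 88L, randomForest::randomForest(
    x = des$x, y = factor(y, levels = c(FALSE, TRUE)), ntree = n_trees,
    mtry = mtry.grid[which.max(final.scores)], importance = FALSE))
  imp <- randomForest::importance(final, type = 2)[, 1]

  pred <- prob >= 0.5
  tp <- sum(pred & y); tn <- sum(!pred & !y)
  fp <- sum(pred & !y); fn <- sum(!pred & y)
  perm <- auroc_perm_test(prob, y, n_perm = n_perm, seed = seed + 99L)
  per.vaccine <- vapply(unique(des$meta$vaccine), function(v) {
    i <- des$meta$vaccine == v
    if (length(unique(y[i])) < 2L) return(NA_real_)
    auroc(prob[i], y[i])
  }, numeric(1))

  res <- list(
    predictions = data.frame(des$meta, label = y, fold = fold, prob = prob,
                             stringsAsFactors = FALSE),
    metrics = c(auroc = perm$auroc,
                accuracy = (tp + tn) / length(y),
                ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
                sensitivity = tp / (tp + fn),
                specificity = tn / (tn + fp),
                brier = mean((prob - as.numeric(y))^2)),
    auroc_p = perm$p_value,
    per_vaccine_auroc = per.vaccine,
    importance = imp,
    tuning = do.call(rbind, tuning),
    n_folds = as.integer(n_folds), n_trees = as.integer(n_trees),
    features = colnames(des$x), seed = as.integer(seed),
    stratification = "class")
  class(res) <- "classifier_report"
  res
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("classifier_report: %d samples, %d features, %d-fold CV\n",
              nrow(x$predictions), length(x$features), x$n_folds))
  print(round(x$metrics, 4))
  cat(sprintf("auROC permutation p = %g\n", x$auroc_p))
  invisible(x)
}

#' Genes above a scaled-importance threshold
#'
#' Importances are min-max scaled to \[0, 100\] (max = 100); genes strictly
#' above `threshold_pct` are returned, most important first.
#'
#' @param report a `classifier_report`.
#' @param threshold_pct threshold on the scaled importance (e.g. 50).
#' @return Character vector of gene symbols (possibly empty).
#' @export
scaled_importance <- function(report, threshold_pct) {
  imp <- report$importance
  if (all(imp == 0)) {
    warning("all importances are zero")
    return(character(0))
  }
  scaled <- 100 * (imp - min(imp)) / (max(imp) - min(imp))
  sel <- scaled > threshold_pct
  names(sort(scaled[sel], decreasing = TRUE))
}

#' Construct a gene signature
#'
#' @param name signature name.
#' @param up_genes,down_genes disjoint gene symbol vectors; at least one gene
#'   in total (`down_genes` may be empty).
#' @return Object of class `signature`.
#' @export
gene_signature <- function(name, up_genes, down_genes = character(0)) {
  if (length(intersect(up_genes, down_genes))) {
    stop("up and down genes overlap")
  }
  if (!length(up_genes) && !length(down_genes)) stop("empty signature")
  structure(list(name = name, up_genes = up_genes, down_genes = down_genes),
            class = "signature")
}

#' Score a fixed signature and test it against responder labels
#'
#' Sample score = mean log2 expression of the present up genes minus mean of
#' the present down genes (an empty side contributes 0); auROC of the score
#' for high vs low responders; significance by label permutation:
#' `p = (1 + #\{auROC_perm >= observed\}) / (n_perm + 1)`.
#'
#' @param x a [compendium()].
#' @param responses a `response_table` with responder classes.
#' @param sig a [gene_signature()].
#' @param n_perm label permutations (default 1000).
#' @param seed integer seed.
#' @return List with `scores` (named per sample), `auroc`, `p_value`,
#'   `genes_used`.
#' @export
signature_auroc <- function(x, responses, sig, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(sig, "signature"))
  up <- intersect(sig$up_genes, rownames(x$expression))
  down <- intersect(sig$down_genes, rownames(x$expression))
  if (!length(up) && !length(down)) {
    stop("no signature gene present in the matrix; missing: ",
         paste(c(sig$up_genes, sig$down_genes), collapse = ", "))
  }
  des <- classifier_design(x, responses)
  expr <- x$expression[, des$meta$sample_id, drop = FALSE]
  score <- (if (length(up)) colMeans(expr[up, , drop = FALSE]) else 0) -
    (if (length(down)) colMeans(expr[down, , drop = FALSE]) else 0)
  perm <- auroc_perm_test(score, des$y, n_perm = n_perm, seed = seed)
  list(scores = stats::setNames(score, des$meta$sample_id),
       auroc = perm$auroc, p_value = perm$p_value,
       genes_used = c(up, down))
}
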