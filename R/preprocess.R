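#' @title Within-study normalization and cross-study batch correction
#' @description Expression values are quantile normalized within each study
#'   (columns of a study become permutations of one common vector), then a
#'   per-gene ordinary least squares model with categorical platform, study
#'   and sample-type effects is fitted on pre-vaccination samples (day -7 and
#'   day 0) only, and the estimated effects are subtracted from all samples,
#'   before and after vaccination. Because studies are typically nested in
#'   platform and processed with a single sample type, the design is usually
#'   rank deficient; aliased columns are dropped in a fixed order (platform
#'   first, then sample type, with study always retained) and recorded.
#' @name preprocess
NULL

#' Quantile normalize within each study
#'
#' Within each study, every sample's sorted values are replaced by the
#' across-sample mean of order statistics; tied input values receive the mean
#' of the normalized values at their tied ranks. Studies with a single sample
#' are returned unchanged.
#'
#' @param x a [compendium()] of log-scale values.
#' @return A new compendium with normalized expression.
#' @export
quantile_normalize_within_study <- function(x) {
  stopifnot(inherits(x, "compendium"))
  expr <- x$expression
  for (st in unique(x$samples$study_id)) {
    cols <- x$samples$sample_id[x$samples$study_id == st]
    if (length(cols) < 2L) next
    expr[, cols] <- limma::normalizeQuantiles(expr[, cols, drop = FALSE],
                                              ties = TRUE)
  }
  compendium(expr, x$samples, gene_sets = x$gene_sets)
}

# Build the categorical design matrix in the fixed column order
# (intercept, study, sample_type, platform) used for aliasing decisions.
batch_design <- function(samples, levels = NULL) {
  mk <- function(col, lv) {
    v <- as.character(samples[[col]])
    if (is.null(lv)) lv <- sort(unique(v))
    unseen <- setdiff(unique(v), lv)
    if (length(unseen)) {
      stop(sprintf("unseen %s level(s): %s", col,
                   paste(unseen, collapse = ", ")))
    }
    f <- factor(v, levels = lv)
    if (nlevels(f) < 2L) {
      return(list(mat = matrix(numeric(0), nrow(samples), 0), levels = lv))
    }
    m <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(m) <- paste0(col, ":", lv[-1])
    list(mat = m, levels = lv)
  }
  st <- mk("study_id", levels$study_id)
  ty <- mk("sample_type", levels$sample_type)
  pl <- mk("platform", levels$platform)
  X <- cbind(`(Intercept)` = 1, st$mat, ty$mat, pl$mat)
  list(X = X,
       levels = list(study_id = st$levels, sample_type = ty$levels,
                     platform = pl$levels))
}

#' Fit the cross-study batch model on pre-vaccination samples
#'
#' Per-gene OLS of expression on categorical study, sample type and platform,
#' using only day -7 / day 0 samples. Aliased (rank-deficient) columns are
#' dropped greedily in the order platform before sample type before study
#' (study columns are added to the design first, so confounded variance is
#' absorbed by the finer study factor); dropped columns are reported in the
#' model. Factors with a single level are omitted with a message.
#'
#' @param x a [compendium()].
#' @return An object of class `batch_model` with per-gene coefficients for
#'   the retained columns, the aliased column names, and the factor levels.
#' @export
fit_batch_model <- function(x) {
  stopifnot(inherits(x, "compendium"))
  pre <- x$samples[is_prevax(x$samples$day), , drop = FALSE]
  if (nrow(pre) < 2L) stop("need >= 2 pre-vaccination (day -7/0) samples")
  for (col in c("study_id", "sample_type", "platform")) {
    if (length(unique(pre[[col]])) < 2L) {
      message("batch model: factor '", col,
              "' has a single level and is omitted")
    }
  }
  des <- batch_design(pre)
  X <- des$X
  # greedy rank pruning in column order: intercept, study, sample_type, platform
  keep <- logical(ncol(X))
  cur <- matrix(numeric(0), nrow(X), 0)
  for (j in seq_len(ncol(X))) {
    cand <- cbind(cur, X[, j])
    if (qr(cand)$rank > ncol(cur)) {
      keep[j] <- TRUE
      cur <- cand
    }
  }
  aliased <- colnames(X)[!keep]
  Xk <- X[, keep, drop = FALSE]
  Y <- t(x$expression[, pre$sample_id, drop = FALSE])
  fit <- stats::lm.fit(Xk, Y)
  coefs <- t(fit$coefficients)  # genes x kept columns
  structure(list(coefficients = coefs, aliased = aliased,
                 columns = colnames(Xk), levels = des$levels),
            class = "batch_model")
}

#' @export
print.batch_model <- function(x, ...) {
  cat(sprintf("batch_model: %d genes, columns: %s\n",
              nrow(x$coefficients), paste(x$columns, collapse = ", ")))
  if (length(x$aliased)) {
    cat("  aliased (dropped):", paste(x$aliased, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subtract estimated batch effects from all samples
#'
#' The non-intercept fitted batch component for each sample's factor levels
#' is subtracted from its expression at every time point; the per-gene
#' intercept (grand level) is retained.
#'
#' @param x a [compendium()].
#' @param model a `batch_model` from [fit_batch_model()]; samples with factor
#'   levels unseen at fit time raise an error.
#' @return The corrected compendium.
#' @export
apply_batch_correction <- function(x, model) {
  stopifnot(inherits(x, "compendium"), inherits(model, "batch_model"))
  des <- batch_design(x$samples, levels = model$levels)
  X <- des$X[, model$columns, drop = FALSE]
  nonint <- model$columns != "(Intercept)"
  if (!any(nonint)) return(x)
  batch <- model$coefficients[, nonint, drop = FALSE] %*%
    t(X[, nonint, drop = FALSE])
  expr <- x$expression - batch
  compendium(expr, x$samples, gene_sets = x$gene_sets)
}
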