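#' @title Principal variance component analysis (PVCA)
#' @description Attributes transcriptome variance to categorical factors:
#'   principal components are computed on the sample-by-sample covariance of
#'   gene-standardized expression, the smallest PC set reaching a cumulative
#'   variance threshold is retained, all factors are fitted jointly as random
#'   effects per PC (REML via lme4, with a method-of-moments fallback), and
#'   per-factor fractions are the eigenvalue-weighted averages of the per-PC
#'   normalized variance components, the remainder labeled `resid`.
#'   Percentile bootstrap confidence intervals resample participants (all
#'   their samples together) to respect repeated measures.
#' @name pvca
NULL

#' Encode metadata columns as categorical PVCA factors
#'
#' Age is binned into 10-year intervals (`"20-29"`, ...); day values above 20
#' are collapsed to a single `">=20"` level while days <= 20 stay distinct;
#' missing values become an explicit `"missing"` level; everything else is
#' coded as its character value.
#'
#' @param samples sample metadata table.
#' @param factors character vector of column names to encode.
#' @return data.frame of factor columns, one row per sample.
#' @export
encode_factors <- function(samples, factors) {
  missing.cols <- setdiff(factors, names(samples))
  if (length(missing.cols)) {
    stop("unknown column(s): ", paste(missing.cols, collapse = ", "))
  }
  out <- lapply(factors, function(col) {
    v <- samples[[col]]
    enc <- if (col %in% c("age", "age_years")) {
      lo <- floor(as.numeric(v) / 10) * 10
      sprintf("%d-%d", as.integer(lo), as.integer(lo) + 9L)
    } else if (col == "day") {
      d <- as.integer(v)
      ifelse(d > 20L, ">=20", as.character(d))
    } else {
      as.character(v)
    }
    enc[is.na(v) | is.na(enc)] <- "missing"
    factor(enc)
  })
  names(out) <- factors
  as.data.frame(out, row.names = samples$sample_id,
                stringsAsFactors = FALSE, check.names = FALSE)
}

# point-estimate PVCA on an expression matrix + encoded factor table
pvca_point <- function(expr, design, threshold) {
  Z <- standardize_genes(expr)
  n <- ncol(Z)
  C <- crossprod(Z) / max(1, nrow(Z) - 1)
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  if (sum(ev) <= 0) stop("degenerate expression matrix (zero variance)")
  cum <- cumsum(ev) / sum(ev)
  n.pc <- which(cum >= threshold)[1]
  if (is.na(n.pc)) n.pc <- length(ev)
  # weights are each retained PC's share of *total* variance; the discarded
  # tail therefore accrues to the residual ("remainder") below
  w <- ev[seq_len(n.pc)] / sum(ev)
  fac.names <- names(design)
  frac <- matrix(0, n.pc, length(fac.names) + 1L,
                 dimnames = list(NULL, c(fac.names, "resid")))
  usable <- vapply(design, function(f) {
    nlevels(droplevels(f)) >= 2L && nlevels(droplevels(f)) < n
  }, logical(1))
  for (i in seq_len(n.pc)) {
    y <- eig$vectors[, i]
    comp <- fit_variance_components(y, design[, usable, drop = FALSE])
    tot <- sum(comp$vc) + comp$resid
    if (tot <= 0) {
      frac[i, "resid"] <- 1
    } else {
      frac[i, names(comp$vc)] <- comp$vc / tot
      frac[i, "resid"] <- comp$resid / tot
    }
  }
  fractions <- as.vector(w %*% frac)
  names(fractions) <- colnames(frac)
  fractions["resid"] <- 1 - sum(fractions[fac.names])
  list(fractions = fractions, n_pcs = n.pc, pc_weights = w,
       eigenvalues = ev[seq_len(n.pc)])
}

# REML via lme4 (all factors jointly), method-of-moments fallback
fit_variance_components <- function(y, design) {
  if (!ncol(design)) return(list(vc = numeric(0), resid = stats::var(y)))
  dat <- cbind(data.frame(.y = y), design)
  terms <- vapply(names(design), function(f) sprintf("(1 | `%s`)", f),
                  character(1))
  form <- stats::as.formula(paste(".y ~ 1 +", paste(terms, collapse = " + ")))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(form, data = dat, REML = TRUE,
                 control = lme4::lmerControl(
                   check.nobs.vs.nlev = "ignore",
                   check.nobs.vs.rankZ = "ignore",
                   check.nobs.vs.nRE = "ignore",
                   calc.derivs = FALSE))
    )),
    error = function(e) NULL)
  if (!is.null(fit)) {
    vc <- lme4::VarCorr(fit)
    comps <- vapply(names(design), function(f) {
      v <- vc[[f]]
      if (is.null(v)) 0 else as.numeric(v[1, 1])
    }, numeric(1))
    return(list(vc = pmax(comps, 0), resid = attr(vc, "sc")^2))
  }
  # fallback: one-way method-of-moments per factor on level-mean contrasts
  comps <- vapply(names(design), function(f) {
    g <- droplevels(design[[f]])
    icc <- one_way_icc(y, g)
    if (is.na(icc)) 0 else icc * stats::var(y)
  }, numeric(1))
  resid <- max(0, stats::var(y) - sum(comps))
  list(vc = comps, resid = resid)
}

#' PVCA with participant-level bootstrap confidence intervals
#'
#' @param x a [compendium()].
#' @param factors metadata columns to attribute variance to (encoded by
#'   [encode_factors()]); a factor with as many levels as samples is
#'   unidentifiable and dropped with a warning.
#' @param threshold cumulative PC variance retained (default 0.60).
#' @param n_bootstrap bootstrap replicates (participants resampled with
#'   replacement); 0 skips the bootstrap.
#' @param seed integer seed for the bootstrap.
#' @return Object of class `pvca_result`: point-estimate `fractions` (sum to
#'   1, `resid` included), bootstrap `boot_mean` / `ci_lower` / `ci_upper`,
#'   `n_pcs`, `pc_weights`, `n_bootstrap`.
#' @export
pvca <- function(x, factors, threshold = 0.6, n_bootstrap = 100L, seed = 1L) {
  stopifnot(inherits(x, "compendium"))
  if (ncol(x$expression) < 2L) stop("need >= 2 samples")
  if (!length(factors)) stop("need >= 1 factor")
  design <- encode_factors(x$samples, factors)
  n <- ncol(x$expression)
  saturated <- vapply(design, function(f) nlevels(droplevels(f)) >= n,
                      logical(1))
  if (any(saturated)) {
    warning("factor(s) with as many levels as samples are unidentifiable ",
            "and were dropped: ",
            paste(names(design)[saturated], collapse = ", "))
    design <- design[, !saturated, drop = FALSE]
    if (!ncol(design)) stop("no identifiable factor left")
  }
  point <- pvca_point(x$expression, design, threshold)

  boot <- NULL
  if (n_bootstrap > 0L) {
    parts <- split(seq_len(n), x$samples$participant_id)
    boot <- with_seed(seed, {
      vapply(seq_len(n_bootstrap), function(b) {
        take <- unlist(parts[sample.int(length(parts), replace = TRUE)],
                       use.names = FALSE)
        pvca_point(x$expression[, take, drop = FALSE],
                   droplevels(design[take, , drop = FALSE]),
                   threshold)$fractions[names(point$fractions)]
      }, numeric(length(point$fractions)))
    })
  }
  res <- list(fractions = point$fractions,
              n_pcs = point$n_pcs,
              pc_weights = point$pc_weights,
              n_bootstrap = as.integer(n_bootstrap),
              seed = as.integer(seed),
              threshold = threshold,
              boot_mean = if (!is.null(boot)) rowMeans(boot) else NULL,
              ci_lower = if (!is.null(boot)) {
                apply(boot, 1, stats::quantile, probs = 0.025, names = FALSE)
              } else NULL,
              ci_upper = if (!is.null(boot)) {
                apply(boot, 1, stats::quantile, probs = 0.975, names = FALSE)
              } else NULL)
  class(res) <- "pvca_result"
  res
}

#' @export
print.pvca_result <- function(x, ...) {
  cat(sprintf("pvca_result: %d PCs (threshold %.2f), %d bootstrap replicates\n",
              x$n_pcs, x$threshold, x$n_bootstrap))
  df <- data.frame(fraction = round(x$fractions, 4))
  if (!is.null(x$boot_mean)) {
    df$boot_mean <- round(x$boot_mean, 4)
    df$ci_lower <- round(x$ci_lower, 4)
    df$ci_upper <- round(x$ci_upper, 4)
  }
  print(df)
  invisible(x)
}
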