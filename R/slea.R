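#' @title Sample-level enrichment analysis (SLEA)
#' @description Per-sample gene-set activity z-scores: the mean standardized
#'   expression of a set's genes in a sample is compared against a null of
#'   random gene sets of the same size drawn from the whole matrix. Genes are
#'   standardized (centered and scaled across samples) before scoring so
#'   nulls are comparable across sets; the same random draws are reused for
#'   every set of a given size, removing set-to-set Monte-Carlo noise at
#'   equal size. Member-set z-scores can be aggregated into the seven
#'   superset scores used for endotype discovery.
#' @name slea
NULL

# center/scale each gene (row) across samples; constant genes become all-zero
standardize_genes <- function(expr) {
  mu <- rowMeans(expr)
  sd <- apply(expr, 1, stats::sd)
  z <- (expr - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' SLEA z-scores for a gene-set collection
#'
#' For a set `S` of effective size `m` (genes found in the matrix) and sample
#' `s`: `observed = mean standardized expression of S's genes in s`; the null
#' is the distribution of means of random `m`-gene sets (drawn without
#' replacement from all matrix genes; the same draws are shared across sets
#' of size `m`); `z = (observed - null_mean) / null_sd`, defined as 0 when
#' the null sd is 0. Sets with no matched genes are dropped with a warning;
#' sets below `min_size` matched genes are filtered out.
#'
#' @param x a [compendium()] (typically batch-corrected).
#' @param gene_sets a [gene_set_collection()]; defaults to the one attached
#'   to the compendium.
#' @param n_permutations random sets per size (>= 100 unless `exact`).
#' @param seed integer seed for the null draws.
#' @param min_size minimum effective set size retained (default 5).
#' @param exact if TRUE, enumerate all size-`m` subsets instead of sampling
#'   (only feasible for tiny universes; used for validation).
#' @return An object of class `slea_matrix`: z-score matrix (sets x samples)
#'   plus effective sizes, permutation count and seed.
#' @export
slea_zscores <- function(x, gene_sets = x$gene_sets, n_permutations = 1000L,
                         seed = 1L, min_size = 5L, exact = FALSE) {
  stopifnot(inherits(x, "compendium"), inherits(gene_sets, "gene_set_collection"))
  if (!exact && n_permutations < 100L) stop("n_permutations must be >= 100")
  Z <- standardize_genes(x$expression)
  genes <- rownames(Z)
  G <- length(genes)

  eff <- lapply(gene_sets$sets, function(g) intersect(g, genes))
  sizes <- lengths(eff)
  none <- names(sizes)[sizes == 0L]
  if (length(none)) {
    warning("dropping set(s) with no matched genes: ",
            paste(none, collapse = ", "))
  }
  small <- names(sizes)[sizes > 0L & sizes < min_size]
  keep <- names(sizes)[sizes >= min_size]
  if (!length(keep)) stop("no gene set with effective size >= ", min_size)
  eff <- eff[keep]
  sizes <- sizes[keep]

  # shared null per set size: null_mean(s), null_sd(s)
  nulls <- list()
  for (m in sort(unique(sizes))) {
    if (exact) {
      combos <- utils::combn(G, m)
      idx <- t(combos)
    } else {
      idx <- with_seed((seed + m) %% .Machine$integer.max,
                       t(replicate(n_permutations, sample.int(G, m))))
    }
    A <- matrix(0, nrow(idx), G)
    A[cbind(rep(seq_len(nrow(idx)), ncol(idx)), as.vector(idx))] <- 1 / m
    null.scores <- A %*% Z  # draws x samples
    nm <- colMeans(null.scores)
    nsd <- sqrt(colSums(sweep(null.scores, 2, nm)^2) /
                  max(1, nrow(null.scores) - 1))
    nulls[[as.character(m)]] <- list(mean = nm, sd = nsd)
  }

  z <- matrix(0, length(keep), ncol(Z),
              dimnames = list(keep, colnames(Z)))
  for (nm in keep) {
    obs <- colMeans(Z[eff[[nm]], , drop = FALSE])
    nl <- nulls[[as.character(sizes[[nm]])]]
    zi <- (obs - nl$mean) / ifelse(nl$sd > 0, nl$sd, 1)
    zi[nl$sd == 0] <- 0
    z[nm, ] <- zi
  }
  structure(list(z = z, effective_size = sizes,
                 n_permutations = if (exact) NA_integer_ else as.integer(n_permutations),
                 seed = as.integer(seed),
                 dropped = c(none, small)),
            class = "slea_matrix")
}

#' @export
print.slea_matrix <- function(x, ...) {
  cat(sprintf("slea_matrix: %d gene sets x %d samples", nrow(x$z), ncol(x$z)))
  if (is.na(x$n_permutations)) cat(" (exact null)\n")
  else cat(sprintf(" (%d permutations, seed %d)\n", x$n_permutations, x$seed))
  invisible(x)
}

#' Restrict an SLEA matrix to a set of samples
#'
#' @param slea a `slea_matrix`.
#' @param sample_ids sample ids to keep (column subset).
#' @return A `slea_matrix` over the requested samples.
#' @export
subset_slea <- function(slea, sample_ids) {
  structure(list(z = slea$z[, sample_ids, drop = FALSE],
                 effective_size = slea$effective_size,
                 n_permutations = slea$n_permutations, seed = slea$seed,
                 dropped = slea$dropped),
            class = "slea_matrix")
}

#' Aggregate member-set z-scores into superset scores
#'
#' Superset score per sample = unweighted mean of the z-scores of the member
#' sets mapped to it; supersets with no mapped set are omitted.
#'
#' @param slea a `slea_matrix` from [slea_zscores()].
#' @param gene_sets the [gene_set_collection()] carrying `superset_map`.
#' @return A `slea_matrix` with at most seven rows (one per superset).
#' @export
superset_scores <- function(slea, gene_sets) {
  stopifnot(inherits(slea, "slea_matrix"))
  map <- gene_sets$superset_map
  if (is.null(map) || !length(map)) stop("superset_map is absent")
  map <- map[names(map) %in% rownames(slea$z)]
  labs <- intersect(SUPERSET_LABELS, unique(map))
  z <- t(vapply(labs, function(lab) {
    members <- names(map)[map == lab]
    colMeans(slea$z[members, , drop = FALSE])
  }, numeric(ncol(slea$z))))
  rownames(z) <- labs
  colnames(z) <- colnames(slea$z)
  structure(list(z = z,
                 effective_size = stats::setNames(
                   vapply(labs, function(lab) sum(map == lab), integer(1)), labs),
                 n_permutations = slea$n_permutations, seed = slea$seed,
                 dropped = character(0)),
            class = "slea_matrix")
}
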