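#' @title Pre-vaccination endotype discovery
#' @description Samples are clustered on their SLEA profiles by agglomerative
#'   hierarchical clustering (Euclidean distance, complete linkage); the
#'   number of clusters is selected by the Gap statistic with a uniform
#'   reference over the per-feature range and the one-standard-error rule;
#'   the three clusters are labeled `inflam.lo` / `inflam.mid` / `inflam.hi`
#'   by their mean inflammatory SLEA score; and a temporal stability metric
#'   (between-participant fraction of variance across repeated pre-vaccination
#'   and late samples) quantifies how trait-like the profiles are.
#' @name endotype
NULL

INFLAMMATORY_HALLMARK_SETS <- c("HALLMARK_INFLAMMATORY_RESPONSE",
                                "HALLMARK_COMPLEMENT",
                                "HALLMARK_IL6_JAK_STAT3_SIGNALING",
                                "HALLMARK_TNFA_SIGNALING_VIA_NFKB")

slea_z <- function(x) {
  if (inherits(x, "slea_matrix")) x$z else as.matrix(x)
}

#' Hierarchical clustering of samples on SLEA profiles
#'
#' Euclidean distance on the SLEA column vectors, complete linkage, dendrogram
#' cut to exactly `k` clusters. Deterministic given input order (ties resolved
#' by `stats::hclust`'s fixed merge order).
#'
#' @param slea a `slea_matrix` (or plain feature x sample matrix).
#' @param k number of clusters (1..n_samples).
#' @return Integer cluster ids named by sample id.
#' @export
hierarchical_clusters <- function(slea, k) {
  z <- slea_z(slea)
  n <- ncol(z)
  if (k < 1L || k > n) stop("k must be in 1..", n)
  if (k == 1L) return(stats::setNames(rep(1L, n), colnames(z)))
  hc <- stats::hclust(stats::dist(t(z), method = "euclidean"),
                      method = "complete")
  stats::cutree(hc, k = k)
}

# within-cluster dispersion W_k = sum_r D_r / (2 n_r), D_r the sum of
# pairwise squared Euclidean distances over ordered pairs in cluster r
within_dispersion <- function(points, cluster) {
  total <- 0
  for (cl in unique(cluster)) {
    p <- points[cluster == cl, , drop = FALSE]
    nr <- nrow(p)
    if (nr < 2L) next
    d2 <- as.matrix(stats::dist(p))^2
    total <- total + sum(d2) / (2 * nr)
  }
  total
}

#' Gap statistic for the number of clusters
#'
#' `Gap(k) = mean_ref[log W_k(ref)] - log W_k(data)` where `W_k` is the
#' within-cluster dispersion of the hierarchical clustering cut at `k` and the
#' reference datasets are uniform over each feature's observed range. The
#' chosen k is the smallest k with `Gap(k) >= Gap(k+1) - se(k+1)`
#' (one-standard-error rule, `se = sd_ref(log W) * sqrt(1 + 1/n_ref)`).
#'
#' @param slea a `slea_matrix` (or feature x sample matrix), typically
#'   restricted to pre-vaccination samples.
#' @param k_max largest k considered (>= 2).
#' @param n_ref number of reference datasets (>= 10).
#' @param seed integer seed for the reference draws.
#' @return List with `gap` (data.frame k, gap, se, log_w) and `k` (chosen).
#' @export
gap_statistic <- function(slea, k_max = 6L, n_ref = 50L, seed = 1L) {
  if (k_max < 2L) stop("k_max must be >= 2")
  if (n_ref < 10L) stop("n_ref must be >= 10")
  z <- slea_z(slea)
  pts <- t(z)  # samples x features
  if (nrow(pts) <= k_max) stop("need more samples than k_max")
  if (all(stats::dist(pts) < 1e-12)) {
    warning("all points identical; k = 1")
    return(list(gap = NULL, k = 1L))
  }
  ks <- seq_len(k_max)
  log.w <- vapply(ks, function(k) {
    log(within_dispersion(pts, hierarchical_clusters(z, k)))
  }, numeric(1))
  rng.lo <- apply(pts, 2, min)
  rng.hi <- apply(pts, 2, max)
  ref.log.w <- with_seed(seed, {
    vapply(seq_len(n_ref), function(b) {
      ref <- sapply(seq_along(rng.lo), function(j) {
        stats::runif(nrow(pts), rng.lo[j], rng.hi[j])
      })
      refz <- t(ref)
      vapply(ks, function(k) {
        log(within_dispersion(ref, hierarchical_clusters(refz, k)))
      }, numeric(1))
    }, numeric(length(ks)))
  })  # k x n_ref
  gap <- rowMeans(ref.log.w) - log.w
  se <- apply(ref.log.w, 1, stats::sd) * sqrt(1 + 1 / n_ref)
  chosen <- NA_integer_
  for (k in seq_len(k_max - 1L)) {
    if (gap[k] >= gap[k + 1L] - se[k + 1L]) { chosen <- k; break }
  }
  if (is.na(chosen)) chosen <- k_max
  list(gap = data.frame(k = ks, gap = gap, se = se, log_w = log.w),
       k = as.integer(chosen))
}

#' Label three clusters as inflammatory endotypes
#'
#' The per-sample inflammatory score is the mean SLEA z-score over the
#' supplied inflammatory gene sets (by default the four hallmark inflammatory
#' sets). Clusters are ranked by their mean score and labeled
#' `inflam.lo` < `inflam.mid` < `inflam.hi`; each sample is also annotated
#' with its inflammatory tertile (type-7 empirical quantiles at 1/3 and 2/3,
#' ties to the lower bin).
#'
#' @param clusters integer cluster ids (exactly 3 distinct values) named by
#'   sample id, e.g. from [hierarchical_clusters()].
#' @param slea the `slea_matrix` the clustering was computed on.
#' @param inflammatory_sets character vector of SLEA row names whose mean
#'   defines the inflammatory score.
#' @return data.frame of class `endotype_assignment` with columns sample_id,
#'   cluster, endotype, inflam_score, tertile.
#' @export
label_endotypes <- function(clusters, slea,
                            inflammatory_sets = INFLAMMATORY_HALLMARK_SETS) {
  z <- slea_z(slea)
  if (length(unique(clusters)) != 3L) {
    stop("expected exactly 3 clusters; for other k use the raw cluster ids")
  }
  missing.sets <- setdiff(inflammatory_sets, rownames(z))
  if (length(missing.sets)) {
    stop("inflammatory set(s) not in SLEA matrix: ",
         paste(missing.sets, collapse = ", "))
  }
  ids <- names(clusters)
  score <- colMeans(z[inflammatory_sets, ids, drop = FALSE])
  cl.mean <- tapply(score, clusters, mean)
  ord <- order(cl.mean)  # ascending score
  lab.map <- stats::setNames(ENDOTYPE_LEVELS, names(cl.mean)[ord])
  q <- stats::quantile(score, probs = c(1, 2) / 3, type = 7, names = FALSE)
  tertile <- ifelse(score <= q[1], "low", ifelse(score <= q[2], "mid", "high"))
  out <- data.frame(sample_id = ids,
                    cluster = as.integer(clusters),
                    endotype = unname(lab.map[as.character(clusters)]),
                    inflam_score = unname(score),
                    tertile = tertile,
                    stringsAsFactors = FALSE)
  class(out) <- c("endotype_assignment", "data.frame")
  out
}

#' Participant-level consensus endotype
#'
#' Majority endotype label across a participant's labeled samples; ties are
#' broken by the participant's mean inflammatory score (higher score wins the
#' more inflammatory label).
#'
#' @param assignment an `endotype_assignment`.
#' @param samples the sample metadata table (for participant ids).
#' @return data.frame with participant_id, endotype, mean inflammatory score.
#' @export
participant_endotypes <- function(assignment, samples) {
  m <- merge(assignment, samples[, c("sample_id", "participant_id")],
             by = "sample_id")
  out <- do.call(rbind, lapply(split(m, m$participant_id), function(d) {
    tab <- table(d$endotype)
    top <- names(tab)[tab == max(tab)]
    lab <- if (length(top) == 1L) top else {
      # tie: pick the label whose rank matches the participant's mean score
      sc <- mean(d$inflam_score)
      top[order(match(top, ENDOTYPE_LEVELS))][
        if (sc >= 0) length(top) else 1L]
    }
    data.frame(participant_id = d$participant_id[1], endotype = lab,
               inflam_score = mean(d$inflam_score),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Temporal stability of SLEA profiles
#'
#' For each gene set, a one-way random-effects decomposition of the SLEA
#' scores of *eligible* samples (day -7, day 0, or day >= 70) across
#' participants: stability = between-participant variance / total variance,
#' truncated to \[0, 1\] (method-of-moments estimator). The aggregate is the
#' mean over sets.
#'
#' @param slea a `slea_matrix` over all samples.
#' @param samples the sample metadata table.
#' @return List with `per_set` (named numeric) and `aggregate`.
#' @export
temporal_stability <- function(slea, samples) {
  z <- slea_z(slea)
  eligible <- samples[is_prevax(samples$day) | samples$day >= 70L, ,
                      drop = FALSE]
  eligible <- eligible[eligible$sample_id %in% colnames(z), , drop = FALSE]
  reps <- table(eligible$participant_id)
  if (!any(reps >= 2L)) {
    stop("no participant with repeated eligible samples (day -7/0 or >= 70)")
  }
  grp <- factor(eligible$participant_id)
  zz <- z[, eligible$sample_id, drop = FALSE]
  per.set <- apply(zz, 1, function(y) one_way_icc(y, grp))
  list(per_set = per.set, aggregate = mean(per.set))
}

# method-of-moments one-way random-effects intraclass correlation,
# truncated to [0, 1]
one_way_icc <- function(y, grp) {
  grp <- droplevels(grp)
  a <- nlevels(grp)
  n.i <- as.vector(table(grp))
  N <- length(y)
  if (a < 2L) return(NA_real_)
  mu.i <- tapply(y, grp, mean)
  mu <- mean(y)
  ssb <- sum(n.i * (mu.i - mu)^2)
  ssw <- sum((y - mu.i[grp])^2)
  msb <- ssb / (a - 1)
  dfw <- N - a
  msw <- if (dfw > 0) ssw / dfw else 0
  n0 <- (N - sum(n.i^2) / N) / (a - 1)
  sb2 <- max(0, (msb - msw) / n0)
  if (sb2 + msw <= 0) return(0)
  min(1, sb2 / (sb2 + msw))
}
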