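# Shared fixture builders: everything is generated in code at test time.

# minimal metadata row block
make_meta <- function(sample_id, study = "studyA", platform = "platform1",
                      sample_type = "whole_blood", vaccine = "influenza",
                      day = 0L, participant = sub("_d.*$", "", sample_id)) {
  data.frame(sample_id = sample_id, participant_id = participant,
             study_id = study, platform = platform, sample_type = sample_type,
             vaccine = vaccine, day = day, stringsAsFactors = FALSE)
}

# compendium with explicit expression values (genes x samples)
make_compendium <- function(expr, meta = NULL, gene_sets = NULL) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) {
    rownames(expr) <- sprintf("G%03d", seq_len(nrow(expr)))
  }
  if (is.null(colnames(expr))) {
    colnames(expr) <- if (!is.null(meta)) meta$sample_id
                      else sprintf("S%03d", seq_len(ncol(expr)))
  }
  if (is.null(meta)) meta <- make_meta(colnames(expr))
  compendium(expr, meta, gene_sets = gene_sets)
}

# random compendium: one study unless study vector given
random_compendium <- function(n_genes = 50, n_samples = 6, seed = 1,
                              meta = NULL) {
  set.seed(seed)
  expr <- matrix(rnorm(n_genes * n_samples, 6, 1), n_genes, n_samples)
  make_compendium(expr, meta = meta)
}

# brute-force two-sided Wilcoxon rank-sum p by enumeration of group
# assignments (two-sided convention: 2 * min tail, capped at 1)
enum_wilcoxon_p <- function(x, y) {
  r <- rank(c(x, y))
  n <- length(r); nx <- length(x)
  combos <- utils::combn(n, nx)
  sums <- colSums(matrix(r[combos], nrow = nx))
  w <- sum(r[seq_len(nx)])
  eps <- 1e-9
  min(1, 2 * min(mean(sums <= w + eps), mean(sums >= w - eps)))
}

# brute-force two-sided Fisher p: enumerate all tables with the observed
# margins, sum hypergeometric probabilities <= observed (with slack)
enum_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  probs <- vapply(max(0, r1 + c1 - n):min(r1, c1), function(a) {
    stats::dhyper(a, c1, n - c1, r1)
  }, numeric(1))
  obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# O(n^2) pairwise auROC oracle with ties counted one half
pairwise_auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# closed-form BH oracle
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  sorted <- p[ord] * m / seq_len(m)
  adj[ord] <- rev(cummin(rev(pmin(sorted, 1))))
  adj
}

# exact SLEA null (finite population): for sample values v and set size m,
# mean = mean(v), sd of a without-replacement subset mean
exact_subset_mean_sd <- function(v, m) {
  G <- length(v)
  pop.var <- sum((v - mean(v))^2) / G
  sqrt(pop.var / m * (G - m) / (G - 1))
}

# brute-force SLEA oracle: enumerate every m-subset of the universe and form
# the null from the subset means, independently of the package implementation
brute_force_slea <- function(expr, genes) {
  Z <- sweep(sweep(expr, 1, rowMeans(expr)), 1, apply(expr, 1, sd), "/")
  m <- length(genes)
  combos <- utils::combn(nrow(Z), m)
  null.means <- apply(combos, 2, function(ix) colMeans(Z[ix, , drop = FALSE]))
  obs <- colMeans(Z[genes, , drop = FALSE])
  nm <- rowMeans(null.means)
  nsd <- apply(null.means, 1, sd)
  z <- (obs - nm) / ifelse(nsd > 0, nsd, 1)
  z[nsd == 0] <- 0
  z
}

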