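# naive O(n^3) complete-linkage oracle returning merge heights
naive_complete_linkage_heights <- function(points) {
  d <- as.matrix(dist(points))
  clusters <- as.list(seq_len(nrow(points)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  heights
}

test_that("hierarchical clustering matches a brute-force complete-linkage oracle", {
  set.seed(1)
  z <- matrix(rnorm(5 * 8), 5, 8, dimnames = list(NULL, paste0("s", 1:8)))
  hc <- hclust(dist(t(z)), method = "complete")
  expect_equal(sort(hc$height), sort(naive_complete_linkage_heights(t(z))),
               tolerance = 1e-12)
  cl <- hierarchical_clusters(z, 3)
  expect_equal(sort(unique(cl)), 1:3)
  expect_named(cl, colnames(z))
})

test_that("well-separated blobs are recovered perfectly and duplicates co-cluster", {
  set.seed(2)
  centers <- c(0, 10, 20)
  z <- sapply(rep(1:3, each = 10), function(k) rnorm(4, centers[k], 0.1))
  colnames(z) <- sprintf("s%02d", 1:30)
  cl <- hierarchical_clusters(z, 3)
  expect_equal(adjusted_rand_index(cl, rep(1:3, each = 10)), 1)

  zdup <- cbind(z, z[, 1, drop = FALSE])
  colnames(zdup) <- sprintf("s%02d", 1:31)
  for (k in 2:5) {
    cld <- hierarchical_clusters(zdup, k)
    expect_equal(cld[[1]], cld[[31]])
  }
})

test_that("the Gap statistic picks 1 for a single blob and 3 for separated blobs", {
  set.seed(3)
  blob <- matrix(rnorm(4 * 40, 0, 1), 4, 40)
  g1 <- gap_statistic(blob, k_max = 5, n_ref = 30, seed = 4)
  expect_equal(g1$k, 1L)

  centers <- c(0, 8, 16)
  z <- sapply(rep(1:3, each = 15), function(k) rnorm(4, centers[k], 0.5))
  g3 <- gap_statistic(z, k_max = 6, n_ref = 30, seed = 5)
  expect_equal(g3$k, 3L)

  # invariance to feature permutation
  g3p <- gap_statistic(z[c(3, 1, 4, 2), ], k_max = 6, n_ref = 30, seed = 5)
  expect_equal(g3p$k, 3L)

  # degenerate data
  expect_warning(gd <- gap_statistic(matrix(1, 3, 10), k_max = 4, n_ref = 20),
                 "identical")
  expect_equal(gd$k, 1L)

  # reproducibility bit-for-bit under a fixed seed
  expect_identical(gap_statistic(z, k_max = 4, n_ref = 20, seed = 6)$gap,
                   gap_statistic(z, k_max = 4, n_ref = 20, seed = 6)$gap)
})

test_that("clusters are labeled by inflammatory score rank with tertile annotation", {
  z <- rbind(INFL = c(-1, -1, -1, 0, 0, 0, 1, 1, 1))
  colnames(z) <- paste0("s", 1:9)
  clusters <- setNames(c(2L, 2L, 2L, 3L, 3L, 3L, 1L, 1L, 1L), colnames(z))
  endo <- label_endotypes(clusters, z, inflammatory_sets = "INFL")
  expect_equal(endo$endotype[1:3], rep("inflam.lo", 3))
  expect_equal(endo$endotype[4:6], rep("inflam.mid", 3))
  expect_equal(endo$endotype[7:9], rep("inflam.hi", 3))

  # relabeling cluster ids leaves endotype labels unchanged
  clusters2 <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L), colnames(z))
  endo2 <- label_endotypes(clusters2, z, inflammatory_sets = "INFL")
  expect_equal(endo2$endotype, endo$endotype)

  # tertile rule on scores 1..9
  z9 <- rbind(INFL = as.numeric(1:9))
  colnames(z9) <- paste0("s", 1:9)
  e9 <- label_endotypes(setNames(rep(1:3, each = 3), colnames(z9)), z9,
                        inflammatory_sets = "INFL")
  expect_equal(e9$tertile, rep(c("low", "mid", "high"), each = 3))

  expect_error(label_endotypes(setNames(rep(1:2, c(5, 4)), colnames(z)), z,
                               inflammatory_sets = "INFL"), "3 clusters")
  expect_error(label_endotypes(clusters, z, inflammatory_sets = "MISSING"),
               "MISSING")
})

test_that("planted endotypes are recovered with high ARI and recovery improves with delta", {
  # batch effects are switched off to exercise the clustering in isolation;
  # the preprocess tests own batch-effect removal
  run_ari <- function(delta, seed) {
    cfg <- sim_config(n_studies = 3, participants_per_study = 15, n_genes = 210,
                      module_sizes = setNames(rep(15L, 7), vaxendo:::SUPERSET_LABELS),
                      endotype_effect_delta = delta, noise_sd = 0.25,
                      batch_sd = 0, platform_sd = 0, sampletype_sd = 0,
                      timepoints = c(0L), seed = seed)
    sim <- simulate_compendium(cfg)
    comp <- sim$compendium
    sl <- slea_zscores(comp, n_permutations = 200, seed = seed)
    cl <- hierarchical_clusters(sl, 3)
    endo <- label_endotypes(cl, sl, inflammatory_sets = "inflammation")
    pe <- participant_endotypes(endo, comp$samples)
    m <- merge(pe, sim$truth$participants, by = "participant_id")
    adjusted_rand_index(m$endotype.x, m$endotype.y)
  }
  ari_mean <- function(delta) mean(vapply(1:10, function(s) run_ari(delta, s),
                                          numeric(1)))
  aris <- vapply(c(0.25, 0.5, 1, 2), ari_mean, numeric(1))
  expect_true(all(diff(aris) >= -1e-9))
  expect_gte(aris[3], 0.9)
})

test_that("temporal stability is 1 for participant-constant scores and near 0 for iid noise", {
  meta <- rbind(make_meta(sprintf("P%02d_d0", 1:20), day = 0L,
                          participant = sprintf("P%02d", 1:20)),
                make_meta(sprintf("P%02d_d70", 1:20), day = 70L,
                          participant = sprintf("P%02d", 1:20)))
  set.seed(6)
  per.part <- matrix(rnorm(3 * 20), 3, 20)
  z <- cbind(per.part, per.part)
  colnames(z) <- meta$sample_id
  rownames(z) <- paste0("set", 1:3)
  st <- temporal_stability(z, meta)
  expect_equal(unname(st$per_set), rep(1, 3))
  expect_equal(st$aggregate, 1)

  meta3 <- do.call(rbind, lapply(c(-7L, 0L, 70L), function(d) {
    make_meta(sprintf("Q%02d_d%d", 1:50, d), day = d,
              participant = sprintf("Q%02d", 1:50))
  }))
  znull <- matrix(rnorm(4 * 150), 4, 150,
                  dimnames = list(paste0("set", 1:4), meta3$sample_id))
  stn <- temporal_stability(znull, meta3)
  expect_lte(stn$aggregate, 0.1)

  # error when no participant repeats
  meta1 <- make_meta(sprintf("R%02d_d0", 1:5), day = 0L,
                     participant = sprintf("R%02d", 1:5))
  z1 <- matrix(rnorm(10), 2, 5, dimnames = list(NULL, meta1$sample_id))
  expect_error(temporal_stability(z1, meta1), "repeated eligible")
})

test_that("participant-constant endotypes yield high aggregate stability on simulator output", {
  cfg <- sim_config(n_studies = 2, participants_per_study = 25, n_genes = 210,
                    module_sizes = setNames(rep(15L, 7), vaxendo:::SUPERSET_LABELS),
                    endotype_effect_delta = 1, noise_sd = 0.25,
                    timepoints = c(0L, 70L), seed = 10)
  sim <- simulate_compendium(cfg)
  comp <- apply_batch_correction(sim$compendium,
                                 fit_batch_model(sim$compendium))
  sl <- slea_zscores(comp, n_permutations = 200, seed = 3)
  st <- temporal_stability(sl, comp$samples)
  expect_gte(st$aggregate, 0.6)
})
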