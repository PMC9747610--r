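test_that("the same seed reproduces byte-identical compendia and titers", {
  cfg <- sim_config(n_studies = 2, participants_per_study = 6, n_genes = 120,
                    module_sizes = setNames(rep(10L, 7), vaxendo:::SUPERSET_LABELS),
                    timepoints = c(0L, 1L), seed = 5)
  a <- simulate_compendium(cfg)
  b <- simulate_compendium(cfg)
  expect_identical(a$compendium$expression, b$compendium$expression)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_titers(a$truth, cfg), simulate_titers(b$truth, cfg))
})

test_that("with all effect and noise sds zero, samples are identical within a time point", {
  cfg <- sim_config(n_studies = 2, participants_per_study = 5, n_genes = 120,
                    module_sizes = setNames(rep(10L, 7), vaxendo:::SUPERSET_LABELS),
                    endotype_effect_delta = 0, batch_sd = 0, platform_sd = 0,
                    sampletype_sd = 0, noise_sd = 0, timepoints = c(0L, 1L),
                    kinetic_attenuation = 1, seed = 2)
  sim <- simulate_compendium(cfg)
  for (d in c(0L, 1L)) {
    cols <- sim$compendium$samples$sample_id[sim$compendium$samples$day == d]
    e <- sim$compendium$expression[, cols]
    expect_lte(max(abs(e - e[, 1])), 1e-12)
  }
})

test_that("noiseless endotype gap on inflammation-module genes equals delta exactly", {
  cfg <- sim_config(n_studies = 1, participants_per_study = 30, n_genes = 120,
                    module_sizes = setNames(rep(10L, 7), vaxendo:::SUPERSET_LABELS),
                    endotype_effect_delta = 1.5, batch_sd = 0, platform_sd = 0,
                    sampletype_sd = 0, noise_sd = 0, timepoints = c(0L), seed = 3)
  sim <- simulate_compendium(cfg)
  truth <- sim$truth$participants
  genes <- sim$gene_sets$sets$inflammation
  expr <- sim$compendium$expression
  meta <- sim$compendium$samples
  mean_for <- function(lab) {
    ids <- meta$sample_id[meta$participant_id %in%
                            truth$participant_id[truth$endotype == lab]]
    mean(expr[genes, ids])
  }
  skip_if(sum(truth$endotype == "inflam.hi") == 0 ||
            sum(truth$endotype == "inflam.lo") == 0)
  expect_equal(mean_for("inflam.hi") - mean_for("inflam.lo"), 1.5,
               tolerance = 1e-12)
})

test_that("the empirical endotype module gap is within 3 SE of delta under noise", {
  cfg <- sim_config(n_studies = 3, participants_per_study = 30, n_genes = 300,
                    module_sizes = setNames(rep(20L, 7), vaxendo:::SUPERSET_LABELS),
                    endotype_effect_delta = 1, batch_sd = 0, platform_sd = 0,
                    sampletype_sd = 0, noise_sd = 0.25, timepoints = c(0L),
                    seed = 13)
  sim <- simulate_compendium(cfg)
  truth <- sim$truth$participants
  genes <- sim$gene_sets$sets$inflammation
  expr <- sim$compendium$expression
  meta <- sim$compendium$samples
  ids_for <- function(lab) {
    meta$sample_id[meta$participant_id %in%
                     truth$participant_id[truth$endotype == lab]]
  }
  hi <- ids_for("inflam.hi"); lo <- ids_for("inflam.lo")
  gap <- mean(expr[genes, hi]) - mean(expr[genes, lo])
  se <- 0.25 * sqrt(1 / (length(hi) * length(genes)) +
                      1 / (length(lo) * length(genes)))
  expect_lt(abs(gap - 1), 3 * se)
})

test_that("noiseless titers separate endotypes by exactly the planted effect", {
  cfg <- sim_config(n_studies = 2, participants_per_study = 10, n_genes = 120,
                    module_sizes = setNames(rep(10L, 7), vaxendo:::SUPERSET_LABELS),
                    titer_beta = 2, titer_noise_sd = 0, seed = 8)
  sim <- simulate_compendium(cfg)
  titers <- simulate_titers(sim$truth, cfg)
  resp <- suppressMessages(compute_mfc(titers))
  m <- merge(resp, sim$truth$participants, by = "participant_id")
  hi <- m$log2_mfc[m$endotype == "inflam.hi"]
  lo <- m$log2_mfc[m$endotype == "inflam.lo"]
  skip_if(length(hi) == 0 || length(lo) == 0)
  expect_equal(unique(round(hi, 10)), 2)
  expect_equal(unique(round(lo, 10)), 0)
})

test_that("the planted titer effect is detectable with high power", {
  # 100 seeds, n = 300 participants: Wilcoxon hi vs lo significant in >= 95%
  cfg0 <- sim_config(n_studies = 3, participants_per_study = 100,
                     titer_beta = 1.5, titer_noise_sd = 1, seed = 1)
  truth <- list(participants = data.frame(
    participant_id = sprintf("P%03d", 1:300),
    study_id = rep(c("s1", "s2", "s3"), each = 100),
    vaccine = rep("influenza", 300),
    endotype = rep(c("inflam.lo", "inflam.mid", "inflam.hi"), 100),
    endotype_score = rep(c(0, 0.5, 1), 100),
    stringsAsFactors = FALSE))
  hits <- 0L
  for (s in 1:100) {
    cfg <- sim_config(n_studies = 3, participants_per_study = 100,
                      titer_beta = 1.5, titer_noise_sd = 1, seed = s)
    titers <- simulate_titers(truth, cfg)
    resp <- suppressMessages(compute_mfc(titers))
    m <- merge(resp, truth$participants, by = "participant_id")
    p <- wilcoxon_rank_sum(m$log2_mfc[m$endotype == "inflam.hi"],
                           m$log2_mfc[m$endotype == "inflam.lo"])$p_value
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("realized batch effects match their planted variances", {
  cfg <- sim_config(n_studies = 4, participants_per_study = 5, n_genes = 1500,
                    module_sizes = setNames(rep(30L, 7), vaxendo:::SUPERSET_LABELS),
                    batch_sd = 0.5, timepoints = c(0L), seed = 17)
  sim <- simulate_compendium(cfg)
  v <- var(as.vector(sim$truth$effects$study))
  expect_lt(abs(v - 0.25) / 0.25, 0.10)
  fr <- sim$truth$variance_fractions$fractions
  expect_equal(sum(fr), 1, tolerance = 1e-12)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_genes = 100,
                          module_sizes = setNames(rep(40L, 7),
                                                  vaxendo:::SUPERSET_LABELS)),
               "exceed")
  expect_error(sim_config(endotype_proportions = c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(sim_config(timepoints = c(1, 7)), "day 0")
  expect_error(sim_config(noise_sd = -1), ">= 0")
})
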