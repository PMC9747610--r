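#' @title Synthetic multi-study compendium generator
#' @description Generates compendia with the statistical structure the
#'   pipeline assumes: an additive Gaussian model on the log2 scale with a
#'   per-gene baseline, a planted three-level inflammatory endotype per
#'   participant (constant across that participant's samples), additive
#'   study/platform/sample-type batch effects, per-superset post-vaccination
#'   kinetic responses with an endotype-specific attenuation, and multi-strain
#'   antibody titers whose log2 fold change depends on the endotype. Ground
#'   truth (endotypes, realized effects, analytic variance fractions) is
#'   returned for recovery tests.
#' @name synthetic_data
NULL

ENDOTYPE_LEVELS <- c("inflam.lo", "inflam.mid", "inflam.hi")
# supersets raised in the high-inflammatory endotype; the remaining four are
# raised in the low-inflammatory endotype
HI_SUPERSETS <- c("inflammation", "ISGs", "monocytes_DCs")
LO_SUPERSETS <- c("T_cells", "NK_cells", "B_cells", "E2F_MYC")

# bacterial/viral etiology marker symbols planted among background genes so
# the metascore stage is exercisable on synthetic compendia
ETIOLOGY_MARKERS <- c("HK3", "TNIP1", "GPAA1", "CTSB", "IFI27", "JUP", "LAX1")

default_kinetic_effects <- function() {
  data.frame(
    superset = c("inflammation", "inflammation", "monocytes_DCs", "ISGs",
                 "B_cells"),
    day = c(1L, 3L, 1L, 1L, 7L),
    effect = c(1.0, 0.5, 0.75, 1.0, 0.5),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Defaults describe a small multi-study compendium with a clear but noisy
#' endotype structure: three studies of thirty participants, a log2 endotype
#' shift of 1 on the affected modules, residual noise sd 0.25, study batch sd
#' 0.5, and titers whose log2 fold change increases by 1.5 per unit endotype
#' score with noise sd 1.
#'
#' @param n_studies number of studies; each study gets exactly one platform
#'   and one sample type (platforms and sample types alternate across studies).
#' @param participants_per_study participants per study.
#' @param n_genes total genes; must be at least `sum(module_sizes)`.
#' @param module_sizes named integer vector, genes per superset (seven labels).
#' @param endotype_proportions probabilities of `inflam.lo/mid/hi`, summing to 1.
#' @param endotype_effect_delta log2-units shift applied to modules per
#'   endotype: `inflam.hi` raises the inflammation/ISG/monocyte-DC modules by
#'   `+delta`, `inflam.lo` raises the T/NK/B/E2F-MYC modules by `+delta`,
#'   `inflam.mid` applies `+delta/2` to both groups.
#' @param batch_sd,platform_sd,sampletype_sd standard deviations of the
#'   additive per-factor x gene effects.
#' @param noise_sd residual standard deviation.
#' @param timepoints days sampled per participant; must include 0.
#' @param kinetic_effects data.frame (superset, day, effect) of mean log2
#'   inductions relative to baseline.
#' @param kinetic_attenuation multiplicative factor (< 1) applied to the
#'   inflammation-superset induction at days <= 3 in `inflam.hi` participants.
#' @param titer_beta effect of the endotype score (0/0.5/1 for lo/mid/hi) on
#'   the log2 maximum fold change of titers.
#' @param titer_noise_sd sd of the titer fold-change noise (log2 scale).
#' @param titer_day0_log2_mean,titer_day0_log2_sd log-normal baseline titer
#'   parameters (log2 scale).
#' @param n_strains antigen strains per vaccine.
#' @param seed master seed; independent streams for baseline, assignment,
#'   batch, noise and titers are derived from it, so e.g. adding strains does
#'   not perturb the expression draws.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_studies = 3L,
                       participants_per_study = 30L,
                       n_genes = 1000L,
                       module_sizes = stats::setNames(rep(40L, 7),
                                                      SUPERSET_LABELS),
                       endotype_proportions = c(inflam.lo = 1 / 3,
                                                inflam.mid = 1 / 3,
                                                inflam.hi = 1 / 3),
                       endotype_effect_delta = 1,
                       batch_sd = 0.5,
                       platform_sd = 0.25,
                       sampletype_sd = 0.25,
                       noise_sd = 0.25,
                       timepoints = c(0L, 1L, 3L, 7L, 70L),
                       kinetic_effects = default_kinetic_effects(),
                       kinetic_attenuation = 0.5,
                       titer_beta = 1.5,
                       titer_noise_sd = 1,
                       titer_day0_log2_mean = 5,
                       titer_day0_log2_sd = 1,
                       n_strains = 3L,
                       seed = 1L) {
  cfg <- list(n_studies = as.integer(n_studies),
              participants_per_study = as.integer(participants_per_study),
              n_genes = as.integer(n_genes),
              module_sizes = module_sizes,
              endotype_proportions = endotype_proportions,
              endotype_effect_delta = endotype_effect_delta,
              batch_sd = batch_sd, platform_sd = platform_sd,
              sampletype_sd = sampletype_sd, noise_sd = noise_sd,
              timepoints = as.integer(timepoints),
              kinetic_effects = kinetic_effects,
              kinetic_attenuation = kinetic_attenuation,
              titer_beta = titer_beta, titer_noise_sd = titer_noise_sd,
              titer_day0_log2_mean = titer_day0_log2_mean,
              titer_day0_log2_sd = titer_day0_log2_sd,
              n_strains = as.integer(n_strains),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!setequal(names(cfg$module_sizes), SUPERSET_LABELS)) {
    stop("module_sizes must be named by the seven superset labels")
  }
  if (sum(cfg$module_sizes) > cfg$n_genes) {
    stop("module sizes exceed n_genes")
  }
  if (abs(sum(cfg$endotype_proportions) - 1) > 1e-12) {
    stop("endotype_proportions must sum to 1")
  }
  sds <- c(cfg$batch_sd, cfg$platform_sd, cfg$sampletype_sd, cfg$noise_sd,
           cfg$titer_noise_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (!0L %in% cfg$timepoints) stop("timepoints must include day 0")
  if (cfg$n_strains < 1L) stop("n_strains must be >= 1")
  invisible(cfg)
}

# Independent RNG streams derived from the master seed.
stream_seed <- function(seed, stream) {
  offsets <- c(baseline = 11L, assign = 23L, batch = 37L, noise = 53L,
               titer = 71L)
  (as.integer(seed) * 97L + offsets[[stream]]) %% .Machine$integer.max
}

#' Simulate a multi-study compendium with planted endotype structure
#'
#' @param config a [sim_config()].
#' @return List with elements `compendium` (gene sets attached), `gene_sets`
#'   (the planted modules, superset map filled), and `truth` (per-participant
#'   endotype and score, realized study/platform/sample-type effect matrices,
#'   and analytic per-factor variance fractions for day-0 samples).
#' @export
simulate_compendium <- function(config) {
  validate_sim_config(config)
  cfg <- config

  # gene universe: module genes named after their superset, plus background
  gene.names <- character(0)
  sets <- list()
  superset.map <- character(0)
  for (lab in SUPERSET_LABELS) {
    m <- cfg$module_sizes[[lab]]
    nm <- sprintf("%s_G%03d", toupper(gsub("[^A-Za-z0-9]", "", lab)),
                  seq_len(m))
    sets[[lab]] <- nm
    superset.map[lab] <- lab
    gene.names <- c(gene.names, nm)
  }
  n.bg <- cfg$n_genes - length(gene.names)
  if (n.bg > 0) {
    bg <- sprintf("BG_G%04d", seq_len(n.bg))
    if (n.bg >= length(ETIOLOGY_MARKERS)) {
      bg[seq_along(ETIOLOGY_MARKERS)] <- ETIOLOGY_MARKERS
    }
    gene.names <- c(gene.names, bg)
  }
  G <- length(gene.names)
  gsc <- gene_set_collection(sets, superset_map = superset.map)

  # participants, studies, endotypes
  n.part <- cfg$n_studies * cfg$participants_per_study
  study.ids <- sprintf("study%02d", seq_len(cfg$n_studies))
  platforms <- sprintf("platform%d", ((seq_len(cfg$n_studies) - 1L) %% 2L) + 1L)
  sample.types <- c("whole_blood", "pbmc")[((seq_len(cfg$n_studies) - 1L) %% 2L) + 1L]
  vaccine.pool <- c("influenza", "yellow_fever", "hepatitis_B", "meningococcus",
                    "varicella_zoster", "malaria", "tuberculosis")
  vaccines <- vaccine.pool[((seq_len(cfg$n_studies) - 1L) %% length(vaccine.pool)) + 1L]

  part.study <- rep(seq_len(cfg$n_studies), each = cfg$participants_per_study)
  part.ids <- sprintf("%s_P%03d", study.ids[part.study],
                      sequence(rep(cfg$participants_per_study, cfg$n_studies)))
  assign.draw <- with_seed(stream_seed(cfg$seed, "assign"), {
    e <- sample(ENDOTYPE_LEVELS, n.part, replace = TRUE,
                prob = cfg$endotype_proportions)
    list(endotype = e,
         age = round(stats::runif(n.part, 18, 80)),
         sex = sample(c("F", "M"), n.part, replace = TRUE))
  })
  endotype <- assign.draw$endotype
  score <- c(inflam.lo = 0, inflam.mid = 0.5, inflam.hi = 1)[endotype]

  # per-gene effect layers
  baseline <- with_seed(stream_seed(cfg$seed, "baseline"),
                        stats::rnorm(G, mean = 6, sd = 1))
  batch.draw <- with_seed(stream_seed(cfg$seed, "batch"), {
    list(study = matrix(stats::rnorm(G * cfg$n_studies, 0, cfg$batch_sd),
                        G, cfg$n_studies,
                        dimnames = list(gene.names, study.ids)),
         platform = matrix(stats::rnorm(G * 2L, 0, cfg$platform_sd), G, 2L,
                           dimnames = list(gene.names,
                                           c("platform1", "platform2"))),
         sample_type = matrix(stats::rnorm(G * 2L, 0, cfg$sampletype_sd),
                              G, 2L,
                              dimnames = list(gene.names,
                                              c("whole_blood", "pbmc"))))
  })

  # endotype shift per gene x endotype
  delta <- cfg$endotype_effect_delta
  shift <- matrix(0, G, 3, dimnames = list(gene.names, ENDOTYPE_LEVELS))
  hi.genes <- unlist(sets[HI_SUPERSETS], use.names = FALSE)
  lo.genes <- unlist(sets[LO_SUPERSETS], use.names = FALSE)
  shift[hi.genes, "inflam.hi"] <- delta
  shift[lo.genes, "inflam.lo"] <- delta
  shift[c(hi.genes, lo.genes), "inflam.mid"] <- delta / 2

  # samples: every participant at every time point
  tp <- sort(cfg$timepoints)
  sample.grid <- expand.grid(tp = seq_along(tp), part = seq_len(n.part),
                             KEEP.OUT.ATTRS = FALSE)
  day <- tp[sample.grid$tp]
  pidx <- sample.grid$part
  sample.ids <- sprintf("%s_d%d", part.ids[pidx], day)
  S <- length(sample.ids)

  # kinetic shift per gene x sample
  expr <- matrix(baseline, G, S, dimnames = list(gene.names, sample.ids))
  expr <- expr + shift[, endotype[pidx], drop = FALSE]
  ke <- cfg$kinetic_effects
  if (!is.null(ke) && nrow(ke)) {
    for (r in seq_len(nrow(ke))) {
      g <- sets[[ke$superset[r]]]
      cols <- which(day == ke$day[r])
      if (!length(cols)) next
      eff <- rep(ke$effect[r], length(cols))
      if (ke$superset[r] == "inflammation" && ke$day[r] <= 3L) {
        eff[endotype[pidx[cols]] == "inflam.hi"] <-
          ke$effect[r] * cfg$kinetic_attenuation
      }
      expr[g, cols] <- expr[g, cols] + rep(eff, each = length(g))
    }
  }

  st <- part.study[pidx]
  expr <- expr + batch.draw$study[, st, drop = FALSE]
  expr <- expr + batch.draw$platform[, platforms[st], drop = FALSE]
  expr <- expr + batch.draw$sample_type[, sample.types[st], drop = FALSE]
  if (cfg$noise_sd > 0) {
    expr <- expr + with_seed(stream_seed(cfg$seed, "noise"),
                             matrix(stats::rnorm(G * S, 0, cfg$noise_sd), G, S))
  }

  samples <- data.frame(
    sample_id = sample.ids,
    participant_id = part.ids[pidx],
    study_id = study.ids[st],
    platform = platforms[st],
    sample_type = sample.types[st],
    vaccine = vaccines[st],
    day = day,
    age_years = assign.draw$age[pidx],
    sex = assign.draw$sex[pidx],
    stringsAsFactors = FALSE
  )

  comp <- compendium(expr, samples, gene_sets = gsc)
  truth <- list(
    participants = data.frame(participant_id = part.ids,
                              study_id = study.ids[part.study],
                              vaccine = vaccines[part.study],
                              endotype = endotype,
                              endotype_score = unname(score),
                              stringsAsFactors = FALSE),
    effects = batch.draw,
    endotype_shift = shift,
    variance_fractions = planted_variance_fractions(cfg, shift)
  )
  list(compendium = comp, gene_sets = gsc, truth = truth)
}

# Analytic per-factor variance (and normalized fractions) for a day-0 sample,
# averaged over genes.
planted_variance_fractions <- function(cfg, shift) {
  p <- cfg$endotype_proportions
  # per-gene endotype variance across participants
  m1 <- shift %*% as.numeric(p)
  m2 <- (shift^2) %*% as.numeric(p)
  v.endo <- mean(m2 - m1^2)
  v <- c(study = cfg$batch_sd^2,
         platform = cfg$platform_sd^2,
         sample_type = cfg$sampletype_sd^2,
         endotype = v.endo,
         resid = cfg$noise_sd^2)
  list(variances = v, fractions = v / sum(v))
}

#' Simulate multi-strain antibody titers
#'
#' Day-0 titers are log-normal; the day-28 log2 titer adds
#' `max(0, titer_beta * endotype_score + noise)` per strain, so higher
#' inflammatory endotype scores yield larger maximum fold changes when
#' `titer_beta > 0`.
#'
#' @param truth ground-truth list from [simulate_compendium()].
#' @param config the same [sim_config()].
#' @return data.frame with columns participant_id, study_id, vaccine, strain,
#'   day, titer, assay.
#' @export
simulate_titers <- function(truth, config) {
  validate_sim_config(config)
  parts <- truth$participants
  if (!nrow(parts)) stop("no participants in ground truth")
  n <- nrow(parts)
  k <- config$n_strains
  draws <- with_seed(stream_seed(config$seed, "titer"), {
    list(base = stats::rnorm(n * k, config$titer_day0_log2_mean,
                             config$titer_day0_log2_sd),
         noise = stats::rnorm(n * k, 0, config$titer_noise_sd))
  })
  strain <- rep(sprintf("strain_%d", seq_len(k)), each = n)
  pid <- rep(parts$participant_id, times = k)
  idx <- rep(seq_len(n), times = k)
  base.log2 <- draws$base
  rise <- pmax(0, config$titer_beta * parts$endotype_score[idx] + draws$noise)
  out <- rbind(
    data.frame(participant_id = pid, study_id = parts$study_id[idx],
               vaccine = parts$vaccine[idx], strain = strain, day = 0L,
               titer = 2^base.log2, assay = "HAI",
               stringsAsFactors = FALSE),
    data.frame(participant_id = pid, study_id = parts$study_id[idx],
               vaccine = parts$vaccine[idx], strain = strain, day = 28L,
               titer = 2^(base.log2 + rise), assay = "HAI",
               stringsAsFactors = FALSE)
  )
  out[order(out$participant_id, out$strain, out$day), , drop = FALSE]
}
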