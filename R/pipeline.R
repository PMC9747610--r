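#' @title End-to-end pipeline orchestration
#' @description Runs the full analysis from a single validated configuration:
#'   load -> within-study quantile normalization -> batch correction -> PVCA
#'   -> SLEA -> endotype discovery -> antibody response -> classifier ->
#'   etiology metascore -> kinetics, writing one plain-text table per stage
#'   plus a JSON manifest recording input hashes, every parameter and seed,
#'   per-stage counts, and output hashes. Re-running with the same
#'   configuration reproduces hash-identical outputs (single-threaded).
#' @name pipeline_cli
NULL

#' Build and validate a pipeline run configuration
#'
#' Every stochastic stage requires an explicit seed in `seeds`; unknown
#' configuration keys are rejected (a YAML document read with
#' [read_run_config()] goes through the same validation).
#'
#' @param expr,meta paths to the expression and metadata TSV files.
#' @param out_dir output directory.
#' @param seeds named list with integer seeds `slea`, `pvca`, `gap`,
#'   `classifier` (all required).
#' @param gmt optional path to a GMT gene-set file.
#' @param supersets optional path to a (gene_set, superset) mapping TSV.
#' @param titers optional path to a titer TSV.
#' @param slea_permutations,min_set_size SLEA parameters.
#' @param pvca_factors,pvca_bootstrap,pvca_threshold PVCA parameters.
#' @param k_max,gap_refs Gap-statistic parameters.
#' @param inflammatory_sets set names defining the inflammatory score; `NULL`
#'   auto-selects the four hallmark inflammatory sets if present, else the
#'   sets mapped to the `inflammation` superset.
#' @param mfc_day,mfc_window response-window parameters.
#' @param n_features,n_folds,n_trees,n_perm classifier parameters.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(expr, meta, out_dir, seeds,
                       gmt = NULL, supersets = NULL, titers = NULL,
                       slea_permutations = 1000L, min_set_size = 5L,
                       pvca_factors = c("study_id", "platform", "sample_type",
                                        "day"),
                       pvca_bootstrap = 100L, pvca_threshold = 0.6,
                       k_max = 6L, gap_refs = 50L,
                       inflammatory_sets = NULL,
                       mfc_day = 28L, mfc_window = 2L,
                       n_features = 500L, n_folds = 10L, n_trees = 500L,
                       n_perm = 1000L) {
  need.seeds <- c("slea", "pvca", "gap", "classifier")
  if (missing(seeds) || !is.list(seeds) ||
      !all(need.seeds %in% names(seeds))) {
    stop("seeds must be a named list with entries: ",
         paste(need.seeds, collapse = ", "))
  }
  extra <- setdiff(names(seeds), need.seeds)
  if (length(extra)) stop("unknown seed key(s): ", paste(extra, collapse = ", "))
  cfg <- list(expr = expr, meta = meta, out_dir = out_dir,
              gmt = gmt, supersets = supersets, titers = titers,
              seeds = lapply(seeds, as.integer),
              slea_permutations = as.integer(slea_permutations),
              min_set_size = as.integer(min_set_size),
              pvca_factors = pvca_factors,
              pvca_bootstrap = as.integer(pvca_bootstrap),
              pvca_threshold = pvca_threshold,
              k_max = as.integer(k_max), gap_refs = as.integer(gap_refs),
              inflammatory_sets = inflammatory_sets,
              mfc_day = as.integer(mfc_day), mfc_window = as.integer(mfc_window),
              n_features = as.integer(n_features),
              n_folds = as.integer(n_folds), n_trees = as.integer(n_trees),
              n_perm = as.integer(n_perm))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML document
#'
#' Unknown keys are rejected before any computation.
#'
#' @param path path to a YAML file whose keys are the arguments of
#'   [run_config()].
#' @return Validated `run_config`.
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "...")
  unknown <- setdiff(names(doc), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, doc)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Stages run in dependency order; any stage error halts with the stage name.
#' The manifest records input md5 hashes, all parameters and seeds, per-stage
#' counts and output md5 hashes.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the manifest and in-memory stage results.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log <- list()
  stage <- function(name, code) {
    tryCatch(force(code),
             error = function(e) stop("stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }

  inputs <- c(expr = config$expr, meta = config$meta,
              gmt = config$gmt, supersets = config$supersets,
              titers = config$titers)
  input.md5 <- vapply(inputs, function(p) unname(tools::md5sum(p)),
                      character(1))

  gsc <- if (!is.null(config$gmt)) stage("read_gmt", read_gmt(config$gmt))
  if (!is.null(gsc) && !is.null(config$supersets)) {
    gsc <- stage("read_superset_map",
                 gene_set_collection(gsc$sets,
                                     read_superset_map(config$supersets)))
  }
  comp <- stage("load", load_compendium(config$expr, config$meta,
                                        gene_sets = gsc))
  log$load <- list(genes = nrow(comp$expression),
                   samples = ncol(comp$expression),
                   studies = length(unique(comp$samples$study_id)))

  comp <- stage("quantile_normalize", quantile_normalize_within_study(comp))
  bm <- stage("fit_batch_model", fit_batch_model(comp))
  comp <- stage("apply_batch_correction", apply_batch_correction(comp, bm))
  coef.df <- data.frame(gene_symbol = rownames(bm$coefficients),
                        bm$coefficients, check.names = FALSE)
  write_tsv(coef.df, file.path(out, "batch_model.tsv"))
  write_tsv(data.frame(gene_symbol = rownames(comp$expression),
                       comp$expression, check.names = FALSE),
            file.path(out, "corrected_expression.tsv"))
  log$batch <- list(columns = bm$columns, aliased = bm$aliased)

  pv <- stage("pvca", pvca(comp, factors = config$pvca_factors,
                           threshold = config$pvca_threshold,
                           n_bootstrap = config$pvca_bootstrap,
                           seed = config$seeds$pvca))
  pv.df <- data.frame(factor = names(pv$fractions), fraction = pv$fractions,
                      boot_mean = pv$boot_mean, ci_lower = pv$ci_lower,
                      ci_upper = pv$ci_upper)
  write_tsv(pv.df, file.path(out, "pvca.tsv"))
  log$pvca <- list(n_pcs = pv$n_pcs, n_bootstrap = pv$n_bootstrap)

  if (is.null(comp$gene_sets)) stop("stage 'slea' failed: no gene sets supplied")
  sl <- stage("slea", slea_zscores(comp, comp$gene_sets,
                                   n_permutations = config$slea_permutations,
                                   seed = config$seeds$slea,
                                   min_size = config$min_set_size))
  write_tsv(data.frame(gene_set = rownames(sl$z), sl$z, check.names = FALSE),
            file.path(out, "slea.tsv"))
  ss <- stage("superset_scores", superset_scores(sl, comp$gene_sets))
  write_tsv(data.frame(superset = rownames(ss$z), ss$z, check.names = FALSE),
            file.path(out, "slea_supersets.tsv"))
  log$slea <- list(sets = nrow(sl$z), dropped = sl$dropped)

  # endotype discovery on pre-vaccination samples
  pre.ids <- comp$samples$sample_id[is_prevax(comp$samples$day)]
  sl.pre <- subset_slea(sl, pre.ids)
  gap <- stage("gap_statistic", gap_statistic(sl.pre, k_max = config$k_max,
                                              n_ref = config$gap_refs,
                                              seed = config$seeds$gap))
  cl <- stage("hierarchical_clusters", hierarchical_clusters(sl.pre, k = 3L))
  inflam.sets <- config$inflammatory_sets
  if (is.null(inflam.sets)) {
    inflam.sets <- if (all(INFLAMMATORY_HALLMARK_SETS %in% rownames(sl$z))) {
      INFLAMMATORY_HALLMARK_SETS
    } else {
      map <- comp$gene_sets$superset_map
      names(map)[map == "inflammation"]
    }
  }
  endo <- stage("label_endotypes", label_endotypes(cl, sl.pre, inflam.sets))
  write_tsv(endo, file.path(out, "endotypes.tsv"))
  part.endo <- participant_endotypes(endo, comp$samples)
  write_tsv(part.endo, file.path(out, "participant_endotypes.tsv"))
  stab <- tryCatch(temporal_stability(sl, comp$samples),
                   error = function(e) NULL)
  log$endotype <- list(chosen_k = gap$k,
                       gap = gap$gap,
                       cluster_sizes = as.list(table(endo$endotype)),
                       inflammatory_sets = inflam.sets,
                       temporal_stability = if (is.null(stab)) NA
                                            else stab$aggregate)

  resp <- NULL
  if (!is.null(config$titers)) {
    titers <- utils::read.delim(config$titers, stringsAsFactors = FALSE)
    resp <- stage("response", {
      r <- compute_mfc(titers, target_day = config$mfc_day,
                       window = config$mfc_window)
      discretize_responders(scale_mfc(r))
    })
    write_tsv(resp, file.path(out, "responses.tsv"))
    log$response <- list(participants = nrow(resp),
                         classes = as.list(table(resp$responder)))

    feats <- stage("select_features",
                   select_features(comp, resp, n = config$n_features))
    crep <- stage("train_evaluate",
                 train_evaluate(comp, resp, feats,
                                n_folds = config$n_folds,
                                seed = config$seeds$classifier,
                                n_trees = config$n_trees,
                                n_perm = config$n_perm))
    report <- list(metrics = as.list(crep$metrics), auroc_p = crep$auroc_p,
                   per_vaccine_auroc = as.list(crep$per_vaccine_auroc),
                   n_folds = crep$n_folds, n_trees = crep$n_trees,
                   seed = crep$seed, stratification = crep$stratification,
                   importance = as.list(crep$importance))
    jsonlite::write_json(report, file.path(out, "classifier_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log$classifier <- list(samples = nrow(crep$predictions),
                           auroc = unname(crep$metrics["auroc"]))
  }

  ms <- stage("metascore", bacterial_viral_score(comp))
  write_tsv(ms, file.path(out, "metascore.tsv"))
  log$metascore <- as.list(table(ms$call))

  kin <- stage("kinetics", {
    deltas <- compute_deltas(ss, comp$samples, part.endo)
    compare_endotypes(deltas)
  })
  write_tsv(kin$medians, file.path(out, "kinetics.tsv"))
  if (!is.null(kin$comparisons)) {
    write_tsv(kin$comparisons, file.path(out, "kinetics_comparisons.tsv"))
  }
  log$kinetics <- list(rows = nrow(kin$medians),
                       comparisons = if (is.null(kin$comparisons)) 0L
                                     else nrow(kin$comparisons))

  out.files <- list.files(out, full.names = TRUE)
  out.files <- out.files[!grepl("manifest\\.json$", out.files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("vaxendo")),
    inputs = as.list(input.md5),
    parameters = unclass(config),
    stages = log,
    outputs = as.list(stats::setNames(
      vapply(out.files, function(p) unname(tools::md5sum(p)), character(1)),
      basename(out.files)))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, compendium = comp, pvca = pv,
                 slea = sl, supersets = ss, gap = gap, endotypes = endo,
                 participant_endotypes = part.endo, responses = resp,
                 kinetics = kin))
}
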