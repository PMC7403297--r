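# End-to-end pipeline: preprocess -> contrasts -> replication -> burden
# -> composites, with a run manifest for reproducibility -----------------

#' Pipeline configuration
#'
#' Collects every threshold the analysis prints, the seed, and either a
#' simulation configuration or a dataset directory.
#'
#' @param out_dir directory for all output tables and the run manifest.
#' @param sim optional [sim_config()]; when given, the input dataset is
#'   simulated.
#' @param data_dir optional dataset directory (see [read_dataset()]); exactly
#'   one of `sim`/`data_dir` must be supplied.
#' @param alpha_p nominal significance threshold (0.05).
#' @param alpha_fdr within-panel FDR threshold (0.1).
#' @param alpha_replication per-half threshold of the split-half experiment
#'   (0.10).
#' @param candidate_p composite candidate-selection threshold (0.1 or 0.05).
#' @param n_partitions Monte-Carlo partitions (100).
#' @param delta_comparable BIC comparable band (2).
#' @param inner_folds inner CV folds for elastic-net tuning (5).
#' @param seed integer master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, sim = NULL, data_dir = NULL,
                            alpha_p = 0.05, alpha_fdr = 0.1,
                            alpha_replication = 0.10, candidate_p = 0.1,
                            n_partitions = 100, delta_comparable = 2,
                            inner_folds = 5, seed = 1) {
  if (is.null(sim) == is.null(data_dir))
    stop("supply exactly one of 'sim' or 'data_dir'")
  for (th in c(alpha_p, alpha_fdr, alpha_replication, candidate_p))
    if (th <= 0 || th >= 1) stop("thresholds must lie in (0, 1)")
  if (n_partitions < 1 || inner_folds < 2)
    stop("counts must be positive (n_partitions >= 1, inner_folds >= 2)")
  structure(list(out_dir = out_dir, sim = sim, data_dir = data_dir,
                 alpha_p = alpha_p, alpha_fdr = alpha_fdr,
                 alpha_replication = alpha_replication,
                 candidate_p = candidate_p, n_partitions = n_partitions,
                 delta_comparable = delta_comparable,
                 inner_folds = inner_folds, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes preprocessing (LOD imputation, bridging batch correction,
#' bridging-sample removal), the three case/control contrasts, the
#' Monte-Carlo split-half replication, the disease-burden screen on the
#' comorbid contrast's FDR-significant proteins, and the three elastic-net
#' composite scores. Writes every result table plus a run manifest (config,
#' seed, versions, timestamp) into `cfg$out_dir`; a stage failure aborts
#' with the stage name, preserving the outputs already written.
#'
#' @param cfg a [pipeline_config()].
#' @return invisible list with all in-memory stage results.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  data <- stage("input", {
    if (!is.null(cfg$sim)) simulate_dataset(cfg$sim)
    else read_dataset(cfg$data_dir)
  })

  pre <- stage("preprocess", {
    x <- impute_lod(data$expr,
                    batches = data$meta$batch[match(rownames(data$expr$values),
                                                    data$meta$sample_id)])
    x <- bridge_correct(x, data$meta)
    drop_bridging(x, data$meta)
  })

  contrasts <- default_contrasts()
  diffs <- stage("differential", {
    out <- lapply(contrasts, function(ct)
      run_contrast(pre$expr, pre$meta, ct, cfg$alpha_p, cfg$alpha_fdr))
    for (nm in names(out))
      utils::write.csv(out[[nm]]$table,
                       file.path(cfg$out_dir, paste0("diff_", nm, ".csv")),
                       row.names = FALSE)
    out
  })

  overlap <- stage("overlap", {
    ov <- overlap_sets(lapply(diffs, `[[`, "sig_p"))
    betas <- as.data.frame(lapply(diffs, function(d) d$table$beta))
    rownames(betas) <- diffs[[1]]$table$protein
    bc <- beta_correlation(betas)
    sc <- sign_consistency(betas, ov$union)
    jsonlite::write_json(
      list(regions = as.list(ov$regions), union_size = length(ov$union),
           n_sign_consistent = sc$n_consistent,
           beta_correlations = bc),
      file.path(cfg$out_dir, "overlap_summary.json"),
      auto_unbox = TRUE, digits = NA)
    list(overlap = ov, beta_cor = bc, sign_consistency = sc)
  })

  repl <- stage("replication", {
    out <- lapply(seq_along(contrasts), function(k)
      replicate_mc(pre$expr, pre$meta, contrasts[[k]],
                   n_partitions = cfg$n_partitions,
                   alpha = cfg$alpha_replication, seed = cfg$seed + k))
    names(out) <- names(contrasts)
    for (nm in names(out))
      utils::write.csv(out[[nm]],
                       file.path(cfg$out_dir,
                                 paste0("replication_", nm, ".csv")),
                       row.names = FALSE)
    out
  })

  burden <- stage("burden", {
    hits <- diffs$PTSD_MCI_vs_control$sig_fdr
    tab <- if (length(hits)) {
      burden_screen(pre$expr, pre$meta, hits,
                    delta_comparable = cfg$delta_comparable)
    } else {
      data.frame(protein = character(0), middle_group = character(0),
                 bic_h1 = numeric(0), bic_h2 = numeric(0),
                 bic_h3 = numeric(0), best = character(0),
                 comparable = character(0), error = character(0))
    }
    utils::write.csv(tab, file.path(cfg$out_dir, "burden.csv"),
                     row.names = FALSE)
    tab
  })

  composites <- stage("composite", {
    out <- lapply(seq_along(contrasts), function(k) {
      ct <- contrasts[[k]]
      cand <- select_candidates(diffs[[names(contrasts)[k]]], cfg$candidate_p)
      loo_elastic_net(pre$expr, pre$meta, ct, cand,
                      inner_folds = cfg$inner_folds, seed = cfg$seed + 10 + k)
    })
    names(out) <- names(contrasts)
    for (nm in names(out)) {
      cr <- out[[nm]]
      jsonlite::write_json(
        list(contrast = cr$contrast, n_candidates = length(cr$candidates),
             candidates = cr$candidates, auc = cr$auc,
             r_pcl = cr$r_pcl, p_pcl = cr$p_pcl,
             r_moca = cr$r_moca, p_moca = cr$p_moca),
        file.path(cfg$out_dir, paste0("composite_", nm, ".json")),
        auto_unbox = TRUE, digits = NA)
      utils::write.csv(
        data.frame(sample_id = cr$sample_id, y = cr$y,
                   oof_score = unname(cr$oof_scores)),
        file.path(cfg$out_dir, paste0("composite_oof_", nm, ".csv")),
        row.names = FALSE)
    }
    out
  })

  manifest <- list(
    package = "npxburden",
    version = as.character(utils::packageVersion("npxburden")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("sim"))],
    sim = if (!is.null(cfg$sim)) unclass(cfg$sim) else NULL
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)

  invisible(list(data = data, preprocessed = pre, differential = diffs,
                 overlap = overlap, replication = repl, burden = burden,
                 composite = composites))
}
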