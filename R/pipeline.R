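# One-call orchestration of the whole analysis:
# simulate -> preprocess -> pca -> assoc -> table1 -> enrich,
# with per-stage logging and run metadata, reproducible from a single seed.

#' Pipeline configuration
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Integer seed driving the simulation and the randomization
#'   null.
#' @param sim A [sim_config()] for the simulate stage (its own seed is
#'   overridden by `seed`).
#' @param stages Character vector of stages to run, in dependency order;
#'   any subset of `c("simulate", "preprocess", "pca", "assoc", "table1",
#'   "enrich")`. Stages not listed are skipped (downstream stages require
#'   their inputs).
#' @param R Randomization draws for the association stage.
#' @param p_threshold Candidate p-value threshold.
#' @param detection_alpha,call_rate,max_bad_samples,knn_k,logit_eps
#'   Preprocessing parameters (see [preprocess_signals()]).
#' @param n_components PCA components to keep (capped at the data's rank).
#' @param background_fraction Island background for [island_enrichment()].
#' @param gmt Optional path to a GMT file for the enrich stage (skipped with
#'   a log line when `NULL`).
#' @param write_signals Also write the raw signal matrices (can be large).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = sim_config(seed = seed),
                            stages = c("simulate", "preprocess", "pca",
                                       "assoc", "table1", "enrich"),
                            R = 999, p_threshold = 0.005,
                            detection_alpha = 0.05, call_rate = 0.95,
                            max_bad_samples = 10, knn_k = 10,
                            logit_eps = 1e-6, n_components = 20,
                            background_fraction = 0.76, gmt = NULL,
                            write_signals = FALSE) {
  stages <- match.arg(stages, c("simulate", "preprocess", "pca", "assoc",
                                "table1", "enrich"), several.ok = TRUE)
  sim$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 stages = stages, R = R, p_threshold = p_threshold,
                 detection_alpha = detection_alpha, call_rate = call_rate,
                 max_bad_samples = max_bad_samples, knn_k = knn_k,
                 logit_eps = logit_eps, n_components = n_components,
                 background_fraction = background_fraction, gmt = gmt,
                 write_signals = isTRUE(write_signals)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes the configured stages in dependency order, writing every stage's
#' outputs under `config$out_dir` together with `run.log` (one line per
#' stage with input/output row counts) and `metadata.json` (seed and all
#' stage parameters). Reruns with an identical configuration are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the output
#'   paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$gmt) && !file.exists(config$gmt)) {
    rlang::abort(sprintf("input file not found before run: %s", config$gmt),
                 class = "methylwas_preflight_error")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  unlink(log_path)
  log_line <- function(...) {
    line <- sprintf(...)
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
    rlang::inform(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
                   class = "methylwas_stage_error", parent = e)
    })
  }
  res <- list()
  out <- function(f) file.path(config$out_dir, f)

  if ("simulate" %in% config$stages) {
    res$cohort <- stage("simulate", simulate_cohort(config$sim))
    sim <- stage("simulate", simulate_signals(res$cohort, config$sim))
    res$signals <- sim$signals
    res$manifest <- sim$manifest
    res$truth <- sim$truth
    write_sample_sheet(res$cohort, out("sample_sheet.csv"))
    write_manifest(res$manifest, out("manifest.csv"))
    write_ground_truth(res$truth, out("ground_truth.json"))
    if (config$write_signals) write_signals(res$signals, out("signals"))
    log_line("simulate: %d samples on %d chips, %d probes, %d spiked sites",
             nrow(res$cohort), length(unique(res$cohort$chip_id)),
             config$sim$n_probes, length(res$truth$true_sites))
  }

  if ("preprocess" %in% config$stages) {
    res$prep <- stage("preprocess", preprocess_signals(
      res$signals, detection_alpha = config$detection_alpha,
      call_rate = config$call_rate, max_bad_samples = config$max_bad_samples,
      knn_k = config$knn_k, logit_eps = config$logit_eps))
    write_beta_matrix(res$prep$beta, out("beta.tsv"))
    readr::write_tsv(res$prep$sample_qc, out("sample_qc.tsv"), progress = FALSE)
    log_line("preprocess: samples %d -> %d, probes %d -> %d, %d entries imputed",
             res$prep$counts$n_samples_in, res$prep$counts$n_samples_kept,
             res$prep$counts$n_probes_in, res$prep$counts$n_probes_kept,
             res$prep$counts$n_imputed)
  }

  if ("pca" %in% config$stages) {
    k <- min(config$n_components, dim(res$prep$m) - 1L)
    res$pca <- stage("pca", run_pca(res$prep$m, n_components = k))
    scree <- tibble::tibble(component = colnames(res$pca$scores),
                            variance_explained = res$pca$variance_explained)
    readr::write_tsv(scree, out("scree.tsv"), progress = FALSE)
    .write_matrix_tsv(res$pca$scores, out("pc_scores.tsv"), "sample_id")
    res$pc_screen <- stage("pca", screen_pcs(res$pca, res$cohort))
    readr::write_tsv(res$pc_screen, out("pc_screen.tsv"), progress = FALSE)
    log_line("pca: %d components keep %.1f%% of variance",
             res$pca$n_components, 100 * sum(res$pca$variance_explained))
  }

  if ("assoc" %in% config$stages) {
    res$ewas <- stage("assoc", run_association(
      res$prep$m, res$cohort, res$manifest, R = config$R, seed = config$seed,
      p_threshold = config$p_threshold))
    write_association_results(res$ewas$results, out("results.tsv"))
    write_candidate_table(res$ewas$candidates, out("candidates.tsv"))
    readr::write_tsv(res$ewas$qq, out("qq.tsv"), progress = FALSE)
    if (nrow(res$ewas$candidates) > 0) {
      res$island <- island_enrichment(res$ewas$candidates,
                                      background_fraction = config$background_fraction)
      readr::write_tsv(res$island, out("island_enrichment.tsv"), progress = FALSE)
    }
    log_line("assoc: %d probes tested in %d samples, R = %d; %d candidates at p < %g",
             res$ewas$n_probes, res$ewas$n_samples, config$R,
             nrow(res$ewas$candidates), config$p_threshold)
  }

  if ("table1" %in% config$stages) {
    res$table1 <- stage("table1", build_table1(res$cohort))
    readr::write_tsv(res$table1, out("table1.tsv"), progress = FALSE)
    log_line("table1: %d covariates summarized",
             length(unique(res$table1$covariate)))
  }

  if ("enrich" %in% config$stages) {
    if (is.null(config$gmt)) {
      log_line("enrich: skipped (no GMT file configured)")
    } else {
      sets <- stage("enrich", read_gmt(config$gmt))
      genes <- stage("enrich", map_probes_to_genes(res$ewas$candidates,
                                                   res$manifest))
      universe <- unique(toupper(res$manifest$gene_symbol))
      universe <- universe[nzchar(universe)]
      res$overlaps <- stage("enrich", overlap_test(genes, sets, universe))
      readr::write_tsv(res$overlaps, out("enrichment.tsv"), progress = FALSE)
      log_line("enrich: %d sets tested against %d query genes (universe %d)",
               nrow(res$overlaps), nrow(genes), length(universe))
    }
  }

  meta <- config
  class(meta) <- NULL
  meta$sim <- unclass(meta$sim)
  meta$package_version <- as.character(utils::packageVersion("methylwas"))
  jsonlite::write_json(meta, out("metadata.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(res)
}
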