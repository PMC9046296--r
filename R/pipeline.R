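#' Run configuration for the end-to-end pipelines
#'
#' A single configuration object driving the orchestrated runs; the seed
#' is mandatory because every pipeline has stochastic steps (simulation,
#' cell selection), and the full config is embedded verbatim in every
#' report for auditability.
#'
#' @param seed root integer seed; module sub-streams are derived from it.
#' @param out_dir output directory (`NULL` = no files written).
#' @param n_queries_per_stage synthetic queries simulated per stage.
#' @param n_rounds detection rounds per indicator.
#' @param stage_overrides named list of per-stage parameter overrides
#'   (passed to [make_stage_params()]).
#' @param n_per_class,n_flat,n_cells,noise_sd trajectory simulation sizes
#'   for [run_pattern_study()].
#' @param qc a [qc_config()].
#' @param out_of_model_factor see [assign_stage()].
#' @param write_figures write the distance heatmap and PCA scatter as PNG.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed, out_dir = NULL, n_queries_per_stage = 10,
                       n_rounds = DEFAULT_ROUNDS,
                       stage_overrides = list(),
                       n_per_class = 10, n_flat = 50, n_cells = 300,
                       noise_sd = 0.2, qc = qc_config(),
                       out_of_model_factor = 1.5, write_figures = TRUE) {
  if (missing(seed) || is.null(seed)) {
    stop("seed is mandatory: every pipeline run has stochastic steps")
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_queries_per_stage = n_queries_per_stage,
                 n_rounds = n_rounds, stage_overrides = stage_overrides,
                 n_per_class = n_per_class, n_flat = n_flat,
                 n_cells = n_cells, noise_sd = noise_sd, qc = qc,
                 out_of_model_factor = out_of_model_factor,
                 write_figures = write_figures,
                 version = as.character(utils::packageVersion("chondrostage"))),
            class = "run_config")
}

#' End-to-end staging evaluation on synthetic data
#'
#' Simulates a staged reference (one sample per stage P0/P2/P4/P8) and a
#' set of query samples with known generating stages, builds the reference
#' model, stages every query, and reports per-stage assignment accuracy,
#' the early/late separation rates, distances and PCA coordinates. With an
#' output directory set, writes the report JSON, the staging CSV table,
#' and PNG heatmap/PCA figures.
#'
#' @param config a [run_config()].
#' @return List of class `evaluation_report`: `config`, `results` (one
#'   [assign_stage()] result per query), `table` (summary data.frame),
#'   `accuracy` (overall and per-stage), `early_late` rates, and the
#'   reference model.
#' @export
run_evaluation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  params <- lapply(stage_levels(), function(s) {
    make_stage_params(s, overrides = config$stage_overrides[[s]] %||% list())
  })
  names(params) <- stage_levels()

  ref_seed <- derive_seed(config$seed, "reference")
  refs <- lapply(seq_along(stage_levels()), function(i) {
    s <- stage_levels()[i]
    simulate_sample_profile(params[[s]], paste0("ref_", s),
                            n_rounds = config$n_rounds,
                            seed = ref_seed + 10L * i)
  })
  model <- build_reference(refs)

  q_seed <- derive_seed(config$seed, "queries")
  queries <- list(); truth <- character(0)
  for (i in seq_along(stage_levels())) {
    s <- stage_levels()[i]
    for (j in seq_len(config$n_queries_per_stage)) {
      q <- simulate_sample_profile(
        params[[s]], sprintf("query_%s_%02d", s, j),
        n_rounds = config$n_rounds,
        seed = q_seed + 1000L * i + 10L * j)
      q$stage <- "UNKNOWN"
      queries[[length(queries) + 1L]] <- q
      truth <- c(truth, s)
    }
  }

  results <- lapply(queries, assign_stage, model = model,
                    out_of_model_factor = config$out_of_model_factor)
  assigned <- vapply(results, `[[`, "", "stage")
  tab <- data.frame(
    sample_id = vapply(results, `[[`, "", "sample_id"),
    true_stage = truth, assigned_stage = assigned,
    confidence = vapply(results, `[[`, 1, "confidence"),
    ambiguous = vapply(results, `[[`, TRUE, "ambiguous"),
    out_of_model = vapply(results, `[[`, TRUE, "out_of_model"),
    nearest_distance = vapply(results, function(r) min(r$distances), 1))

  per_stage <- vapply(stage_levels(), function(s) {
    mean(assigned[truth == s] == s)
  }, numeric(1))
  early_late <- c(
    p2_assigned_early = mean(is_early_stage(assigned[truth == "P2"])),
    p8_assigned_late = mean(!is_early_stage(assigned[truth == "P8"])))

  report <- structure(
    list(config = config, results = results, table = tab,
         accuracy = list(overall = mean(assigned == truth),
                         per_stage = per_stage),
         early_late = early_late, model = model),
    class = "evaluation_report")

  if (!is.null(config$out_dir)) write_evaluation_report(report)
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  if (!is.null(x$accuracy)) {
    cat(sprintf("  stage assignment accuracy: %.1f%% (n = %d queries)\n",
                100 * x$accuracy$overall, nrow(x$table)))
    cat("  per stage:",
        paste(sprintf("%s %.0f%%", names(x$accuracy$per_stage),
                      100 * x$accuracy$per_stage), collapse = ", "), "\n")
    cat(sprintf("  P2 queries assigned early: %.0f%%; P8 assigned late: %.0f%%\n",
                100 * x$early_late["p2_assigned_early"],
                100 * x$early_late["p8_assigned_late"]))
  }
  if (!is.null(x$pattern)) {
    cat(sprintf("  pattern-gene label recovery: %.1f%%\n",
                100 * x$pattern$recovery))
  }
  invisible(x)
}

write_evaluation_report <- function(report) {
  dir <- report$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$table, file.path(dir, "staging_results.csv"),
                   row.names = FALSE)
  payload <- list(
    config = unclass(report$config)[setdiff(names(report$config), "qc")],
    accuracy = report$accuracy, early_late = as.list(report$early_late),
    n_queries = nrow(report$table))
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (isTRUE(report$config$write_figures)) {
    write_figures(report, dir)
  }
  invisible(dir)
}

write_figures <- function(report, dir) {
  model <- report$model
  d <- sample_distance_matrix(model$matrix)
  grDevices::png(file.path(dir, "distance_heatmap.png"),
                 width = 800, height = 700)
  pheatmap::pheatmap(d, clustering_method = "average",
                     main = "Sample-to-sample distance")
  grDevices::dev.off()

  pca <- report$results[[1]]$pca
  qc <- do.call(rbind, lapply(report$results,
                              function(r) r$pca$query_coords))
  grDevices::png(file.path(dir, "pca.png"), width = 800, height = 700)
  rng1 <- range(pca$reference_coords[, 1], qc[, 1])
  rng2 <- range(pca$reference_coords[, 2], qc[, 2])
  plot(pca$reference_coords, pch = 17, cex = 2, col = seq_len(4),
       xlim = rng1, ylim = rng2,
       xlab = sprintf("PC1 (%.0f%%)", 100 * pca$explained_variance[1]),
       ylab = sprintf("PC2 (%.0f%%)", 100 * pca$explained_variance[2]),
       main = "Reference stages (triangles) and queries (circles)")
  graphics::text(pca$reference_coords, labels = model$stages, pos = 3)
  graphics::points(qc, pch = 1,
                   col = match(report$table$true_stage, stage_levels()))
  grDevices::dev.off()
}

#' End-to-end pseudotime pattern study on synthetic data
#'
#' Simulates a trajectory matrix (five archetype classes plus flat
#' background), applies the QC filters, ranks dynamic genes, classifies
#' every gene's temporal pattern and reports the confusion table and the
#' pattern-gene label recovery rate.
#'
#' @param config a [run_config()].
#' @param apply_qc run the QC filters before classification (default
#'   FALSE: the simulator emits dense QC-clean matrices, so QC is a no-op
#'   unless configured otherwise).
#' @return `evaluation_report` with a `pattern` element: `classes` table,
#'   `confusion`, `recovery` (fraction of pattern genes recovering their
#'   generating label), and the `ranking` of dynamic genes.
#' @export
run_pattern_study <- function(config, apply_qc = FALSE) {
  stopifnot(inherits(config, "run_config"))
  tm <- simulate_trajectory_matrix(
    n_per_class = config$n_per_class, n_flat = config$n_flat,
    n_cells = config$n_cells, noise_sd = config$noise_sd,
    seed = derive_seed(config$seed, "trajectories"))
  if (apply_qc) tm <- qc_pipeline(tm, config$qc)
  ranking <- rank_dynamic_genes(tm, config$qc)
  classes <- classify_all(tm, config$qc)
  is_pattern <- classes$true_class != "FLAT"
  recovery <- mean(classes$class[is_pattern] ==
                     classes$true_class[is_pattern])
  report <- structure(
    list(config = config,
         pattern = list(classes = classes,
                        confusion = attr(classes, "confusion"),
                        recovery = recovery, ranking = ranking)),
    class = "evaluation_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(classes,
                     file.path(config$out_dir, "pattern_classes.csv"),
                     row.names = FALSE)
    utils::write.csv(ranking,
                     file.path(config$out_dir, "dynamic_genes.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(recovery = recovery,
           confusion = as.data.frame(report$pattern$confusion),
           seed = config$seed),
      file.path(config$out_dir, "pattern_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
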