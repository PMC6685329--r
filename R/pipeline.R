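#' Run the full simulate -> analyse -> report pipeline
#'
#' Chains both analysis arms under a single resolved configuration: tissue
#' simulation for the healthy and infarct-border presets, clone calling,
#' clonal statistics, vessel classification, merger inference and group
#' comparisons; then count simulation, QC filtering, clustering, contaminant
#' removal, marker detection, composition testing, EndMT signature scoring
#' and a Plvap expression query. All outputs (tissue CSVs, clone and
#' statistics tables, the counts triplet, cluster assignments, marker table,
#' QC report, signature scores) plus an aggregating JSON report and the
#' fully resolved configuration are written to the output directory. Every
#' stage draws from an RNG stream derived from the mandatory seed, so a
#' saved configuration reproduces its outputs.
#'
#' @param config A named list or path to a YAML file. Recognized fields:
#'   `seed` (mandatory), `out_dir` (mandatory), `sections` (default 30),
#'   `tissue` (overrides for both presets), `counts` (overrides passed to
#'   [sim_counts_params()]), `qc` (overrides for [qc_params()]),
#'   `n_clusters_hint` (default 11: ten endothelial states plus the
#'   contaminant), `tsne` (default TRUE), `signature_panel` (path to a YAML
#'   panel; defaults to the shipped EndMT panel), `query_gene`
#'   (default "Plvap"), `merger_resamples` (default 2000).
#' @return The report, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_clonevasc("`config` must be a list or a YAML file path")
  if (is.null(config$seed)) stop_clonevasc("`seed` is mandatory in the pipeline config")
  if (is.null(config$out_dir)) stop_clonevasc("`out_dir` is mandatory in the pipeline config")
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sections <- config$sections %||% 30L
  report <- list(package_version = as.character(utils::packageVersion("clonevasc")),
                 seed = seed, sections = sections)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_clonevasc(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }

  # ---- lineage-tracing arm --------------------------------------------------
  stats_by_preset <- list()
  for (preset in c("healthy", "mi")) {
    tissue <- stage(paste0("simulate_tissue/", preset), {
      params <- do.call(tissue_preset, c(list(name = preset), config$tissue))
      simulate_tissue(params, sections = sections,
                      seed = seed + match(preset, c("healthy", "mi")))
    })
    clones <- stage(paste0("call_clones/", preset), call_clones(tissue))
    stats <- stage(paste0("clonal_stats/", preset), clonal_stats(clones, tissue))
    mt <- stage(paste0("merger_test/", preset), {
      merger_test(clones, n_resamples = config$merger_resamples %||% 2000L,
                  seed = seed + 100L)
    })
    write_tissue_csv(tissue, file.path(out_dir, paste0("tissue_", preset, ".csv")))
    write.csv(clones$clones[, setdiff(names(clones$clones), "vessel_ids")],
              file.path(out_dir, paste0("clones_", preset, ".csv")), row.names = FALSE)
    write.csv(stats$per_section,
              file.path(out_dir, paste0("clonal_stats_", preset, ".csv")),
              row.names = FALSE)
    stats_by_preset[[preset]] <- stats
    report[[paste0("clonal_", preset)]] <- c(
      stats$summary[c("mean_clone_size", "sd_clone_size",
                      "founder_events_per_section", "singleton_fraction",
                      "monoclonal_vessel_fraction", "edu_confetti_fraction",
                      "recombination_efficiency_est")],
      list(colour_fractions = as.list(stats$colour_fractions),
           merger_p = mt$p_value, merger_p_kruskal = mt$p_kruskal))
  }
  cmp <- stage("compare_groups", {
    compare_groups(stats_by_preset$healthy, stats_by_preset$mi, "mean_clone_size")
  })
  report$group_comparison <- cmp[c("metric", "method", "effect", "p_value")]

  # ---- single-cell arm ------------------------------------------------------
  counts <- stage("simulate_counts", {
    params <- do.call(sim_counts_params, config$counts %||% list())
    simulate_counts(params, seed = seed + 10L)
  })
  write_counts_mtx(counts, file.path(out_dir, "counts"))
  qc <- stage("qc_filter", {
    qcp <- do.call(qc_params, config$qc %||% list())
    qc_filter(counts, qcp)
  })
  jsonlite::write_json(
    list(n_input = nrow(qc$qc_report), n_removed = sum(qc$qc_report$removed),
         reasons = as.list(table(qc$qc_report$reason[qc$qc_report$removed]))),
    file.path(out_dir, "qc_report.json"), auto_unbox = TRUE)

  res <- stage("embed_and_cluster", {
    embed_and_cluster(qc, n_clusters_hint = config$n_clusters_hint %||% 11L,
                      tsne = config$tsne %||% TRUE, seed = seed + 20L)
  })
  res <- stage("remove_contaminant_cluster", remove_contaminant_cluster(res, qc))
  write.table(data.frame(cell_id = res$cell_ids, cluster = res$cluster),
              file.path(out_dir, "clusters.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  markers <- stage("cluster_markers", cluster_markers(res, qc))
  write.csv(markers, file.path(out_dir, "markers.csv"), row.names = FALSE)
  comp <- stage("composition_test", composition_test(res))
  write.csv(comp, file.path(out_dir, "composition.csv"), row.names = FALSE)

  panel <- if (!is.null(config$signature_panel)) {
    read_signature_panel(config$signature_panel)
  } else {
    endmt_panel()
  }
  qc_retained <- qc
  qc_retained$counts <- qc$counts[, match(res$cell_ids, colnames(qc$counts)), drop = FALSE]
  qc_retained$cells <- qc$cells[match(res$cell_ids, qc$cells$cell_id), , drop = FALSE]
  sig <- stage("score_signature",
               score_signature(qc_retained, panel, seed = seed + 30L))
  write.csv(sig$scores, file.path(out_dir, "signature_scores.csv"), row.names = FALSE)
  gq <- stage("gene_query", gene_query(res, qc, config$query_gene %||% "Plvap"))

  report$scrna <- list(
    n_cells_input = ncol(counts$counts),
    n_cells_retained = length(res$cell_ids),
    n_clusters = res$n_clusters,
    removed_clusters = res$removed_clusters,
    double_positive_fraction = as.list(res$double_positive_fraction),
    exclusive_clusters = comp$cluster[comp$exclusive & !comp$underpowered],
    signature_effect = sig$group_test$effect,
    signature_p = sig$group_test$p_value,
    query_gene = gq$gene,
    query_top_clusters = utils::head(gq$by_cluster$cluster, 3)
  )

  resolved <- config
  resolved$sections <- sections
  yaml::write_yaml(resolved, file.path(out_dir, "config_resolved.yaml"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
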