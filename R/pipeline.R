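#' Default pipeline configuration
#'
#' All tunable parameters of every stage, as a plain named list that can be
#' serialized to a YAML config file and echoed into every output directory.
#' Input paths (`expression`, `metadata`, and optionally `hvg`, `gene_sets`)
#' point at the TSV/GMT artifacts; leaving them `NULL` and setting
#' `synthetic: yes` makes the run generate the default synthetic study
#' instead.
#'
#' @param ... overrides of the default values.
#' @return named list of parameters.
#' @export
default_config <- function(...) {
  cfg <- list(
    expression = NULL, metadata = NULL, hvg = NULL, gene_sets = NULL,
    synthetic = FALSE,
    fdr = 0.10, k = 4L, gaps = 1L, circular = FALSE, positive_only = FALSE,
    n_min = 8L, exact_n_max = 9L,
    alpha = 0.05,
    seed = 0L, restarts = 1L, resolution = 1.0,
    day_start = 0, day_end = 12,
    min_module_size = 5L,
    version = as.character(utils::packageVersion("varnet"))
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read / write a pipeline configuration file
#'
#' @param path YAML `key: value` file.
#' @return named list (read) or invisibly `path` (write).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  base[names(cfg)] <- cfg
  base
}

#' @rdname read_config
#' @param config named list of parameters.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full inference pipeline
#'
#' Loads (or generates) the expression tensor, builds the variability and
#' averaged time-course networks, detects modules, and writes every artifact
#' plus a structured log of counts at each filtering stage into `out_dir`:
#' `config.yaml`, `variability_net.tsv`/`.graphml`,
#' `averaged_net.tsv`/`.graphml`, `partition.tsv`, `module_summary.tsv`,
#' `edge_counts_by_timepoint.tsv`, `overlap.json`, `log.json`.
#'
#' @param config list from [default_config()] / [read_config()], or a path
#'   to a YAML config file.
#' @param out_dir output directory (created).
#' @return Invisibly, a list with the in-memory results (`tensor`,
#'   `variability_net`, `averaged_net`, `partition`, `summary`, `overlap`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  cfg <- default_config()
  cfg[names(config)] <- config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  write_config(cfg, file.path(out_dir, "config.yaml"))
  hvg <- character(0)
  sets <- NULL
  if (isTRUE(cfg$synthetic)) {
    sim <- stage("synthetic", generate_expression(synthetic_spec(),
                                                  seed = cfg$seed))
    tensor <- sim$tensor
    hvg <- names(sim$truth$hvg)[sim$truth$hvg]
    stage("synthetic", write_synthetic_study(sim, file.path(out_dir, "input")))
  } else {
    if (is.null(cfg$expression) || is.null(cfg$metadata))
      stop("pipeline stage 'input' failed: config must give expression and metadata paths (or synthetic: yes)")
    tensor <- stage("input", read_expression(cfg$expression, cfg$metadata))
    if (!is.null(cfg$hvg)) hvg <- stage("input", read_gene_list(cfg$hvg))
  }
  if (!is.null(cfg$gene_sets))
    sets <- stage("input", read_gmt(cfg$gene_sets))
  vnet <- stage("variability_network", build_variability_network(
    tensor, fdr = cfg$fdr, k = cfg$k, gaps = cfg$gaps,
    circular = cfg$circular, positive_only = cfg$positive_only,
    exact_n_max = cfg$exact_n_max, n_min = cfg$n_min))
  anet <- stage("averaged_network", build_averaged_network(
    tensor, alpha = cfg$alpha, exact_n_max = cfg$exact_n_max))
  part <- stage("communities", louvain_partition(
    vnet, seed = cfg$seed, resolution = cfg$resolution,
    restarts = cfg$restarts))
  summ <- stage("module_analytics", module_summary(
    vnet, part, hvg = hvg, averaged_net = anet, gene_sets = sets,
    min_size = cfg$min_module_size,
    day_window = c(cfg$day_start, cfg$day_end)))
  ov <- stage("overlap", network_overlap(vnet, anet))

  write_network(vnet, file.path(out_dir, "variability_net.tsv"),
                file.path(out_dir, "variability_net.graphml"))
  write_network(anet, file.path(out_dir, "averaged_net.tsv"),
                file.path(out_dir, "averaged_net.graphml"))
  write_partition(part, file.path(out_dir, "partition.tsv"))
  counts <- edge_counts_by_timepoint(vnet)
  utils::write.table(
    data.frame(timepoint_zt = as.integer(names(counts)), n_edges = counts,
               row.names = NULL),
    file.path(out_dir, "edge_counts_by_timepoint.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(summ) > 0L || TRUE)
    utils::write.table(summ, file.path(out_dir, "module_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ov, file.path(out_dir, "overlap.json"),
                       auto_unbox = TRUE)
  log <- list(
    n_genes_input = length(tensor$gene_ids),
    n_timepoints = length(tensor$timepoints_zt),
    n_individuals = tensor$n_individuals,
    n_tested_by_timepoint = as.list(vnet$provenance$n_tested_by_timepoint),
    n_selected_by_timepoint = as.list(vnet$provenance$n_selected_by_timepoint),
    n_edges_variability = n_edges(vnet),
    n_genes_variability = n_nodes(vnet),
    n_edges_averaged = n_edges(anet),
    n_genes_averaged = n_nodes(anet),
    n_modules = part$n_modules,
    n_modules_min_size = nrow(summ),
    modularity = part$modularity,
    shared_genes = ov$shared_genes,
    shared_edges = ov$shared_edges
  )
  jsonlite::write_json(log, file.path(out_dir, "log.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(tensor = tensor, variability_net = vnet,
                 averaged_net = anet, partition = part, summary = summ,
                 overlap = ov, log = log, config = cfg))
}

#' Human-readable summary of a completed pipeline run
#'
#' Recomputes every headline count from the serialized artifacts in
#' `run_dir` (edge files, partition, module summary) and cross-checks them
#' against the run log; an inconsistency — e.g. an edited edge file — raises
#' an error naming the artifact.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return character vector of report lines (also printed).
#' @export
report <- function(run_dir) {
  need <- c("variability_net.tsv", "averaged_net.tsv", "partition.tsv",
            "module_summary.tsv", "log.json", "overlap.json")
  for (f in need)
    if (!file.exists(file.path(run_dir, f)))
      stop("missing artifact: ", f)
  log <- jsonlite::read_json(file.path(run_dir, "log.json"))
  vedges <- utils::read.delim(file.path(run_dir, "variability_net.tsv"))
  aedges <- utils::read.delim(file.path(run_dir, "averaged_net.tsv"))
  part <- utils::read.delim(file.path(run_dir, "partition.tsv"))
  summ <- utils::read.delim(file.path(run_dir, "module_summary.tsv"))
  check <- function(what, got, logged) {
    if (got != logged)
      stop(sprintf("consistency check failed for %s: artifact says %d, log says %d",
                   what, got, logged))
  }
  check("variability edges", nrow(vedges), log$n_edges_variability)
  check("variability genes",
        length(unique(c(vedges$gene_a, vedges$gene_b))),
        log$n_genes_variability)
  check("averaged edges", nrow(aedges), log$n_edges_averaged)
  check("modules", length(unique(part$module_id)),
        ifelse(nrow(part) == 0, 0L, log$n_modules))
  lines <- c(
    "== variability-network pipeline report ==",
    sprintf("variability network : %d edges, %d genes",
            nrow(vedges), log$n_genes_variability),
    sprintf("averaged network    : %d edges, %d genes",
            nrow(aedges), log$n_genes_averaged),
    sprintf("shared genes/edges  : %d / %d",
            log$shared_genes, log$shared_edges),
    sprintf("modules             : %d total, %d with >= min size (modularity %s)",
            log$n_modules, nrow(summ),
            if (is.null(log$modularity) || is.na(log$modularity)) "NA"
            else sprintf("%.4f", log$modularity))
  )
  if (nrow(summ) > 0L) {
    lines <- c(lines, "module summary (size / %HVG / %night edges):")
    lines <- c(lines, sprintf("  module %d: %d genes, %.1f%% HVG, %s%% night",
                              summ$module_id, summ$size, summ$pct_hvg,
                              ifelse(is.na(summ$pct_night_edges), "NA",
                                     sprintf("%.1f", summ$pct_night_edges))))
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
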