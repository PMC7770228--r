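#' Per-module edge-timepoint distributions
#'
#' For every module, counts at each timepoint the intra-module edges (both
#' endpoints in the module) whose support mask is true there. An edge
#' supported at four timepoints contributes four detections in total, so the
#' vector describes when the module's co-expression is detectable across the
#' day/night cycle.
#'
#' @param net a [coexpression_network()] with per-timepoint support.
#' @param partition a [module_partition()] covering the network's nodes.
#' @return integer matrix, one row per module id, one column per ZT hour.
#' @export
edge_time_distribution <- function(net, partition) {
  stopifnot(inherits(net, "coexpression_network"),
            inherits(partition, "module_partition"))
  mods <- sort(unique(partition$assignment))
  out <- matrix(0L, length(mods), length(net$timepoints_zt),
                dimnames = list(as.character(mods),
                                as.character(net$timepoints_zt)))
  if (n_edges(net) == 0L) return(out)
  ma <- partition$assignment[net$edges$gene_a]
  mb <- partition$assignment[net$edges$gene_b]
  intra <- !is.na(ma) & !is.na(mb) & ma == mb
  for (e in which(intra)) {
    r <- as.character(ma[e])
    out[r, ] <- out[r, ] + as.integer(net$support[e, ])
  }
  out
}

#' Percentage of edge detections falling during the night
#'
#' @param edge_time_counts integer vector of per-timepoint edge-detection
#'   counts (one row of [edge_time_distribution()]), named by ZT hour.
#' @param day_window half-open ZT interval `[start, end)` counted as day
#'   (default `c(0, 12)`: lights on ZT0-ZT12).
#' @return percentage in `[0, 100]`, or `NA` (with a message) when the module
#'   has no detections at all.
#' @export
night_edge_percentage <- function(edge_time_counts, day_window = c(0, 12)) {
  zt <- as.numeric(names(edge_time_counts))
  if (any(is.na(zt)))
    stop("edge_time_counts must be named by ZT hour")
  total <- sum(edge_time_counts)
  if (total == 0) {
    message("no edge detections: night percentage undefined")
    return(NA_real_)
  }
  is_day <- zt >= day_window[1L] & zt < day_window[2L]
  100 * sum(edge_time_counts[!is_day]) / total
}

#' Fisher exact gene-set enrichment of a module
#'
#' Tests the 2x2 table (in module x in set) over a declared background
#' universe with Fisher's exact test. Both one-sided p-values and the
#' two-sided p are reported; the odds ratio is the sample cross-product
#' ratio with a Haldane-Anscombe 0.5 correction when any cell is zero (the
#' raw table is also returned).
#'
#' @param module_genes character vector of module member genes (must lie in
#'   the background).
#' @param gene_set character vector; intersected with the background.
#' @param background character vector, the enrichment universe (typically all
#'   network genes).
#' @return list with `overlap`, `odds_ratio`, `p_two_sided`, `p_enrich`,
#'   `p_deplete` and `table` (the 2x2 contingency matrix).
#' @export
set_enrichment <- function(module_genes, gene_set, background) {
  background <- unique(as.character(background))
  if (length(background) == 0L) stop("empty background universe")
  module_genes <- unique(as.character(module_genes))
  if (!all(module_genes %in% background))
    stop("module genes must be a subset of the background")
  gene_set <- intersect(unique(as.character(gene_set)), background)
  in_mod <- background %in% module_genes
  in_set <- background %in% gene_set
  tab <- matrix(c(sum(in_mod & in_set), sum(in_mod & !in_set),
                  sum(!in_mod & in_set), sum(!in_mod & !in_set)),
                nrow = 2,
                dimnames = list(c("in_set", "not_in_set"),
                                c("in_module", "not_in_module")))
  p_two <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  p_enr <- stats::fisher.test(tab, alternative = "greater")$p.value
  p_dep <- stats::fisher.test(tab, alternative = "less")$p.value
  or_tab <- tab
  if (any(tab == 0)) or_tab <- tab + 0.5
  orr <- (or_tab[1, 1] * or_tab[2, 2]) / (or_tab[1, 2] * or_tab[2, 1])
  list(overlap = tab[1, 1], odds_ratio = unname(orr),
       p_two_sided = p_two, p_enrich = p_enr, p_deplete = p_dep,
       table = tab)
}

#' Per-module overlap with the averaged time-course network
#'
#' For every module of the variability-network partition: how many member
#' genes also appear as nodes of the averaged network, and the percentage of
#' the module size.
#'
#' @param partition a [module_partition()].
#' @param averaged_net the averaged-route [coexpression_network()].
#' @return data.frame with columns `module_id`, `size`, `n_in_averaged`,
#'   `pct_in_averaged`.
#' @export
averaged_overlap_per_module <- function(partition, averaged_net) {
  stopifnot(inherits(partition, "module_partition"),
            inherits(averaged_net, "coexpression_network"))
  mods <- sort(unique(partition$assignment))
  rows <- lapply(mods, function(m) {
    g <- module_genes(partition, m)
    n_in <- sum(g %in% averaged_net$nodes)
    data.frame(module_id = m, size = length(g), n_in_averaged = n_in,
               pct_in_averaged = 100 * n_in / length(g))
  })
  do.call(rbind, rows)
}

#' Build the module meta-graph
#'
#' Nodes are modules of at least `min_size` genes; an edge between two
#' modules is weighted by the number of network edges with one endpoint in
#' each. Node attributes carry module size, night-edge percentage and HVG
#' percentage when the inputs to compute them are given.
#'
#' @param net a [coexpression_network()].
#' @param partition a [module_partition()].
#' @param min_size smallest module kept (default 5).
#' @param hvg optional character vector of highly-variable genes (enables
#'   the `pct_hvg` node attribute).
#' @param day_window ZT day interval for the night-edge attribute.
#' @return object of class `module_graph`: list with `nodes` (data.frame:
#'   `module_id`, `size`, `pct_night_edges`, `pct_hvg`) and `edges`
#'   (data.frame: `module_a`, `module_b`, `weight`).
#' @export
build_module_graph <- function(net, partition, min_size = 5L, hvg = NULL,
                               day_window = c(0, 12)) {
  stopifnot(inherits(net, "coexpression_network"),
            inherits(partition, "module_partition"))
  sizes <- module_sizes(partition)
  keep_ids <- as.integer(names(sizes)[sizes >= min_size])
  etd <- edge_time_distribution(net, partition)
  nodes <- do.call(rbind, lapply(keep_ids, function(m) {
    g <- module_genes(partition, m)
    counts <- etd[as.character(m), ]
    pct_night <- if (sum(counts) == 0) NA_real_
                 else suppressMessages(night_edge_percentage(counts, day_window))
    data.frame(module_id = m, size = length(g),
               pct_night_edges = pct_night,
               pct_hvg = if (is.null(hvg)) NA_real_
                         else 100 * mean(g %in% hvg))
  }))
  if (is.null(nodes))
    nodes <- data.frame(module_id = integer(0), size = integer(0),
                        pct_night_edges = numeric(0), pct_hvg = numeric(0))
  ma <- partition$assignment[net$edges$gene_a]
  mb <- partition$assignment[net$edges$gene_b]
  inter <- !is.na(ma) & !is.na(mb) & ma != mb &
    ma %in% keep_ids & mb %in% keep_ids
  if (any(inter)) {
    lo <- pmin(ma[inter], mb[inter])
    hi <- pmax(ma[inter], mb[inter])
    key <- paste(lo, hi)
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
    edges <- data.frame(module_a = as.integer(parts[, 1L]),
                        module_b = as.integer(parts[, 2L]),
                        weight = as.integer(tab))
    edges <- edges[order(edges$module_a, edges$module_b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(module_a = integer(0), module_b = integer(0),
                        weight = integer(0))
  }
  structure(list(nodes = nodes, edges = edges), class = "module_graph")
}

#' @export
print.module_graph <- function(x, ...) {
  cat(sprintf("module_graph: %d modules, %d inter-module connections\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Attribute assortativity of the module graph
#'
#' Measures whether connected modules have similar values of an attribute
#' (e.g. the percentage of night-time edge detections, or the HVG
#' percentage): the Pearson correlation between endpoint attribute values
#' over the orientation-symmetrized edge list (each module-graph edge
#' contributes both (a, b) and (b, a)), with a two-sided p-value from the
#' t-distribution on the symmetrized list. Positive values mean similar
#' modules connect to one another.
#'
#' @param mg a [build_module_graph()] result.
#' @param attribute node-attribute column name in `mg$nodes` (e.g.
#'   `"pct_night_edges"`, `"pct_hvg"`).
#' @return list with `r` (Pearson correlation), `p` (two-sided), `n_edges`
#'   (module-graph edges used; edges with a missing endpoint attribute are
#'   dropped). Constant attributes yield `r = NA` with a message.
#' @export
assortativity_pearson <- function(mg, attribute) {
  stopifnot(inherits(mg, "module_graph"))
  if (!attribute %in% names(mg$nodes))
    stop("unknown module attribute: ", attribute)
  att <- stats::setNames(mg$nodes[[attribute]],
                         as.character(mg$nodes$module_id))
  va <- att[as.character(mg$edges$module_a)]
  vb <- att[as.character(mg$edges$module_b)]
  ok <- !is.na(va) & !is.na(vb)
  va <- va[ok]; vb <- vb[ok]
  if (length(va) < 3L)
    stop("assortativity needs at least 3 module-graph edges with attributes")
  x <- c(va, vb)  # symmetrized endpoint lists
  y <- c(vb, va)
  if (stats::sd(x) == 0) {
    message("constant attribute: assortativity undefined")
    return(list(r = NA_real_, p = NA_real_, n_edges = length(va)))
  }
  r <- stats::cor(x, y)
  n <- length(x)
  tt <- if (abs(r) >= 1) Inf else abs(r) * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-tt, df = n - 2), n_edges = length(va))
}

#' Z-scored mean time profiles grouped by module
#'
#' Each gene's mean-over-individuals profile is standardized to mean 0 and
#' sample standard deviation 1 over the timepoints (the usual display for
#' module expression patterns). Constant profiles cannot be standardized and
#' are omitted with a message.
#'
#' @param tensor an [expression_tensor()].
#' @param partition optional [module_partition()]; when given, only genes in
#'   the partition are returned and a `module_id` column is attached.
#' @return data.frame with `gene_id`, optional `module_id`, and one `zt_<h>`
#'   column per timepoint.
#' @export
zscore_profiles <- function(tensor, partition = NULL) {
  prof <- mean_profiles(tensor)
  genes <- tensor$gene_ids
  if (!is.null(partition)) {
    genes <- intersect(genes, names(partition$assignment))
    prof <- prof[genes, , drop = FALSE]
  }
  sds <- apply(prof, 1L, stats::sd)
  const <- is.na(sds) | sds == 0
  if (any(const))
    message(sum(const), " constant profile(s) omitted from z-scoring")
  prof <- prof[!const, , drop = FALSE]
  z <- t(scale(t(prof)))  # sample-sd convention
  out <- data.frame(gene_id = rownames(z), stringsAsFactors = FALSE)
  if (!is.null(partition))
    out$module_id <- unname(partition$assignment[out$gene_id])
  for (j in seq_along(tensor$timepoints_zt))
    out[[sprintf("zt_%d", tensor$timepoints_zt[j])]] <- unname(z[, j])
  out
}

#' Per-module summary table
#'
#' One row per module of at least `min_size` genes: size, HVG content with
#' Fisher enrichment p against the network background, night-edge
#' percentage, overlap with the averaged network, and (optionally) the best
#' enrichment per supplied gene set.
#'
#' @param net variability-route [coexpression_network()].
#' @param partition a [module_partition()].
#' @param hvg character vector of highly-variable gene IDs.
#' @param averaged_net optional averaged-route network.
#' @param gene_sets optional [gene_set_collection()]; enrichment is computed
#'   per set against the network background.
#' @param min_size smallest module summarized (default 5).
#' @param day_window ZT day interval (default `c(0, 12)`).
#' @return data.frame, one row per module.
#' @export
module_summary <- function(net, partition, hvg = character(0),
                           averaged_net = NULL, gene_sets = NULL,
                           min_size = 5L, day_window = c(0, 12)) {
  sizes <- module_sizes(partition)
  keep_ids <- as.integer(names(sizes)[sizes >= min_size])
  if (length(keep_ids) == 0L)
    return(data.frame(module_id = integer(0), size = integer(0),
                      n_hvg = integer(0), pct_hvg = numeric(0),
                      hvg_fisher_p = numeric(0),
                      pct_night_edges = numeric(0)))
  bg <- names(partition$assignment)
  etd <- edge_time_distribution(net, partition)
  avg_overlap <- if (!is.null(averaged_net))
    averaged_overlap_per_module(partition, averaged_net) else NULL
  rows <- lapply(keep_ids, function(m) {
    g <- module_genes(partition, m)
    counts <- etd[as.character(m), ]
    hv <- intersect(g, hvg)
    enr <- set_enrichment(g, intersect(hvg, bg), bg)
    row <- data.frame(
      module_id = m, size = length(g),
      n_hvg = length(hv), pct_hvg = 100 * length(hv) / length(g),
      hvg_fisher_p = enr$p_two_sided,
      pct_night_edges = if (sum(counts) == 0) NA_real_
        else suppressMessages(night_edge_percentage(counts, day_window))
    )
    if (!is.null(avg_overlap)) {
      ar <- avg_overlap[avg_overlap$module_id == m, ]
      row$n_in_averaged <- ar$n_in_averaged
      row$pct_in_averaged <- ar$pct_in_averaged
    }
    if (!is.null(gene_sets)) {
      for (sn in names(gene_sets$sets)) {
        e <- set_enrichment(g, gene_sets$sets[[sn]], bg)
        row[[paste0("overlap_", sn)]] <- e$overlap
        row[[paste0("p_", sn)]] <- e$p_two_sided
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
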