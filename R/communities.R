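#' Module partition of a network
#'
#' @param assignment named integer vector gene -> module id; module ids are
#'   renumbered to be contiguous from 0 (ordered by first appearance over
#'   sorted gene names, so the labelling is deterministic).
#' @param modularity optional modularity of the partition on its network.
#' @param seed seed used by the detection run, if any.
#' @return object of class `module_partition`.
#' @export
module_partition <- function(assignment, modularity = NA_real_,
                             seed = NA_integer_) {
  if (length(assignment) > 0L) {
    if (is.null(names(assignment))) stop("assignment must be named by gene")
    assignment <- assignment[order(names(assignment))]
    ids <- unique(assignment)
    assignment <- stats::setNames(match(assignment, ids) - 1L,
                                  names(assignment))
  }
  structure(
    list(assignment = assignment, modularity = modularity,
         seed = seed, n_modules = length(unique(assignment))),
    class = "module_partition"
  )
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d genes in %d modules (modularity %.4f)\n",
              length(x$assignment), x$n_modules, x$modularity))
  invisible(x)
}

#' Genes of one module
#' @param partition a [module_partition()].
#' @param module_id module id.
#' @return character vector of gene IDs.
#' @export
module_genes <- function(partition, module_id) {
  names(partition$assignment)[partition$assignment == module_id]
}

#' Module sizes
#' @param partition a [module_partition()].
#' @return named integer vector, module id -> size, ordered by id.
#' @export
module_sizes <- function(partition) {
  if (length(partition$assignment) == 0L)
    return(stats::setNames(integer(0), character(0)))
  tab <- table(partition$assignment)
  stats::setNames(as.integer(tab), names(tab))
}

#' Louvain community detection on a co-expression network
#'
#' Runs modularity-maximizing Louvain clustering on the unweighted network
#' (the network is already thresholded, so every surviving edge counts
#' equally; `weighted = TRUE` switches to |mean rho| edge weights). Louvain
#' is a stochastic local search: the result is deterministic given `seed`
#' but the module composition can vary between seeds, so `restarts` runs
#' are performed and the maximum-modularity one kept.
#'
#' @param net a [coexpression_network()] or an `igraph` graph.
#' @param seed base random seed (default 0); restart `r` uses `seed + r - 1`.
#' @param resolution Louvain resolution parameter (default 1.0).
#' @param restarts number of independent runs to keep the best of (default 1).
#' @param weighted use |mean rho| as edge weights (default FALSE).
#' @return a [module_partition()]; empty networks give an empty partition
#'   with 0 modules.
#' @export
louvain_partition <- function(net, seed = 0L, resolution = 1.0,
                              restarts = 1L, weighted = FALSE) {
  g <- if (inherits(net, "coexpression_network")) as_igraph(net)
       else net
  if (igraph::vcount(g) == 0L)
    return(module_partition(stats::setNames(integer(0), character(0)),
                            modularity = NA_real_, seed = seed))
  w <- if (weighted) abs(igraph::E(g)$mean_rho) else NULL
  best <- NULL
  for (r in seq_len(restarts)) {
    run_seed <- as.integer(seed) + r - 1L
    set.seed(run_seed)
    cl <- igraph::cluster_louvain(g, weights = w, resolution = resolution)
    q <- igraph::modularity(g, igraph::membership(cl), weights = w)
    if (is.null(best) || q > best$q) best <- list(cl = cl, q = q,
                                                  seed = run_seed)
  }
  assignment <- stats::setNames(as.integer(igraph::membership(best$cl)),
                                igraph::V(g)$name)
  module_partition(assignment, modularity = best$q, seed = best$seed)
}

#' Compare two module partitions
#'
#' Cross-tabulates shared-gene counts between the modules of two partitions
#' (restricted to genes present in both) and reports, for every module of
#' `p1`, its best-match Jaccard index against the modules of `p2`. Used to
#' assess robustness of module detection between related networks (e.g. the
#' 4-consecutive vs 3-consecutive persistence variants).
#'
#' @param p1,p2 [module_partition()] objects with overlapping gene universes.
#' @return list with `table` (matrix of shared-gene counts, rows = modules of
#'   `p1`), `best_jaccard` (named numeric per module of `p1`) and `ari`
#'   (adjusted Rand index over the shared genes).
#' @export
compare_partitions <- function(p1, p2) {
  stopifnot(inherits(p1, "module_partition"), inherits(p2, "module_partition"))
  shared <- intersect(names(p1$assignment), names(p2$assignment))
  if (length(shared) == 0L) stop("partitions share no genes")
  a1 <- p1$assignment[shared]
  a2 <- p2$assignment[shared]
  tab <- table(factor(a1), factor(a2))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  best <- apply(m, 1L, function(row) {
    sizes1 <- sum(row)
    jac <- row / (sizes1 + colSums(m) - row)
    max(jac)
  })
  list(table = m, best_jaccard = best,
       ari = mclust::adjustedRandIndex(a1, a2))
}
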