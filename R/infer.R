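#' Per-timepoint significant co-expression pairs
#'
#' For each timepoint, Spearman correlations are computed between every pair
#' of testable genes across the individuals sampled at that timepoint, and
#' pairs are selected by Benjamini-Hochberg FDR control applied independently
#' within the timepoint (over all pairs tested there). A gene is testable at a
#' timepoint when it is non-constant over its observed individuals; pairs with
#' missing data are scored on jointly observed individuals only and skipped
#' below `n_min` joint observations.
#'
#' @param tensor an [expression_tensor()].
#' @param fdr per-timepoint Benjamini-Hochberg false-discovery rate
#'   (default 0.10).
#' @param gene_filter optional restriction of the tested gene universe: a
#'   character vector of gene IDs or a predicate `function(gene_ids)` returning
#'   a logical mask.
#' @param exact_n_max exact-p cutoff passed to the Spearman machinery.
#' @param n_min minimum joint observations for pairs with missing data.
#' @return list of `timepoint_edge_set` objects, one per timepoint: selected
#'   pairs with `rho` and `p`, the number of tested pairs `n_tested`, and the
#'   BH threshold realized at that timepoint.
#' @export
per_timepoint_networks <- function(tensor, fdr = 0.10, gene_filter = NULL,
                                   exact_n_max = 9L, n_min = 8L) {
  stopifnot(inherits(tensor, "expression_tensor"))
  genes <- tensor$gene_ids
  keep <- rep(TRUE, length(genes))
  if (!is.null(gene_filter)) {
    keep <- if (is.function(gene_filter)) gene_filter(genes)
            else genes %in% as.character(gene_filter)
  }
  if (sum(keep) < 2L)
    stop("fewer than 2 genes pass the gene filter")
  idx <- which(keep)
  lapply(seq_along(tensor$timepoints_zt), function(t) {
    mat <- tensor$values[idx, t, , drop = FALSE]
    dim(mat) <- c(length(idx), tensor$n_individuals)
    sp <- spearman_pairs_matrix(mat, exact_n_max = exact_n_max, n_min = n_min)
    ut <- upper.tri(sp$p)
    pv <- sp$p[ut]
    rv <- sp$rho[ut]
    ij <- which(ut, arr.ind = TRUE)
    tested <- !is.na(pv)
    sel <- bh_select(pv, fdr)
    thr <- if (any(sel)) max(pv[sel]) else NA_real_
    edges <- data.frame(
      gene_a = genes[idx[ij[sel, 1L]]],
      gene_b = genes[idx[ij[sel, 2L]]],
      rho = rv[sel], p = pv[sel],
      stringsAsFactors = FALSE
    )
    structure(
      list(timepoint_zt = tensor$timepoints_zt[t], edges = edges,
           n_tested = sum(tested), n_selected = sum(sel),
           bh_threshold = thr, fdr = fdr),
      class = "timepoint_edge_set"
    )
  })
}

#' @export
print.timepoint_edge_set <- function(x, ...) {
  cat(sprintf("timepoint_edge_set ZT%d: %d selected of %d tested pairs (FDR %g)\n",
              x$timepoint_zt, x$n_selected, x$n_tested, x$fdr))
  invisible(x)
}

#' Variability network: per-timepoint FDR selection + persistence filter
#'
#' Composes [per_timepoint_networks()] and [persistence_filter()]: a gene pair
#' becomes an edge when its per-timepoint significance mask contains `k`
#' significant timepoints in a row with at most `gaps` intervening
#' non-significant ones. Nodes are exactly the genes incident to a surviving
#' edge. Correlation sign is recorded per timepoint and both signs are kept by
#' default; `positive_only = TRUE` restricts selection to positive rho before
#' the persistence filter.
#'
#' @inheritParams per_timepoint_networks
#' @param k,gaps,circular persistence-filter parameters (defaults 4, 1,
#'   FALSE); see [persistence_filter()].
#' @param positive_only drop negative-rho selections before filtering.
#' @return a [coexpression_network()] with provenance, per-edge support mask
#'   and per-timepoint rho at supporting timepoints.
#' @export
build_variability_network <- function(tensor, fdr = 0.10, k = 4L, gaps = 1L,
                                      circular = FALSE, positive_only = FALSE,
                                      gene_filter = NULL, exact_n_max = 9L,
                                      n_min = 8L) {
  prov <- list(route = "variability", fdr = fdr, k = k, gaps = gaps,
               circular = circular, positive_only = positive_only)
  if (length(tensor$gene_ids) < 2L)
    return(empty_network(tensor$timepoints_zt, prov))
  tps <- per_timepoint_networks(tensor, fdr = fdr, gene_filter = gene_filter,
                                exact_n_max = exact_n_max, n_min = n_min)
  nt <- length(tps)
  # union of selected pairs across timepoints
  keys <- character(0)
  for (t in seq_len(nt)) {
    e <- tps[[t]]$edges
    if (positive_only && nrow(e) > 0L) e <- e[e$rho > 0, , drop = FALSE]
    tps[[t]]$edges <- e
    if (nrow(e) > 0L)
      keys <- c(keys, paste(e$gene_a, e$gene_b, sep = "\r"))
  }
  keys <- sort(unique(keys))
  if (length(keys) == 0L) return(empty_network(tensor$timepoints_zt, prov))
  support <- matrix(FALSE, length(keys), nt)
  rho <- matrix(NA_real_, length(keys), nt)
  for (t in seq_len(nt)) {
    e <- tps[[t]]$edges
    if (nrow(e) == 0L) next
    rowi <- match(paste(e$gene_a, e$gene_b, sep = "\r"), keys)
    support[rowi, t] <- TRUE
    rho[rowi, t] <- e$rho
  }
  pass <- vapply(seq_along(keys), function(i) {
    persistence_filter(support[i, ], k = k, gaps = gaps, circular = circular)
  }, logical(1))
  if (!any(pass)) return(empty_network(tensor$timepoints_zt, prov))
  ab <- do.call(rbind, strsplit(keys[pass], "\r", fixed = TRUE))
  prov$n_selected_by_timepoint <- vapply(tps, function(x) nrow(x$edges),
                                         integer(1))
  prov$n_tested_by_timepoint <- vapply(tps, function(x) x$n_tested, integer(1))
  coexpression_network(
    data.frame(gene_a = ab[, 1L], gene_b = ab[, 2L], stringsAsFactors = FALSE),
    support[pass, , drop = FALSE], rho[pass, , drop = FALSE],
    tensor$timepoints_zt, prov
  )
}

#' Averaged time-course network: Spearman on mean profiles + Bonferroni
#'
#' The conventional inference route: each gene is reduced to its
#' mean-over-individuals time profile, Spearman correlations are computed
#' between profile pairs, and a pair becomes an edge when its two-sided p
#' satisfies the Bonferroni cut `p <= alpha / m`, where `m` is the number of
#' tested pairs. Genes with constant profiles are unscored.
#'
#' @param tensor an [expression_tensor()].
#' @param alpha family-wise significance level before Bonferroni division
#'   (default 0.05).
#' @param exact_n_max exact-p cutoff (profiles have as many points as
#'   timepoints, so the t-approximation is used on the usual 12-point grid).
#' @return a [coexpression_network()]; edges carry profile `rho` and `p`
#'   columns, and the support mask is empty (this route has no per-timepoint
#'   detection concept).
#' @export
build_averaged_network <- function(tensor, alpha = 0.05, exact_n_max = 9L) {
  stopifnot(inherits(tensor, "expression_tensor"))
  if (length(tensor$timepoints_zt) < 3L)
    stop("averaged route needs at least 3 timepoints")
  prov <- list(route = "averaged", alpha = alpha)
  prof <- mean_profiles(tensor)
  sp <- spearman_pairs_matrix(prof, exact_n_max = exact_n_max, n_min = 3L)
  ut <- upper.tri(sp$p)
  pv <- sp$p[ut]
  rv <- sp$rho[ut]
  ij <- which(ut, arr.ind = TRUE)
  m <- sum(!is.na(pv))
  prov$n_tested_pairs <- m
  if (m == 0L) return(empty_network(integer(0), prov))
  sel <- !is.na(pv) & pv <= alpha / m
  if (!any(sel)) return(empty_network(integer(0), prov))
  edges <- data.frame(gene_a = tensor$gene_ids[ij[sel, 1L]],
                      gene_b = tensor$gene_ids[ij[sel, 2L]],
                      rho = rv[sel], p = pv[sel], stringsAsFactors = FALSE)
  coexpression_network(edges,
                       matrix(logical(0), nrow(edges), 0L),
                       matrix(numeric(0), nrow(edges), 0L),
                       integer(0), prov)
}

#' Number of network edges detected at each timepoint
#'
#' For the variability route: the count of surviving edges whose support mask
#' is true at each timepoint (the per-timepoint edge-count profile of the
#' final network).
#'
#' @param net a [coexpression_network()].
#' @return named integer vector over ZT hours.
#' @export
edge_counts_by_timepoint <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  counts <- if (n_edges(net) == 0L) rep(0L, length(net$timepoints_zt))
            else as.integer(colSums(net$support))
  names(counts) <- as.character(net$timepoints_zt)
  counts
}
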