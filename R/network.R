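#' Co-expression network with per-edge timepoint support
#'
#' Undirected graph over genes. Each edge carries its support mask (at which
#' ZT timepoints the pair passed the per-timepoint FDR cut, or a single slot
#' for the averaged route) and the corresponding Spearman rho values.
#'
#' @param edges data.frame with character columns `gene_a`, `gene_b`
#'   (canonicalized so `gene_a < gene_b`; no self-pairs).
#' @param support logical matrix, one row per edge, one column per timepoint.
#' @param rho numeric matrix of the same shape (NA where unscored).
#' @param timepoints_zt integer ZT hours labelling the support columns.
#' @param provenance list describing the route (`"variability"` or
#'   `"averaged"`) and the parameters used.
#' @return object of class `coexpression_network`.
#' @export
coexpression_network <- function(edges, support, rho, timepoints_zt,
                                 provenance = list()) {
  edges$gene_a <- as.character(edges$gene_a)
  edges$gene_b <- as.character(edges$gene_b)
  if (nrow(edges) > 0L) {
    if (any(edges$gene_a == edges$gene_b)) stop("self-loops are not allowed")
    swap <- edges$gene_a > edges$gene_b
    if (any(swap)) {
      tmp <- edges$gene_a[swap]
      edges$gene_a[swap] <- edges$gene_b[swap]
      edges$gene_b[swap] <- tmp
    }
    o <- order(edges$gene_a, edges$gene_b)
    edges <- edges[o, , drop = FALSE]
    support <- support[o, , drop = FALSE]
    rho <- rho[o, , drop = FALSE]
    if (anyDuplicated(edges[c("gene_a", "gene_b")]))
      stop("duplicate edges")
  }
  rownames(edges) <- NULL
  stopifnot(nrow(support) == nrow(edges), nrow(rho) == nrow(edges),
            ncol(support) == length(timepoints_zt),
            ncol(rho) == length(timepoints_zt))
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  structure(
    list(nodes = nodes, edges = edges,
         support = matrix(as.logical(support), nrow = nrow(edges),
                          ncol = length(timepoints_zt)),
         rho = matrix(as.numeric(rho), nrow = nrow(edges),
                      ncol = length(timepoints_zt)),
         timepoints_zt = as.integer(timepoints_zt),
         provenance = provenance),
    class = "coexpression_network"
  )
}

empty_network <- function(timepoints_zt, provenance = list()) {
  coexpression_network(
    data.frame(gene_a = character(0), gene_b = character(0)),
    matrix(logical(0), nrow = 0, ncol = length(timepoints_zt)),
    matrix(numeric(0), nrow = 0, ncol = length(timepoints_zt)),
    timepoints_zt, provenance
  )
}

#' @export
print.coexpression_network <- function(x, ...) {
  route <- if (is.null(x$provenance$route)) "unknown" else x$provenance$route
  cat(sprintf("coexpression_network (%s route): %d genes, %d edges\n",
              route, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of edges / nodes of a network
#' @param net a [coexpression_network()].
#' @return integer count.
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname n_edges
#' @export
n_nodes <- function(net) length(net$nodes)

# mean rho per edge over supporting timepoints; averaged-route edges carry a
# single profile rho in the edge table instead of a per-timepoint vector
edge_mean_rho <- function(net) {
  if (n_edges(net) == 0L) return(numeric(0))
  if (ncol(net$rho) == 0L) {
    if (!is.null(net$edges$rho)) return(net$edges$rho)
    return(rep(NA_real_, n_edges(net)))
  }
  vapply(seq_len(n_edges(net)), function(e) {
    r <- net$rho[e, ]
    m <- net$support[e, ] & !is.na(r)
    if (!any(m)) m <- !is.na(r)
    if (!any(m)) return(NA_real_)
    mean(r[m])
  }, numeric(1))
}

edge_support_zt <- function(net) {
  vapply(seq_len(n_edges(net)), function(e) {
    paste(net$timepoints_zt[which(net$support[e, ])], collapse = ",")
  }, character(1))
}

#' Write a network to an edge-list TSV and a GraphML file
#'
#' Edge rows are canonical (`gene_a < gene_b`, sorted), so the TSV is
#' byte-stable across runs on identical input. Columns: `gene_a`, `gene_b`,
#' `n_supporting_timepoints`, `supporting_zt` (comma-joined ZT hours),
#' `mean_rho`.
#'
#' @param net a [coexpression_network()].
#' @param edge_path output TSV path.
#' @param graphml_path optional GraphML output path (same attributes).
#' @return Invisibly, the written paths.
#' @export
write_network <- function(net, edge_path, graphml_path = NULL) {
  stopifnot(inherits(net, "coexpression_network"))
  df <- data.frame(
    gene_a = net$edges$gene_a, gene_b = net$edges$gene_b,
    n_supporting_timepoints = if (n_edges(net)) rowSums(net$support) else integer(0),
    supporting_zt = edge_support_zt(net),
    mean_rho = edge_mean_rho(net),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path)) {
    g <- as_igraph(net)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(c(edge_path, graphml_path))
}

#' Convert a co-expression network to an igraph object
#'
#' Edge attributes: `n_supporting_timepoints`, `supporting_zt`, `mean_rho`.
#' Graph attributes record the timepoint grid and route.
#'
#' @param net a [coexpression_network()].
#' @return an `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  g <- igraph::graph_from_data_frame(
    d = data.frame(
      from = net$edges$gene_a, to = net$edges$gene_b,
      n_supporting_timepoints = if (n_edges(net)) rowSums(net$support) else integer(0),
      supporting_zt = edge_support_zt(net),
      mean_rho = edge_mean_rho(net),
      stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
  g <- igraph::set_graph_attr(g, "timepoints_zt",
                              paste(net$timepoints_zt, collapse = ","))
  route <- if (is.null(net$provenance$route)) "" else net$provenance$route
  igraph::set_graph_attr(g, "route", route)
}

#' Read a network back from its edge-list TSV
#'
#' Reconstructs the support mask from the `supporting_zt` column; rho values
#' are restored only as the per-edge `mean_rho` replicated over supporting
#' timepoints (the TSV does not carry per-timepoint rho).
#'
#' @param edge_path TSV written by [write_network()].
#' @param timepoints_zt the timepoint grid of the originating analysis.
#' @return a [coexpression_network()].
#' @export
read_network <- function(edge_path, timepoints_zt) {
  df <- utils::read.delim(edge_path, sep = "\t", stringsAsFactors = FALSE)
  timepoints_zt <- as.integer(timepoints_zt)
  nt <- length(timepoints_zt)
  ne <- nrow(df)
  support <- matrix(FALSE, ne, nt)
  rho <- matrix(NA_real_, ne, nt)
  if (ne > 0L) {
    for (e in seq_len(ne)) {
      if (nzchar(df$supporting_zt[e])) {
        zt <- as.integer(strsplit(df$supporting_zt[e], ",", fixed = TRUE)[[1L]])
        idx <- match(zt, timepoints_zt)
        support[e, idx] <- TRUE
        rho[e, idx] <- df$mean_rho[e]
      }
    }
  }
  coexpression_network(df[, c("gene_a", "gene_b"), drop = FALSE],
                       support, rho, timepoints_zt)
}

#' Genes and edges shared between two networks
#'
#' @param a,b [coexpression_network()] objects.
#' @return list with `shared_genes` and `shared_edges` counts.
#' @export
network_overlap <- function(a, b) {
  stopifnot(inherits(a, "coexpression_network"),
            inherits(b, "coexpression_network"))
  key <- function(n) paste(n$edges$gene_a, n$edges$gene_b, sep = "\r")
  list(shared_genes = length(intersect(a$nodes, b$nodes)),
       shared_edges = length(intersect(key(a), key(b))))
}

#' Write / read a module partition as a gene_id -> module_id TSV
#'
#' @param partition a [module_partition()].
#' @param path TSV path.
#' @return Invisibly `path` (write) or a [module_partition()] (read).
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "module_partition"))
  df <- data.frame(gene_id = if (length(partition$assignment))
                               names(partition$assignment) else character(0),
                   module_id = unname(partition$assignment))
  df <- df[order(df$gene_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  a <- as.integer(df$module_id)
  names(a) <- as.character(df$gene_id)
  module_partition(a)
}
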