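#' Specification for a synthetic diurnal transcriptome
#'
#' Describes a study of genetically identical individuals sampled at ZT
#' timepoints over one day/night cycle: a set of co-expression modules whose
#' inter-individual coupling varies with time of day, a tier of
#' highly-variable genes (HVGs), and uncorrelated background genes.
#'
#' The default study emulates the design the inference method targets:
#' 12 timepoints (ZT 0, 2, ..., 22) x 14 individuals, three 20-gene modules
#' coupled at strength 0.9 over six consecutive timepoints (one day-coupled,
#' one night-coupled, one coupled across the day/night transition; the first
#' an HVG module), and 400 background genes.
#'
#' @param modules list of module descriptors, each a list with `size`
#'   (gene count), `hvg` (logical), `coupling` (numeric vector over
#'   timepoints, target pairwise inter-individual correlation in `[0, 1]`),
#'   and `profile` (diurnal mean profile id: `"sin_peak<ZT>"`, `"square_day"`,
#'   `"square_night"` or `"flat"`).
#' @param n_background number of uncorrelated background genes.
#' @param n_timepoints,n_individuals study dimensions (defaults 12 and 14).
#' @param hvg_dispersion_multiplier variance-tier multiplier applied to the
#'   residual noise of HVG genes (their shared-factor loading scales with it,
#'   so HVG modules stay internally correlated).
#' @param noise_sd residual standard deviation of a non-HVG gene.
#' @param background_hvg_fraction fraction of background genes flagged HVG
#'   (default 0.087, the transcriptome-wide HVG rate the design emulates).
#' @param true_edge_threshold coupling above which a within-module pair
#'   counts as a true edge at that timepoint (default 0.5).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(modules = default_modules(),
                           n_background = 400L,
                           n_timepoints = 12L,
                           n_individuals = 14L,
                           hvg_dispersion_multiplier = 3,
                           noise_sd = 1,
                           background_hvg_fraction = 0.087,
                           true_edge_threshold = 0.5) {
  stopifnot(n_timepoints >= 1L, n_individuals >= 3L,
            hvg_dispersion_multiplier > 0, noise_sd >= 0)
  for (m in modules) {
    if (length(m$coupling) != n_timepoints)
      stop("spec error: coupling vector length must equal n_timepoints")
    if (any(m$coupling < 0 | m$coupling > 1))
      stop("spec error: coupling must lie in [0, 1]")
    if (is.null(m$size) || m$size < 2L)
      stop("spec error: module size must be >= 2")
  }
  structure(
    list(modules = modules, n_background = as.integer(n_background),
         n_timepoints = as.integer(n_timepoints),
         n_individuals = as.integer(n_individuals),
         hvg_dispersion_multiplier = hvg_dispersion_multiplier,
         noise_sd = noise_sd,
         background_hvg_fraction = background_hvg_fraction,
         true_edge_threshold = true_edge_threshold),
    class = "synthetic_spec"
  )
}

#' @rdname synthetic_spec
#' @export
default_modules <- function() {
  on6 <- function(start) {  # coupling 0.9 on 6 consecutive slots of 12
    v <- rep(0, 12)
    v[((start - 1L + 0:5) %% 12L) + 1L] <- 0.9
    v
  }
  list(
    list(size = 20L, hvg = TRUE,  coupling = on6(1L), profile = "sin_peak6"),
    list(size = 20L, hvg = FALSE, coupling = on6(7L), profile = "square_night"),
    list(size = 20L, hvg = FALSE, coupling = on6(4L), profile = "sin_peak12")
  )
}

# diurnal mean profile library over ZT hours; amplitude ~1 unit around 0
profile_value <- function(profile, zt) {
  if (startsWith(profile, "sin_peak")) {
    peak <- as.numeric(sub("sin_peak", "", profile))
    cos(2 * pi * (zt - peak) / 24)
  } else if (profile == "square_day") {
    ifelse(zt < 12, 1, -1)
  } else if (profile == "square_night") {
    ifelse(zt < 12, -1, 1)
  } else if (profile == "flat") {
    rep(0, length(zt))
  } else stop("unknown profile id: ", profile)
}

#' Generate a synthetic expression tensor with ground truth
#'
#' Module members follow a single-latent-factor model per module per
#' timepoint: `x[g,t,i] = mu_g(t) + lambda_g(t) * F[m,t,i] + eps[g,t,i]`,
#' with `F ~ N(0,1)` shared by the module's genes at that timepoint and
#' `eps ~ N(0, sd_g)` independent. The loading is
#' `lambda_g(t) = sd_g * sqrt(rho_t / (1 - rho_t))`, so the expected pairwise
#' inter-individual correlation of two members equals the spec's coupling
#' `rho_t` exactly, whatever their noise tiers. HVG genes have
#' `sd_g = noise_sd * hvg_dispersion_multiplier` (loading and noise both
#' scale, so HVG modules stay internally correlated while being more
#' dispersed). With `noise_sd = 0`, members are exact copies of the factor
#' (any positive coupling then yields |rho| = 1). Background genes are pure
#' `mu + eps`.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; the same seed yields a bit-identical tensor.
#' @return list with `tensor` (an [expression_tensor()]) and `truth` (class
#'   `ground_truth`): `module` (named integer, 0 = background), `hvg` (named
#'   logical), `true_edges` (canonical within-module pairs whose coupling
#'   exceeds the spec threshold at >= 1 timepoint) and `true_edges_by_timepoint`.
#' @export
generate_expression <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(as.integer(seed))
  nt <- spec$n_timepoints
  ni <- spec$n_individuals
  zt <- seq(0L, by = as.integer(round(24 / nt)), length.out = nt)
  n_mod_genes <- sum(vapply(spec$modules, function(m) m$size, integer(1)))
  g <- n_mod_genes + spec$n_background
  gene_ids <- sprintf("G%04d", seq_len(g))
  module <- integer(g)
  hvg <- logical(g)
  vals <- array(NA_real_, dim = c(g, nt, ni))
  baseline <- stats::rnorm(g, mean = 8, sd = 1)
  amplitude <- 2  # diurnal swing in expression units
  gi <- 0L
  for (mi in seq_along(spec$modules)) {
    m <- spec$modules[[mi]]
    rows <- gi + seq_len(m$size)
    gi <- gi + m$size
    module[rows] <- mi
    hvg[rows] <- isTRUE(m$hvg)
    sd_g <- spec$noise_sd * if (isTRUE(m$hvg)) spec$hvg_dispersion_multiplier else 1
    mu_t <- amplitude * profile_value(m$profile, zt)
    for (t in seq_len(nt)) {
      rho <- m$coupling[t]
      lambda <- if (spec$noise_sd == 0) {
        if (rho > 0) 1 else 0
      } else {
        sd_g * sqrt(rho / max(1 - rho, .Machine$double.eps))
      }
      f <- stats::rnorm(ni)
      eps <- matrix(stats::rnorm(length(rows) * ni, sd = sd_g),
                    nrow = length(rows))
      vals[rows, t, ] <- baseline[rows] + mu_t[t] +
        lambda * rep(f, each = length(rows)) + eps
    }
  }
  if (spec$n_background > 0L) {
    rows <- n_mod_genes + seq_len(spec$n_background)
    n_bg_hvg <- round(spec$background_hvg_fraction * spec$n_background)
    hvg[rows[seq_len(n_bg_hvg)]] <- TRUE
    sd_bg <- spec$noise_sd *
      ifelse(hvg[rows], spec$hvg_dispersion_multiplier, 1)
    # background genes still follow diurnal means (flat/sinusoid mix) so the
    # averaged route has profile structure to work with
    prof <- rep(c("flat", "sin_peak0", "sin_peak8", "sin_peak16"),
                length.out = spec$n_background)
    for (b in seq_along(rows)) {
      mu_t <- baseline[rows[b]] + amplitude * profile_value(prof[b], zt)
      vals[rows[b], , ] <- mu_t +
        matrix(stats::rnorm(nt * ni, sd = sd_bg[b]), nrow = nt)
    }
  }
  names(module) <- gene_ids
  names(hvg) <- gene_ids
  truth <- structure(
    list(module = module, hvg = hvg,
         true_edges = true_edges_from_modules(spec, gene_ids, module,
                                              union_only = TRUE),
         true_edges_by_timepoint =
           true_edges_from_modules(spec, gene_ids, module, union_only = FALSE),
         timepoints_zt = zt),
    class = "ground_truth"
  )
  list(tensor = expression_tensor(vals, gene_ids, zt), truth = truth)
}

true_edges_from_modules <- function(spec, gene_ids, module, union_only) {
  per_tp <- vector("list", spec$n_timepoints)
  all_pairs <- NULL
  for (mi in seq_along(spec$modules)) {
    rows <- which(module == mi)
    cp <- t(utils::combn(gene_ids[rows], 2L))
    pairs <- data.frame(gene_a = pmin(cp[, 1L], cp[, 2L]),
                        gene_b = pmax(cp[, 1L], cp[, 2L]),
                        stringsAsFactors = FALSE)
    active <- spec$modules[[mi]]$coupling > spec$true_edge_threshold
    if (any(active)) all_pairs <- rbind(all_pairs, pairs)
    for (t in which(active)) per_tp[[t]] <- rbind(per_tp[[t]], pairs)
  }
  if (union_only) {
    if (is.null(all_pairs)) return(data.frame(gene_a = character(0),
                                              gene_b = character(0)))
    return(unique(all_pairs))
  }
  lapply(per_tp, function(d) {
    if (is.null(d)) data.frame(gene_a = character(0), gene_b = character(0))
    else unique(d)
  })
}

#' Score an inferred network and partition against ground truth
#'
#' Edge precision and recall are computed against the union over timepoints
#' of true within-module edges. Partition agreement is the adjusted Rand
#' index restricted to genes in nonzero true modules; true-module genes
#' missing from the inferred partition (no surviving edges) receive unique
#' singleton labels, so missed genes count against agreement.
#'
#' @param inferred a [coexpression_network()].
#' @param truth the `ground_truth` from [generate_expression()].
#' @param partition optional [module_partition()] of the inferred network;
#'   when supplied, `partition_agreement` is reported.
#' @return list with `edge_precision`, `edge_recall` and (if a partition is
#'   given) `partition_agreement`. An empty inferred network has recall 0 and
#'   precision 1 by convention (noted via message).
#' @export
evaluate_recovery <- function(inferred, truth, partition = NULL) {
  stopifnot(inherits(inferred, "coexpression_network"),
            inherits(truth, "ground_truth"))
  if (length(intersect(inferred$nodes, names(truth$module))) == 0L &&
      n_edges(inferred) > 0L)
    stop("inferred network and truth share no genes")
  tkey <- paste(truth$true_edges$gene_a, truth$true_edges$gene_b, sep = "\r")
  ikey <- paste(inferred$edges$gene_a, inferred$edges$gene_b, sep = "\r")
  if (length(ikey) == 0L) {
    message("empty inferred network: precision reported as 1 by convention")
    precision <- 1
  } else {
    precision <- mean(ikey %in% tkey)
  }
  recall <- if (length(tkey) == 0L) 1 else mean(tkey %in% ikey)
  out <- list(edge_precision = precision, edge_recall = recall)
  if (!is.null(partition)) {
    stopifnot(inherits(partition, "module_partition"))
    genes <- names(truth$module)[truth$module != 0L]
    inferred_lab <- partition$assignment[genes]
    miss <- is.na(inferred_lab)
    # unique labels for unclustered genes, disjoint from real module ids
    inferred_lab[miss] <- max(partition$assignment, -1L) + seq_len(sum(miss))
    out$partition_agreement <-
      mclust::adjustedRandIndex(truth$module[genes], inferred_lab)
  }
  out
}

#' Write the synthetic study to disk
#'
#' Writes the expression and metadata TSVs, the HVG list, the true module
#' map and the true edge list, in the formats the rest of the pipeline
#' consumes.
#'
#' @param sim result of [generate_expression()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_synthetic_study <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$tensor,
                   file.path(out_dir, "expression.tsv"),
                   file.path(out_dir, "metadata.tsv"))
  writeLines(names(sim$truth$hvg)[sim$truth$hvg],
             file.path(out_dir, "hvg.txt"))
  utils::write.table(
    data.frame(gene_id = names(sim$truth$module),
               module_id = unname(sim$truth$module)),
    file.path(out_dir, "true_modules.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$true_edges,
                     file.path(out_dir, "true_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
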