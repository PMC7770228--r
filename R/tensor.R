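#' Expression tensor: genes x timepoints x individuals
#'
#' The substrate of all correlation analysis: one normalized expression value
#' per gene, Zeitgeber timepoint and individual. Missing values are stored as
#' `NA` (absent, never zero) and excluded pair-wise downstream.
#'
#' @param values numeric array of dimension (genes, timepoints, individuals);
#'   `NA` marks a missing observation.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param timepoints_zt strictly increasing integer vector of ZT hours in
#'   `[0, 24)`, one per timepoint slice.
#' @return An object of class `expression_tensor`: a list with elements
#'   `values`, `gene_ids`, `timepoints_zt`, `n_individuals`.
#' @export
expression_tensor <- function(values, gene_ids, timepoints_zt) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-d array (gene x timepoint x individual)")
  gene_ids <- as.character(gene_ids)
  timepoints_zt <- as.integer(timepoints_zt)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene IDs in tensor")
  if (length(gene_ids) != dim(values)[1L])
    stop("gene_ids length does not match values")
  if (length(timepoints_zt) != dim(values)[2L])
    stop("timepoints_zt length does not match values")
  if (is.unsorted(timepoints_zt, strictly = TRUE))
    stop("timepoints_zt must be strictly increasing")
  if (any(timepoints_zt < 0L | timepoints_zt >= 24L))
    stop("timepoints_zt must be ZT hours in [0, 24)")
  dimnames(values) <- list(gene_ids, as.character(timepoints_zt),
                           seq_len(dim(values)[3L]))
  structure(
    list(values = values, gene_ids = gene_ids,
         timepoints_zt = timepoints_zt, n_individuals = dim(values)[3L]),
    class = "expression_tensor"
  )
}

#' @export
print.expression_tensor <- function(x, ...) {
  cat(sprintf("expression_tensor: %d genes x %d timepoints x %d individuals\n",
              length(x$gene_ids), length(x$timepoints_zt), x$n_individuals))
  cat("  ZT hours:", paste(x$timepoints_zt, collapse = ", "), "\n")
  n_na <- sum(is.na(x$values))
  if (n_na > 0L) cat(sprintf("  missing values: %d\n", n_na))
  invisible(x)
}

#' @export
dim.expression_tensor <- function(x) dim(x$values)

#' Read an expression matrix and sample metadata into a tensor
#'
#' The matrix is a TSV with gene IDs in the first column and sample IDs in the
#' header; the metadata TSV (columns `sample_id`, `timepoint_zt`, `individual`)
#' must map every sample column to a (ZT hour, individual index) cell.
#'
#' @param matrix_path path to the genes-in-rows expression TSV.
#' @param metadata_path path to the sample metadata TSV.
#' @return An [expression_tensor()].
#' @export
read_expression <- function(matrix_path, metadata_path) {
  mat <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(mat) < 2L) stop("expression matrix has no sample columns")
  gene_ids <- as.character(mat[[1L]])
  if (anyDuplicated(gene_ids))
    stop("schema error: duplicate gene IDs in expression matrix: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  x <- as.matrix(mat[, -1L, drop = FALSE])
  storage.mode(x) <- "double"
  meta <- read_sample_metadata(metadata_path)
  missing_meta <- setdiff(colnames(x), meta$sample_id)
  if (length(missing_meta) > 0L)
    stop("schema error: matrix samples absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  meta <- meta[match(colnames(x), meta$sample_id), , drop = FALSE]
  tps <- sort(unique(meta$timepoint_zt))
  inds <- sort(unique(meta$individual))
  vals <- array(NA_real_, dim = c(length(gene_ids), length(tps), length(inds)))
  ti <- match(meta$timepoint_zt, tps)
  ii <- match(meta$individual, inds)
  for (s in seq_len(ncol(x)))
    vals[, ti[s], ii[s]] <- x[, s]
  expression_tensor(vals, gene_ids, tps)
}

read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  need <- c("sample_id", "timepoint_zt", "individual")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0L)
    stop("schema error: metadata lacks columns: ", paste(miss, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  meta$timepoint_zt <- as.integer(meta$timepoint_zt)
  meta$individual <- as.integer(meta$individual)
  if (anyDuplicated(meta$sample_id))
    stop("schema error: duplicate sample_id in metadata")
  if (anyDuplicated(meta[c("timepoint_zt", "individual")]))
    stop("schema error: duplicate (timepoint_zt, individual) pair in metadata")
  if (any(meta$timepoint_zt < 0L | meta$timepoint_zt >= 24L))
    stop("schema error: timepoint_zt must lie in [0, 24)")
  if (any(meta$individual < 1L))
    stop("schema error: individual index must be >= 1")
  meta
}

#' Write an expression tensor back to matrix + metadata TSVs
#'
#' Inverse of [read_expression()]: cells that are `NA` in the tensor are
#' written as `NA` so a round trip is value-identical.
#'
#' @param tensor an [expression_tensor()].
#' @param matrix_path,metadata_path output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(tensor, matrix_path, metadata_path) {
  stopifnot(inherits(tensor, "expression_tensor"))
  d <- dim(tensor$values)
  sample_ids <- character(0)
  cols <- list()
  meta <- data.frame(sample_id = character(0), timepoint_zt = integer(0),
                     individual = integer(0))
  k <- 0L
  for (t in seq_len(d[2L])) {
    for (i in seq_len(d[3L])) {
      v <- tensor$values[, t, i]
      if (all(is.na(v))) next  # sample never observed
      k <- k + 1L
      sid <- sprintf("ZT%02d_ind%02d", tensor$timepoints_zt[t], i)
      sample_ids[k] <- sid
      cols[[k]] <- v
      meta <- rbind(meta, data.frame(sample_id = sid,
                                     timepoint_zt = tensor$timepoints_zt[t],
                                     individual = i))
    }
  }
  out <- data.frame(gene_id = tensor$gene_ids, stringsAsFactors = FALSE)
  for (k2 in seq_along(cols)) out[[sample_ids[k2]]] <- cols[[k2]]
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, metadata_path))
}

#' Mean-over-individuals time profiles
#'
#' @param tensor an [expression_tensor()].
#' @return numeric matrix genes x timepoints of per-timepoint means
#'   (`NA`-aware).
#' @export
mean_profiles <- function(tensor) {
  stopifnot(inherits(tensor, "expression_tensor"))
  apply(tensor$values, c(1L, 2L), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
}
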