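#' Gene set collection
#'
#' Named gene sets (HVG lists, transcription-factor target lists, GO-style
#' terms) plus an optional declared background universe for enrichment.
#'
#' @param sets named list of character vectors (no duplicates within a set).
#' @param universe optional character vector; when declared, every set is
#'   intersected against it.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets = list(), universe = NULL) {
  if (length(sets) > 0L && is.null(names(sets)))
    stop("sets must be named")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (!is.null(universe)) {
    universe <- unique(as.character(universe))
    sets <- lapply(sets, intersect, y = universe)
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets%s\n", length(x$sets),
              if (is.null(x$universe)) ""
              else sprintf(", universe of %d genes", length(x$universe))))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, `name TAB description TAB gene1 TAB ...`.
#' Duplicate genes within a line are removed with a warning.
#'
#' @param path path to a GMT file.
#' @param universe optional background universe to attach.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT parse error at line %d: fewer than 3 fields", i))
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT line %d ('%s'): duplicate genes removed", i, f[1L]))
      genes <- unique(genes)
    }
    sets[[f[1L]]] <- genes
  }
  gene_set_collection(sets, universe = universe)
}

#' Write gene sets in GMT format
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  nm <- names(collection$sets)
  if (is.null(descriptions)) descriptions <- rep("na", length(nm))
  lines <- vapply(seq_along(nm), function(i) {
    paste(c(nm[i], descriptions[i], collection$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a one-gene-per-line list (e.g. the HVG list)
#'
#' @param path text file with one gene ID per line; blank lines ignored.
#' @return character vector of unique gene IDs.
#' @export
read_gene_list <- function(path) {
  g <- trimws(readLines(path))
  unique(g[nzchar(g)])
}
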