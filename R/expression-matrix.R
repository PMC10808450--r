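#' Gene-by-cell expression matrix with per-cell cluster labels
#'
#' Lightweight container for a non-negative gene x cell expression matrix
#' (TPM-like arbitrary units) together with unique gene and cell identifiers
#' and a cluster label for every cell. All inference in oscinfer operates on
#' one cluster of cells at a time, so the cluster labels are part of the
#' container rather than a side table.
#'
#' @param values numeric matrix, genes in rows, cells in columns, all
#'   entries >= 0. Dimnames, if present, seed `gene_ids`/`cell_ids`.
#' @param gene_ids character vector of unique gene symbols (rows).
#' @param cell_ids character vector of unique cell barcodes (columns).
#' @param clusters cluster label per cell: either a vector of length
#'   `ncol(values)` (optionally named by cell id) or a single label recycled
#'   to all cells.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `gene_ids`, `cell_ids`, `clusters` (named character vector,
#'   one label per cell).
#' @examples
#' m <- expression_matrix(matrix(1:6, 2, 3), c("A", "B"),
#'                        c("c1", "c2", "c3"), "cluster1")
#' cluster_labels(m)
#' @export
expression_matrix <- function(values,
                              gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              clusters = "cluster1") {
  check_that(is.matrix(values) && is.numeric(values),
             "`values` must be a numeric matrix (genes x cells)")
  check_that(all(is.finite(values)), "`values` must be finite")
  check_that(all(values >= 0), "expression values must be non-negative")
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%d", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- sprintf("cell%d", seq_len(ncol(values)))
  check_that(length(gene_ids) == nrow(values),
             "`gene_ids` must name every row of `values`")
  check_that(length(cell_ids) == ncol(values),
             "`cell_ids` must name every column of `values`")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  check_that(!anyDuplicated(gene_ids), "duplicate gene_ids are not allowed")
  check_that(!anyDuplicated(cell_ids), "duplicate cell_ids are not allowed")
  if (length(clusters) == 1L) clusters <- rep(clusters, length(cell_ids))
  check_that(length(clusters) == length(cell_ids),
             "`clusters` must give one label per cell")
  check_that(!anyNA(clusters) && all(nzchar(as.character(clusters))),
             "every cell must have a non-empty cluster label")
  clusters <- stats::setNames(as.character(clusters), cell_ids)
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 clusters = clusters),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
#' @method print expression_matrix
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells, %d cluster(s)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$clusters))))
  invisible(x)
}

#' Cluster labels of an expression matrix
#'
#' @param x an [expression_matrix()].
#' @return Sorted unique cluster labels.
#' @export
cluster_labels <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  sort(unique(unname(x$clusters)))
}

#' Cell barcodes belonging to one cluster
#'
#' @param x an [expression_matrix()].
#' @param cluster a cluster label present in `x`.
#' @return Character vector of cell ids.
#' @export
cluster_cells <- function(x, cluster) {
  stopifnot(inherits(x, "expression_matrix"))
  check_that(cluster %in% x$clusters,
             sprintf("unknown cluster '%s'", cluster))
  names(x$clusters)[x$clusters == cluster]
}
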