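#' Zero-filtering: genes expressed in at least a fraction of a cluster's cells
#'
#' A gene enters inference only if it is detected (expression strictly
#' greater than zero) in at least `threshold` of the cluster's cells. The
#' comparison is inclusive: with 5 cells and the default threshold, a gene
#' detected in exactly 4 cells (80%) is kept. Zero values degrade the
#' paired-sine fit, which motivates the filter.
#'
#' @param matrix an [expression_matrix()].
#' @param cluster cluster label to filter within.
#' @param threshold required detected fraction, in `(0, 1]` (default 0.8).
#' @return Character vector of passing gene ids, in matrix row order.
#' @examples
#' m <- expression_matrix(rbind(a = c(1, 2, 0, 1, 3), b = c(0, 0, 1, 1, 0)),
#'                        clusters = "c")
#' zero_filter(m, "c")  # "a": detected in 4/5 cells
#' @export
zero_filter <- function(matrix, cluster, threshold = 0.8) {
  stopifnot(inherits(matrix, "expression_matrix"))
  check_that(is_number(threshold) && threshold > 0 && threshold <= 1,
             "threshold must lie in (0, 1]")
  cells <- cluster_cells(matrix, cluster)
  vals <- matrix$values[, cells, drop = FALSE]
  frac <- rowMeans(vals > 0)
  matrix$gene_ids[frac >= threshold]
}

#' Variance-filtering: genes more variable than the average gene
#'
#' Among the candidate genes (normally the zero-filter survivors), keeps
#' those whose expression variance across the cluster's cells is strictly
#' greater than the mean of those variances. Variance is the sample variance
#' with denominator n - 1. Ties at exactly the mean are excluded; if all
#' candidate variances are equal, nothing is kept.
#'
#' @param matrix an [expression_matrix()].
#' @param cluster cluster label.
#' @param candidate_genes genes to consider (subset of the matrix's genes).
#' @return Character vector of passing gene ids, in matrix row order.
#' @export
variance_filter <- function(matrix, cluster, candidate_genes) {
  stopifnot(inherits(matrix, "expression_matrix"))
  check_that(all(candidate_genes %in% matrix$gene_ids),
             "candidate_genes must be a subset of the matrix's genes")
  if (length(candidate_genes) == 0) {
    warning("empty candidate gene set; nothing to filter")
    return(character(0))
  }
  cells <- cluster_cells(matrix, cluster)
  candidate_genes <- matrix$gene_ids[matrix$gene_ids %in% candidate_genes]
  vals <- matrix$values[candidate_genes, cells, drop = FALSE]
  v <- apply(vals, 1, stats::var)
  candidate_genes[v > mean(v)]
}

#' Per-cluster filtering cascade report
#'
#' Applies [zero_filter()] then [variance_filter()] for every cluster and
#' tabulates the cascade; `n_oscillators` is `NA` until filled by
#' [infer_oscillators()].
#'
#' @param matrix an [expression_matrix()].
#' @param threshold zero-filter detected fraction.
#' @return data.frame with columns `cluster`, `n_expressed`, `n_variable`,
#'   `n_oscillators`.
#' @export
filter_report <- function(matrix, threshold = 0.8) {
  stopifnot(inherits(matrix, "expression_matrix"))
  cl <- cluster_labels(matrix)
  rows <- lapply(cl, function(cc) {
    expressed <- zero_filter(matrix, cc, threshold)
    variable <- if (length(expressed)) {
      variance_filter(matrix, cc, expressed)
    } else character(0)
    data.frame(cluster = cc, n_expressed = length(expressed),
               n_variable = length(variable), n_oscillators = NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
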