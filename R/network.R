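#' Build the co-oscillation network from pair statistics
#'
#' Every tested gene becomes a node; every pair with `q_value <= alpha`
#' becomes an undirected edge carrying `epsilon`, `psi_hat` and `q_value` as
#' attributes. Genes without a significant partner remain isolated nodes.
#'
#' @param pairs data.frame with columns `gene_i`, `gene_j`, `epsilon`,
#'   `psi_hat`, `q_value` (as produced by [all_pair_statistics()] plus
#'   [pair_pvalue()]/[bh_adjust()]).
#' @param alpha FDR level for edge inclusion.
#' @return An [igraph::graph] (undirected, no self-loops) whose vertices are
#'   the sorted tested genes.
#' @export
build_network <- function(pairs, alpha = 0.05) {
  check_that(is.data.frame(pairs) &&
               all(c("gene_i", "gene_j", "q_value") %in% names(pairs)),
             "pairs must have columns gene_i, gene_j, q_value")
  check_that(is_number(alpha) && alpha > 0 && alpha <= 1,
             "alpha must lie in (0, 1]")
  genes <- sort(unique(c(pairs$gene_i, pairs$gene_j)))
  sig <- pairs[pairs$q_value <= alpha, , drop = FALSE]
  edges <- data.frame(from = sig$gene_i, to = sig$gene_j,
                      stringsAsFactors = FALSE)
  if ("epsilon" %in% names(sig)) edges$epsilon <- sig$epsilon
  if ("psi_hat" %in% names(sig)) edges$psi_hat <- sig$psi_hat
  edges$q_value <- sig$q_value
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = genes))
}

#' Extract non-singleton communities from the co-oscillation network
#'
#' Runs greedy modularity-maximizing community detection (the multilevel
#' algorithm, [igraph::cluster_louvain()]) separately within each connected
#' component, then drops communities containing a single gene: an isolated
#' gene has no evidence of co-oscillation with anything. The surviving
#' communities define the inferred oscillators, regardless of any further
#' per-community score. The multilevel algorithm merges through modularity
#' ties, so a fully connected clique is always returned whole.
#'
#' @param network an undirected [igraph::graph] from [build_network()].
#' @return List of communities, each a sorted character vector of genes,
#'   ordered by decreasing size with ties broken by the lexicographically
#'   first gene.
#' @export
extract_communities <- function(network) {
  check_that(igraph::is_igraph(network), "network must be an igraph graph")
  comp <- igraph::components(network)
  communities <- list()
  for (cid in seq_len(comp$no)) {
    vs <- which(comp$membership == cid)
    if (length(vs) < 2) next
    sub <- igraph::induced_subgraph(network, vs)
    cl <- igraph::cluster_louvain(igraph::simplify(sub))
    for (grp in igraph::groups(cl)) {
      if (length(grp) >= 2) communities <- c(communities, list(sort(grp)))
    }
  }
  if (length(communities) == 0) return(list())
  sizes <- vapply(communities, length, integer(1))
  first <- vapply(communities, `[`, character(1), 1)
  communities[order(-sizes, first)]
}

#' Infer oscillatory genes in one cell cluster
#'
#' The end-to-end per-cluster pipeline: zero-filter, variance-filter,
#' rescale each surviving gene to `[-1, 1]`, compute paired-sine statistics
#' for all gene pairs, assess significance against a pooled permutation null
#' with add-one p-values, adjust by Benjamini-Hochberg, build the
#' significant-pair network, extract non-singleton communities, and report
#' the union of community genes as the cluster's inferred oscillators.
#'
#' @param matrix an [expression_matrix()].
#' @param cluster cluster label to analyse.
#' @param config a [pipeline_config()]; relevant fields: `zero_threshold`,
#'   `alpha`, `n_perm`, `psi_grid_points`, `seed`, `log_transform`,
#'   `min_cells`.
#' @return An object of class `oscillator_call`: list with `cluster`,
#'   `oscillators` (sorted character vector), `communities` (list),
#'   `pair_table` (data.frame with `gene_i`, `gene_j`, `epsilon`, `psi_hat`,
#'   `p_value`, `q_value`), `network` (igraph), and `report` (one-row
#'   data.frame: `cluster`, `n_expressed`, `n_variable`, `n_oscillators`).
#' @examples
#' sim <- generate_cosc_matrix(matrix_spec(n_cells = 60, n_noise_genes = 10,
#'   groups = list(oscillator_group(n_genes = 4)), seed = 2))
#' call <- infer_oscillators(sim$matrix, "cluster1",
#'   pipeline_config(n_perm = 200, min_cells = 10, seed = 2))
#' call$oscillators
#' @export
infer_oscillators <- function(matrix, cluster, config = pipeline_config()) {
  stopifnot(inherits(matrix, "expression_matrix"))
  check_that(inherits(config, "pipeline_config"),
             "config must be created by pipeline_config()")
  cells <- cluster_cells(matrix, cluster)
  check_that(length(cells) >= config$min_cells,
             sprintf("cluster '%s' has %d cells; min_cells is %d",
                     cluster, length(cells), config$min_cells))

  vals <- matrix$values
  if (config$log_transform) {
    vals <- log2(vals + 1)
    matrix <- expression_matrix(vals, matrix$gene_ids, matrix$cell_ids,
                                matrix$clusters)
  }
  expressed <- zero_filter(matrix, cluster, config$zero_threshold)
  variable <- if (length(expressed)) {
    variance_filter(matrix, cluster, expressed)
  } else character(0)

  empty_call <- function() {
    warning(sprintf("cluster '%s': fewer than 2 genes survive filtering; %s",
                    cluster, "returning an empty call"))
    structure(list(cluster = cluster, oscillators = character(0),
                   communities = list(),
                   pair_table = data.frame(gene_i = character(0),
                                           gene_j = character(0),
                                           epsilon = numeric(0),
                                           psi_hat = numeric(0),
                                           p_value = numeric(0),
                                           q_value = numeric(0)),
                   network = NULL,
                   report = data.frame(cluster = cluster,
                                       n_expressed = length(expressed),
                                       n_variable = length(variable),
                                       n_oscillators = 0L)),
              class = "oscillator_call")
  }
  if (length(variable) < 2) return(empty_call())

  sub <- matrix$values[variable, cells, drop = FALSE]
  resc <- t(apply(sub, 1, rescale_to_unit))
  rownames(resc) <- variable

  pairs <- all_pair_statistics(resc, n_grid = config$psi_grid_points)
  null <- permutation_null(resc, n_perm = config$n_perm, seed = config$seed,
                           n_grid = config$psi_grid_points)
  pairs$p_value <- pair_pvalue(pairs$epsilon, null)
  pairs$q_value <- bh_adjust(pairs$p_value)

  net <- build_network(pairs, alpha = config$alpha)
  communities <- extract_communities(net)
  oscillators <- sort(unique(as.character(unlist(communities))))

  structure(list(cluster = cluster, oscillators = oscillators,
                 communities = communities, pair_table = pairs,
                 network = net,
                 report = data.frame(cluster = cluster,
                                     n_expressed = length(expressed),
                                     n_variable = length(variable),
                                     n_oscillators = length(oscillators))),
            class = "oscillator_call")
}

#' @export
#' @method print oscillator_call
print.oscillator_call <- function(x, ...) {
  cat(sprintf(paste0("oscillator_call for cluster '%s': ",
                     "%d expressed -> %d variable -> %d oscillators ",
                     "in %d communities\n"),
              x$cluster, x$report$n_expressed, x$report$n_variable,
              x$report$n_oscillators, length(x$communities)))
  invisible(x)
}
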