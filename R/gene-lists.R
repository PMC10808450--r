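#' Named gene set
#'
#' Symbols are whitespace-trimmed, empty entries dropped, duplicates removed
#' and the result sorted, so set operations are order-independent. Symbols
#' are compared case-sensitively by default; set `normalize_case = TRUE` to
#' uppercase human HGNC-style symbols and avoid silent mismatches between
#' differently-cased lists.
#'
#' @param name set label.
#' @param genes character vector of symbols.
#' @param normalize_case uppercase all symbols before deduplication.
#' @return An object of class `gene_set`: list with `name` and `genes`.
#' @export
gene_set <- function(name, genes, normalize_case = FALSE) {
  check_that(is.character(name) && length(name) == 1L && nzchar(name),
             "name must be a non-empty string")
  genes <- sort(unique(clean_symbols(genes, normalize_case)))
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' @export
#' @method print gene_set
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

as_symbols <- function(x) {
  if (inherits(x, "gene_set")) x$genes
  else if (is.character(x)) sort(unique(clean_symbols(x)))
  else stop("expected a gene_set or character vector", call. = FALSE)
}

## union within a tumour: an element may be a single set or a list of
## subcluster sets
element_union <- function(el) {
  if (inherits(el, "gene_set") || is.character(el)) return(as_symbols(el))
  if (is.list(el)) return(sort(unique(unlist(lapply(el, as_symbols)))))
  stop("each element must be a gene set or a list of gene sets", call. = FALSE)
}

#' Genes shared across all groups
#'
#' Each input element represents one group (e.g. one tumour); an element may
#' itself be a list of per-subcluster sets, which are unioned first. The
#' result is the intersection across groups: genes inferred in every group.
#'
#' @param per_group_oscillators list of >= 2 elements, each a [gene_set()],
#'   character vector, or list of such (unioned within the element).
#' @param name label for the result.
#' @return A [gene_set()] of the shared genes.
#' @examples
#' shared_across(list(c("A", "B", "C"), c("B", "C", "D")))$genes  # B, C
#' @export
shared_across <- function(per_group_oscillators, name = "shared") {
  check_that(is.list(per_group_oscillators) &&
               length(per_group_oscillators) >= 2,
             "need at least 2 groups to intersect")
  unions <- lapply(per_group_oscillators, element_union)
  gene_set(name, Reduce(intersect, unions))
}

#' Union of all gene sets
#'
#' @param per_group_oscillators non-empty list of gene sets (or nested lists).
#' @param name label for the result.
#' @return A deduplicated [gene_set()].
#' @export
union_all <- function(per_group_oscillators, name = "all") {
  check_that(is.list(per_group_oscillators) &&
               length(per_group_oscillators) >= 1,
             "need at least 1 set")
  gene_set(name, unlist(lapply(per_group_oscillators, element_union)))
}

#' Expressed genes never inferred to oscillate
#'
#' `(union of expressed sets) minus (union of oscillator sets)`: genes that
#' passed zero-filtering somewhere but were not called an oscillator
#' anywhere.
#'
#' @param expressed_sets,oscillator_sets lists of gene sets (or nested
#'   lists; unioned internally).
#' @param name label for the result.
#' @return A [gene_set()].
#' @export
derive_nonoscillators <- function(expressed_sets, oscillator_sets,
                                  name = "non_oscillators") {
  expressed <- if (length(expressed_sets)) {
    element_union(expressed_sets)
  } else character(0)
  oscillators <- if (length(oscillator_sets)) {
    element_union(oscillator_sets)
  } else character(0)
  gene_set(name, setdiff(expressed, oscillators))
}

#' Hypergeometric overlap between two gene sets
#'
#' Upper-tail ("at least k overlapping genes") hypergeometric probability of
#' the observed intersection, given a background universe: with
#' `N = |background|`, `K = |A|`, `n = |B|`, `k = |A intersect B|`,
#' `p = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`, evaluated through
#' [stats::phyper()] (log-space-safe). Fold enrichment is `(k/n) / (K/N)`.
#' Symbols outside the background are dropped with a warning before
#' computing.
#'
#' @param set_a,set_b gene sets or character vectors.
#' @param background the background universe (gene set or character vector;
#'   non-empty).
#' @return List of class `overlap_result`: `overlap_count`,
#'   `background_size`, `size_a`, `size_b`, `p_hypergeometric`,
#'   `fold_enrichment`.
#' @examples
#' bg <- sprintf("G%02d", 1:10)
#' hypergeometric_overlap(bg[1:5], bg[1:5], bg)$p_hypergeometric  # 1/252
#' @export
hypergeometric_overlap <- function(set_a, set_b, background) {
  bg <- as_symbols(background)
  check_that(length(bg) >= 1, "background must be non-empty")
  a <- as_symbols(set_a)
  b <- as_symbols(set_b)
  bad <- union(setdiff(a, bg), setdiff(b, bg))
  if (length(bad)) {
    warning(sprintf("%d symbol(s) outside the background dropped: %s",
                    length(bad),
                    paste(utils::head(bad, 5), collapse = ", ")))
    a <- intersect(a, bg)
    b <- intersect(b, bg)
  }
  N <- length(bg); K <- length(a); n <- length(b)
  k <- length(intersect(a, b))
  p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- if (n == 0 || K == 0) NA_real_ else (k / n) / (K / N)
  structure(list(overlap_count = k, background_size = N,
                 size_a = K, size_b = n,
                 p_hypergeometric = p, fold_enrichment = fold),
            class = "overlap_result")
}

#' @export
#' @method print overlap_result
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap %d (|A|=%d, |B|=%d, N=%d): p = %.4g, fold = %.3g\n",
              x$overlap_count, x$size_a, x$size_b, x$background_size,
              x$p_hypergeometric, x$fold_enrichment))
  invisible(x)
}

#' Fraction of a TF set involved in dynamic gene network motifs
#'
#' A dynamic gene network motif is a transcription factor that autoregulates
#' and shares a mutual-feedback interaction with a microRNA -- an
#' architecture predisposed to oscillatory expression. Only TFs for which
#' motif membership could be assessed (`evaluable_tfs`) enter the
#' denominator:
#' `100 * |tf_set  ^ motif_tfs| / |tf_set ^ evaluable_tfs|`.
#'
#' @param tf_set TFs of interest (gene set or character vector).
#' @param motif_tfs TFs known to be in a motif (must be a subset of
#'   `evaluable_tfs`).
#' @param evaluable_tfs TFs that could be assessed.
#' @return Percentage in `[0, 100]`, or `NA` when no member of `tf_set` is
#'   evaluable (missing value, not an error).
#' @export
motif_fraction <- function(tf_set, motif_tfs, evaluable_tfs) {
  tf <- as_symbols(tf_set)
  motif <- as_symbols(motif_tfs)
  evaluable <- as_symbols(evaluable_tfs)
  check_that(all(motif %in% evaluable),
             "motif_tfs must be a subset of evaluable_tfs")
  denom <- length(intersect(tf, evaluable))
  if (denom == 0) return(NA_real_)
  100 * length(intersect(tf, motif)) / denom
}

## canonical form for Hallmark-style gene-set names: strip the HALLMARK
## prefix, uppercase, collapse separators
canonical_set_name <- function(x) {
  x <- toupper(trimws(x))
  x <- sub("^HALLMARK[ _]", "", x)
  gsub("[^A-Z0-9]+", " ", x)
}

#' Classify a cell cluster as low-cycling from its enrichment table
#'
#' A cluster is called low-cycling when at least one of the cell-cycle
#' Hallmark gene sets (E2F Targets, G2M Checkpoint, Mitotic Spindle) is
#' significantly enriched among the downregulated gene sets within the top
#' `top_n` by rank. The significance cutoff defaults to adjusted p < 0.1,
#' matching the enrichment analysis the table comes from. Set names are
#' matched after canonicalization (case, separators and a `HALLMARK_` prefix
#' are ignored).
#'
#' @param records data.frame for one cluster with columns `gene_set_name`,
#'   `direction` ("up"/"down"), `adjusted_p`, `rank_within_direction`.
#' @param p_cutoff significance cutoff on `adjusted_p` (strict `<`).
#' @param top_n rank threshold (inclusive).
#' @param cell_cycle_sets the triggering gene-set names.
#' @return `TRUE` or `FALSE`.
#' @export
classify_low_cycling <- function(records, p_cutoff = 0.1, top_n = 3,
                                 cell_cycle_sets = c("E2F Targets",
                                                     "G2M Checkpoint",
                                                     "Mitotic Spindle")) {
  check_that(is.data.frame(records) &&
               all(c("gene_set_name", "direction", "adjusted_p",
                     "rank_within_direction") %in% names(records)),
             paste("records must have columns gene_set_name, direction,",
                   "adjusted_p, rank_within_direction"))
  if ("cluster" %in% names(records))
    check_that(length(unique(records$cluster)) <= 1,
               "records must belong to a single cluster")
  targets <- canonical_set_name(cell_cycle_sets)
  hit <- canonical_set_name(records$gene_set_name) %in% targets &
    tolower(records$direction) == "down" &
    records$adjusted_p < p_cutoff &
    records$rank_within_direction <= top_n
  any(hit)
}

#' Candidate quiescence regulators
#'
#' The triple intersection of the shared oscillators, a transcription-factor
#' catalogue, and a quiescent-state (Neural G0) signature: genes that
#' oscillate in every tumour, can regulate transcription, and mark the
#' quiescent-like state.
#'
#' @param shared,tf_catalogue,neural_g0 gene sets or character vectors.
#' @param name label for the result.
#' @return A [gene_set()].
#' @export
quiescence_candidates <- function(shared, tf_catalogue, neural_g0,
                                  name = "quiescence_candidates") {
  gene_set(name, Reduce(intersect, list(as_symbols(shared),
                                        as_symbols(tf_catalogue),
                                        as_symbols(neural_g0))))
}
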