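#' Pipeline configuration
#'
#' One validated bundle of every tunable the pipeline exposes. Defaults: a
#' gene must be detected in at least 80% of a cluster's cells
#' (`zero_threshold`), pair significance is controlled at FDR 0.05 over 1000
#' pooled permutations, the phase-shift grid has 1000 points, traces are
#' detrended with a 24 h window, traces shorter than 25 h are excluded, and
#' the periodogram searches periods of 2-24 h.
#'
#' @param zero_threshold detected fraction for [zero_filter()], in `(0, 1]`.
#' @param alpha FDR level for edges, in `(0, 1]`.
#' @param n_perm pooled permutation count (>= 1).
#' @param psi_grid_points phase-shift grid size (>= 10).
#' @param seed integer seed used by every stochastic stage.
#' @param log_transform apply `log2(x + 1)` to expression before filtering.
#' @param window_h detrend window (hours, > 0).
#' @param min_duration_h trace QC duration threshold (hours, > 0).
#' @param band period search band `c(min, max)` in hours.
#' @param min_cells minimum cluster size for inference.
#' @return Object of class `pipeline_config` (list).
#' @export
pipeline_config <- function(zero_threshold = 0.8, alpha = 0.05,
                            n_perm = 1000, psi_grid_points = 1000,
                            seed = 1L, log_transform = FALSE,
                            window_h = 24, min_duration_h = 25,
                            band = c(2, 24), min_cells = 20) {
  check_that(is_number(zero_threshold) && zero_threshold > 0 &&
               zero_threshold <= 1, "zero_threshold must lie in (0, 1]")
  check_that(is_number(alpha) && alpha > 0 && alpha <= 1,
             "alpha must lie in (0, 1]")
  check_that(is_count(n_perm, 1), "n_perm must be an integer >= 1")
  check_that(is_count(psi_grid_points, 10),
             "psi_grid_points must be an integer >= 10")
  check_that(is_count(seed) || is_number(seed), "seed must be an integer")
  check_that(isTRUE(log_transform) || isFALSE(log_transform),
             "log_transform must be TRUE or FALSE")
  check_that(is_number(window_h) && window_h > 0, "window_h must be > 0")
  check_that(is_number(min_duration_h) && min_duration_h > 0,
             "min_duration_h must be > 0")
  check_that(is.numeric(band) && length(band) == 2 && all(band > 0) &&
               band[1] < band[2], "band must be c(min, max) with 0 < min < max")
  check_that(is_count(min_cells, 2), "min_cells must be an integer >= 2")
  structure(list(zero_threshold = zero_threshold, alpha = alpha,
                 n_perm = as.integer(n_perm),
                 psi_grid_points = as.integer(psi_grid_points),
                 seed = as.integer(seed), log_transform = log_transform,
                 window_h = window_h, min_duration_h = min_duration_h,
                 band = band, min_cells = as.integer(min_cells)),
            class = "pipeline_config")
}

config_fields <- c("zero_threshold", "alpha", "n_perm", "psi_grid_points",
                   "seed", "log_transform", "window_h", "min_duration_h",
                   "band", "min_cells")

## canonical text serialization; also the basis of the config hash
serialize_config <- function(config) {
  vapply(config_fields, function(k) {
    v <- config[[k]]
    sprintf("%s=%s", k, paste(format(v, digits = 15), collapse = ","))
  }, character(1))
}

#' Hash of a pipeline configuration
#'
#' MD5 of the canonical key=value serialization; recorded in every run
#' output so results can be traced back to their exact configuration.
#'
#' @param config a [pipeline_config()].
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(serialize_config(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a pipeline configuration from a key=value text file
#'
#' One `key=value` per line; blank lines and `#` comments are ignored;
#' unknown keys are errors (fail fast rather than silently ignoring a
#' mistyped parameter).
#'
#' @param path config file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  check_that(file.exists(path), sprintf("missing config file: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  unknown <- setdiff(keys, config_fields)
  check_that(length(unknown) == 0,
             sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  args <- list()
  for (i in seq_along(keys)) {
    v <- trimws(strsplit(vals[i], ",", fixed = TRUE)[[1]])
    args[[keys[i]]] <- if (keys[i] == "log_transform") as.logical(v)
                       else as.numeric(v)
  }
  do.call(pipeline_config, args)
}

#' Write a pipeline configuration as a key=value text file
#'
#' @param config a [pipeline_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  writeLines(serialize_config(config), path)
  invisible(path)
}

write_stage_tsv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", hash, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full inference pipeline and write a run directory
#'
#' Simulates (when `spec` is given) or loads (when `matrix` is given) an
#' expression matrix, runs [infer_oscillators()] on every cluster with at
#' least `min_cells` cells, derives the cross-cluster shared/all/non
#' oscillator lists, and writes all stage outputs plus a machine-readable
#' manifest. Every table starts with a comment line recording the config
#' hash and seed; two runs with identical config and inputs produce
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @param matrix an [expression_matrix()], or NULL to simulate.
#' @param spec a [matrix_spec()] used when `matrix` is NULL.
#' @return Invisibly, a list with `calls` (per-cluster
#'   [infer_oscillators()] results), `report` (filter cascade data.frame),
#'   `lists` (shared/all/non-oscillator gene sets where defined) and
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         matrix = NULL, spec = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  check_that(!is.null(matrix) || !is.null(spec),
             "provide either a matrix or a synthetic spec")
  truth <- NULL
  if (is.null(matrix)) {
    check_that(inherits(spec, "synth_matrix_spec"),
               "spec must be created by matrix_spec()")
    sim <- generate_cosc_matrix(spec)
    matrix <- sim$matrix
    truth <- sim$truth
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)

  clusters <- cluster_labels(matrix)
  sizes <- table(matrix$clusters)
  run_clusters <- clusters[sizes[clusters] >= config$min_cells]
  check_that(length(run_clusters) >= 1,
             sprintf("no cluster reaches min_cells = %d", config$min_cells))

  calls <- list()
  expressed_sets <- list()
  for (cl in run_clusters) {
    call <- infer_oscillators(matrix, cl, config)
    calls[[cl]] <- call
    expressed_sets[[cl]] <- zero_filter(matrix, cl, config$zero_threshold)
    safe <- gsub("[^A-Za-z0-9._-]", "_", cl)
    write_stage_tsv(call$pair_table,
                    file.path(out_dir, sprintf("pairs_%s.tsv", safe)),
                    hash, config$seed)
    comm <- if (length(call$communities)) {
      data.frame(community_id = rep(seq_along(call$communities),
                                    lengths(call$communities)),
                 gene = unlist(call$communities))
    } else data.frame(community_id = integer(0), gene = character(0))
    write_stage_tsv(comm,
                    file.path(out_dir, sprintf("communities_%s.tsv", safe)),
                    hash, config$seed)
    write_gene_list(call$oscillators,
                    file.path(out_dir, sprintf("oscillators_%s.txt", safe)))
  }
  report <- do.call(rbind, lapply(calls, function(x) x$report))
  write_stage_tsv(report, file.path(out_dir, "filter_report.tsv"),
                  hash, config$seed)

  osc_sets <- lapply(calls, function(x) x$oscillators)
  lists <- list(all = union_all(osc_sets, name = "all_oscillators"),
                non = derive_nonoscillators(expressed_sets, osc_sets))
  if (length(run_clusters) >= 2)
    lists$shared <- shared_across(osc_sets, name = "shared_oscillators")
  write_gene_list(lists$all, file.path(out_dir, "all_oscillators.txt"))
  write_gene_list(lists$non, file.path(out_dir, "non_oscillators.txt"))
  if (!is.null(lists$shared))
    write_gene_list(lists$shared, file.path(out_dir, "shared_oscillators.txt"))

  manifest <- list(
    package = "oscinfer",
    version = as.character(utils::packageVersion("oscinfer")),
    config = stats::setNames(as.list(serialize_config(config)), NULL),
    config_hash = hash,
    seed = config$seed,
    simulated = !is.null(truth),
    clusters = lapply(calls, function(x) {
      list(cluster = x$cluster,
           n_expressed = x$report$n_expressed,
           n_variable = x$report$n_variable,
           n_oscillators = x$report$n_oscillators,
           n_communities = length(x$communities))
    }),
    n_all_oscillators = length(lists$all$genes),
    n_non_oscillators = length(lists$non$genes),
    n_shared_oscillators = if (is.null(lists$shared)) NULL
                           else length(lists$shared$genes))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(calls = calls, report = report, lists = lists,
                 manifest = manifest))
}
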