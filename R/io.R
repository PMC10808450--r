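## readers/writers for the package's file dialects

#' Read an expression matrix from MTX or dense CSV
#'
#' The MTX dialect is a directory holding `matrix.mtx` (Matrix Market
#' coordinate format, 1-based indices, genes in rows), `genes.tsv` (one
#' column `gene_id`) and `barcodes.tsv` (columns `barcode`, `cluster`). The
#' CSV dialect is a dense table with a `gene_id` first column and one column
#' per cell barcode; cluster labels then come from a companion two-column
#' TSV (`barcode`, `cluster`) passed as `clusters`.
#'
#' @param path directory (mtx dialect) or CSV file (csv dialect).
#' @param dialect `"mtx"` or `"csv"`.
#' @param clusters path to a barcode/cluster TSV (csv dialect only; when
#'   omitted all cells get cluster `"cluster1"`).
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, dialect = c("mtx", "csv"),
                                   clusters = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "mtx") {
    mtx <- file.path(path, "matrix.mtx")
    genes_f <- file.path(path, "genes.tsv")
    bc_f <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, genes_f, bc_f))
      check_that(file.exists(f), sprintf("missing input file: %s", f))
    m <- as.matrix(Matrix::readMM(mtx))
    genes <- utils::read.delim(genes_f, stringsAsFactors = FALSE)
    check_that("gene_id" %in% names(genes),
               sprintf("%s: malformed header (need column gene_id)", genes_f))
    bc <- utils::read.delim(bc_f, stringsAsFactors = FALSE)
    check_that(all(c("barcode", "cluster") %in% names(bc)),
               sprintf("%s: malformed header (need barcode, cluster)", bc_f))
    check_that(nrow(m) == nrow(genes),
               sprintf("%s: %d rows but %d gene ids", mtx, nrow(m), nrow(genes)))
    check_that(ncol(m) == nrow(bc),
               sprintf("%s: %d columns but %d barcodes", mtx, ncol(m), nrow(bc)))
    expression_matrix(m, gene_ids = genes$gene_id, cell_ids = bc$barcode,
                      clusters = bc$cluster)
  } else {
    check_that(file.exists(path), sprintf("missing input file: %s", path))
    tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    check_that(names(tab)[1] == "gene_id",
               sprintf("%s: first column must be gene_id", path))
    gid <- tab$gene_id
    dup <- which(duplicated(gid))
    check_that(length(dup) == 0,
               sprintf("%s: duplicated gene row '%s' (line %d)",
                       path, gid[dup[1]], dup[1] + 1L))
    m <- as.matrix(tab[, -1, drop = FALSE])
    cl <- "cluster1"
    if (!is.null(clusters)) {
      check_that(file.exists(clusters),
                 sprintf("missing cluster file: %s", clusters))
      bc <- utils::read.delim(clusters, stringsAsFactors = FALSE)
      check_that(all(c("barcode", "cluster") %in% names(bc)),
                 sprintf("%s: malformed header (need barcode, cluster)",
                         clusters))
      idx <- match(colnames(m), bc$barcode)
      check_that(!anyNA(idx), "cluster file does not cover every barcode")
      cl <- bc$cluster[idx]
    }
    expression_matrix(m, gene_ids = gid, cell_ids = colnames(m), clusters = cl)
  }
}

#' Write an expression matrix as an MTX triplet directory
#'
#' Writes `matrix.mtx` (Matrix Market coordinate, 1-based), `genes.tsv` and
#' `barcodes.tsv` (with the cluster column) into `dir`.
#'
#' @param matrix an [expression_matrix()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_expression_matrix <- function(matrix, dir) {
  stopifnot(inherits(matrix, "expression_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(matrix$values, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(gene_id = matrix$gene_ids),
                     file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(barcode = matrix$cell_ids,
                                cluster = unname(matrix$clusters)),
                     file.path(dir, "barcodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read gene lists from plain text or GMT
#'
#' Plain text holds one symbol per line (blank lines ignored; symbols
#' trimmed and deduplicated) and yields a single [gene_set()] named after
#' the file. GMT holds one set per line (`name TAB description TAB
#' members...`) and yields a named list of gene sets.
#'
#' @param path input file.
#' @param format `"txt"` or `"gmt"`; inferred from the extension by default.
#' @return A [gene_set()] (txt) or named list of gene sets (gmt).
#' @export
read_gene_list <- function(path, format = NULL) {
  check_that(file.exists(path), sprintf("missing input file: %s", path))
  if (is.null(format))
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "txt"
  check_that(format %in% c("txt", "gmt"), "format must be 'txt' or 'gmt'")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "txt") {
    if (length(lines) == 0) {
      warning(sprintf("%s: empty gene list", path))
      return(gene_set(tools::file_path_sans_ext(basename(path)), character(0)))
    }
    return(gene_set(tools::file_path_sans_ext(basename(path)), lines))
  }
  if (length(lines) == 0) {
    warning(sprintf("%s: empty GMT file", path))
    return(list())
  }
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    check_that(length(parts) >= 3,
               sprintf("%s: GMT line needs name, description, >= 1 member", path))
    gene_set(parts[1], parts[-(1:2)])
  })
  stats::setNames(sets, vapply(sets, function(s) s$name, character(1)))
}

#' Write a gene set as a plain-text list (one symbol per line)
#'
#' @param set a [gene_set()] or character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(set, path) {
  writeLines(as_symbols(set), path)
  invisible(path)
}

#' Read fluorescence traces from CSV
#'
#' Expects a header with at least `time_h`, `intensity`, `trace_id`;
#' `condition` and `channel` columns are carried through when present.
#'
#' @param path CSV file.
#' @return data.frame of traces.
#' @export
read_traces <- function(path) {
  check_that(file.exists(path), sprintf("missing input file: %s", path))
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_that(all(c("time_h", "intensity", "trace_id") %in% names(tr)),
             sprintf("%s: need columns time_h, intensity, trace_id", path))
  check_that(!anyNA(tr$intensity), "traces must not contain missing intensities")
  tr
}

#' Write fluorescence traces as CSV
#'
#' @param traces data.frame with at least `time_h`, `intensity`, `trace_id`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
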