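#' Construct a validated spot-by-gene count matrix
#'
#' The package stores counts with spots in rows and genes in columns. All
#' entries must be non-negative integers and both spot and gene identifiers
#' must be unique.
#'
#' @param counts Numeric matrix of counts, spots in rows, genes in columns.
#' @param spot_ids Character vector of spot identifiers (defaults to rownames).
#' @param gene_ids Character vector of gene identifiers (defaults to colnames).
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix with dimnames), `spot_ids` and `gene_ids`.
#' @export
count_matrix <- function(counts, spot_ids = rownames(counts),
                         gene_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  spot_ids <- as.character(spot_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("count matrix must have at least one spot and one gene")
  if (length(spot_ids) != nrow(counts) || length(gene_ids) != ncol(counts))
    stop("identifier length does not match matrix dimensions")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(counts))
    stop(sprintf(
      "invalid count at spot '%s' (row %d), gene '%s' (column %d): %s",
      spot_ids[ij[1]], ij[1], gene_ids[ij[2]], ij[2],
      format(counts[bad[1L]])))
  }
  if (anyDuplicated(spot_ids))
    stop("duplicate spot ids: ",
         paste(unique(spot_ids[duplicated(spot_ids)]), collapse = ", "))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(spot_ids, gene_ids)
  structure(list(counts = counts, spot_ids = spot_ids, gene_ids = gene_ids),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d spots x %d genes, %.1f%% non-zero\n",
              nrow(x$counts), ncol(x$counts),
              100 * mean(x$counts > 0)))
  invisible(x)
}

#' Read a spot-by-gene count matrix from disk
#'
#' Supported formats are dense CSV/TSV (spot ids in the first column, gene
#' ids in the header) and Matrix Market triplets with barcode/feature sidecar
#' files (10x-style, genes x spots on disk; orientation is auto-detected from
#' the sidecar lengths).
#'
#' @param path Path to the matrix file.
#' @param format One of `"auto"`, `"csv"`, `"tsv"`, `"mtx"`. `"auto"` infers
#'   from the file extension.
#' @param spots_in For dense formats, whether spots are in `"rows"` (default)
#'   or `"cols"` of the file.
#' @param barcodes,features For MTX input, paths to the spot-id and gene-id
#'   sidecar files. Default to `barcodes.tsv` / `features.tsv` (or
#'   `genes.tsv`) next to the matrix file.
#' @return A [count_matrix].
#' @export
read_count_matrix <- function(path,
                              format = c("auto", "csv", "tsv", "mtx"),
                              spots_in = c("rows", "cols"),
                              barcodes = NULL, features = NULL) {
  format <- match.arg(format)
  spots_in <- match.arg(spots_in)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
      h5 = , h5ad = stop("HDF5/AnnData input is not supported; ",
                         "export counts as MTX or CSV/TSV"),
      stop("cannot infer format from extension '.", ext,
           "'; pass format= explicitly"))
  }
  if (format == "mtx") {
    dir <- dirname(path)
    if (is.null(barcodes)) barcodes <- .first_existing(
      file.path(dir, c("barcodes.tsv", "barcodes.txt")))
    if (is.null(features)) features <- .first_existing(
      file.path(dir, c("features.tsv", "genes.tsv", "features.txt")))
    if (is.null(barcodes) || is.null(features))
      stop("MTX input requires barcode and feature sidecar files")
    m <- as.matrix(Matrix::readMM(path))
    bc <- utils::read.table(barcodes, sep = "\t",
                            stringsAsFactors = FALSE)[[1L]]
    ft <- utils::read.table(features, sep = "\t",
                            stringsAsFactors = FALSE)[[1L]]
    # 10x convention stores genes x spots; accept either orientation,
    # resolved by matching sidecar lengths against the matrix dimensions.
    if (nrow(m) == length(ft) && ncol(m) == length(bc)) {
      m <- t(m)
    } else if (!(nrow(m) == length(bc) && ncol(m) == length(ft))) {
      stop(sprintf(paste0(
        "sidecar lengths (%d barcodes, %d features) do not match matrix ",
        "dimensions %d x %d"), length(bc), length(ft), nrow(m), ncol(m)))
    }
    return(count_matrix(m, spot_ids = bc, gene_ids = ft))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (spots_in == "cols") m <- t(m)
  count_matrix(m)
}

.first_existing <- function(paths) {
  hit <- paths[file.exists(paths)]
  if (length(hit)) hit[[1L]] else NULL
}

#' Write a count matrix as Matrix Market triplets with sidecars
#'
#' Writes `matrix.mtx`, `barcodes.tsv` and `features.tsv` under `dir`, in the
#' genes-x-spots orientation used by 10x-style tools.
#'
#' @param cm A [count_matrix].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path to the `.mtx` file.
#' @export
write_count_matrix_mtx <- function(cm, dir) {
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mm <- Matrix::Matrix(t(cm$counts), sparse = TRUE)
  p <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(mm, p)
  writeLines(cm$spot_ids, file.path(dir, "barcodes.tsv"))
  writeLines(cm$gene_ids, file.path(dir, "features.tsv"))
  invisible(p)
}

#' Read per-spot metadata
#'
#' The table must contain columns `spot_id`, `x`, `y` and `cluster`; a
#' `sample` column is optional. Cluster and sample levels are ordered by
#' first appearance in the file, which fixes coefficient ordering downstream.
#'
#' @param path Path to a CSV or TSV file (separator inferred from extension,
#'   default tab).
#' @return A `spot_table`: a data.frame with the columns above, `cluster`
#'   (and `sample`, if present) as factors.
#' @export
read_spot_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  spot_table(df)
}

#' Construct a validated spot metadata table
#'
#' @param df A data.frame with columns `spot_id`, `x`, `y`, `cluster` and
#'   optionally `sample`.
#' @return A `spot_table` data.frame.
#' @export
spot_table <- function(df) {
  need <- c("spot_id", "x", "y", "cluster")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  df$spot_id <- as.character(df$spot_id)
  if (anyDuplicated(df$spot_id))
    stop("duplicate spot ids in metadata: ",
         paste(unique(df$spot_id[duplicated(df$spot_id)]), collapse = ", "))
  for (col in c("x", "y")) {
    if (!is.numeric(df[[col]]) || any(!is.finite(df[[col]])))
      stop("non-finite values in coordinate column '", col, "'")
  }
  df$cluster <- factor(as.character(df$cluster),
                       levels = unique(as.character(df$cluster)))
  if ("sample" %in% names(df))
    df$sample <- factor(as.character(df$sample),
                        levels = unique(as.character(df$sample)))
  class(df) <- c("spot_table", "data.frame")
  df
}

#' Align a count matrix and a spot table
#'
#' Enforces that both objects describe the same spots, reorders the metadata
#' to the count-matrix spot order, and drops spots whose cluster label is
#' missing (with a warning). Cluster levels left empty after alignment are
#' an error.
#'
#' @param cm A [count_matrix].
#' @param spots A `spot_table`.
#' @return A list with the aligned `counts` and `spots`.
#' @export
align_spots <- function(cm, spots) {
  stopifnot(inherits(cm, "count_matrix"), inherits(spots, "spot_table"))
  na_cl <- is.na(spots$cluster)
  if (any(na_cl)) {
    warning(sum(na_cl), " spot(s) dropped: missing cluster label")
    spots <- spots[!na_cl, , drop = FALSE]
  }
  only_cm <- setdiff(cm$spot_ids, spots$spot_id)
  only_meta <- setdiff(spots$spot_id, cm$spot_ids)
  if (length(only_cm) || length(only_meta)) {
    stop("spot ids do not match between counts and metadata; ",
         "only in counts: {", paste(utils::head(only_cm, 5), collapse = ", "),
         "}; only in metadata: {",
         paste(utils::head(only_meta, 5), collapse = ", "), "}")
  }
  spots <- spots[match(cm$spot_ids, spots$spot_id), , drop = FALSE]
  rownames(spots) <- NULL
  empty <- setdiff(levels(spots$cluster), unique(as.character(spots$cluster)))
  if (length(empty))
    stop("cluster level(s) empty after alignment: ",
         paste(empty, collapse = ", "))
  list(counts = cm, spots = spots)
}

#' Write an SVG test results table as TSV
#'
#' Rows are ordered by ascending p-value with ties broken by gene id;
#' NA p-values sort last.
#'
#' @param results A results data.frame as returned by [test_global()] or
#'   [test_cluster()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results), "gene_id" %in% names(results),
            "pvalue" %in% names(results))
  ord <- order(results$pvalue, results$gene_id, na.last = TRUE)
  out <- results[ord, , drop = FALSE]
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write results to '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read back a results TSV written by [write_results()]
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the stored columns.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  df$gene_id <- as.character(df$gene_id)
  df
}
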