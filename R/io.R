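# Readers and writers for the plain-text formats the pipeline consumes:
# expression/exon TSV (first column = identifier), MatrixMarket counts with
# sidecar row/column name files, GMT gene sets, survival TSV, BED intervals,
# edge tables and planted-truth JSON.

#' Read a genes x samples expression (or exon) matrix from TSV
#'
#' The first column holds identifiers; remaining columns are samples.
#' Duplicate identifiers and missing values are rejected.
#'
#' @param path TSV file path.
#' @return numeric matrix with identifier rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate identifiers in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(m)) stop("missing values in ", path, "; imputation is not done")
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a matrix as identifier-first-column TSV
#'
#' @param m matrix with rownames.
#' @param path output path.
#' @param id_name header of the identifier column.
#' @export
write_expression_tsv <- function(m, path, id_name = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a MatrixMarket count matrix with sidecar name files
#'
#' @param mtx_path `.mtx` file; `rows_path`, `cols_path` one-id-per-line
#'   text files for row and column names.
#' @param rows_path,cols_path name files.
#' @return dense numeric matrix with dimnames.
#' @export
read_counts_mtx <- function(mtx_path, rows_path, cols_path) {
  m <- as.matrix(Matrix::readMM(mtx_path))
  rownames(m) <- readLines(rows_path)
  colnames(m) <- readLines(cols_path)
  m
}

#' Write a count matrix as MatrixMarket plus name files
#'
#' @param m matrix.
#' @param mtx_path,rows_path,cols_path output paths.
#' @export
write_counts_mtx <- function(m, mtx_path, rows_path, cols_path) {
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), mtx_path)
  writeLines(rownames(m), rows_path)
  writeLines(colnames(m), cols_path)
  invisible(NULL)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Write regulons (or any named gene sets) to GMT
#'
#' @param sets named list of character vectors (e.g. TF -> targets).
#' @param path output path.
#' @param description per-set description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "regplast") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
}

#' Read a survival table (sample, time, event) from TSV
#'
#' @param path TSV with columns `sample`, `time`, `event`; extra columns are
#'   kept as covariates.
#' @return data.frame; times must be positive and events 0/1.
#' @export
read_survival_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "time", "event") %in% names(df)))
  if (any(df$time <= 0)) stop("non-positive survival times in ", path)
  if (!all(df$event %in% c(0, 1))) stop("event flags must be 0/1 in ", path)
  df
}

#' Read BED intervals as 0-based half-open data.frame
#'
#' @param path BED file path.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open), sorted
#'   within chromosome.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

#' Write an edge table as TSV
#'
#' @param edges `edge_table` data.frame.
#' @param path output path.
#' @export
write_edge_table <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read an edge table TSV
#'
#' @param path TSV with columns regulator, target, importance.
#' @return `edge_table`, sorted by importance descending.
#' @export
read_edge_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("regulator", "target", "importance") %in% names(df)))
  sort_edges(df)
}

#' Write a planted network truth as JSON
#'
#' @param truth `planted_network`.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write truth JSON")
  obj <- list(tf_ids = truth$tf_ids, target_map = truth$target_map,
              edge_weights = truth$edge_weights,
              cluster_of_tf = as.list(truth$cluster_of_tf),
              role_of_gene = as.list(truth$role_of_gene))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}
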