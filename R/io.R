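#' Read a genes-by-cells count matrix
#'
#' Supports delimited text (genes as rows, header row of cell ids, first
#' column of gene ids) and Matrix Market, where `path` is the `.mtx` file and
#' sidecar files hold one gene name per line and one cell name per line.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"mtx"`.
#' @param genes_path,cells_path Sidecar name files, required for `"mtx"`
#'   (default: `<path>.genes.txt`, `<path>.cells.txt` next to the matrix).
#' @return Validated integer matrix, genes as rows.
#' @export
read_counts <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                        genes_path = NULL, cells_path = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot infer format from extension: ", path, call. = FALSE))
  }
  if (format == "mtx") {
    if (is.null(genes_path)) genes_path <- paste0(path, ".genes.txt")
    if (is.null(cells_path)) cells_path <- paste0(path, ".cells.txt")
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
    if (length(genes) != nrow(m) || length(cells) != ncol(m)) {
      stop(sprintf(
        "sidecar length mismatch: %d genes / %d rows, %d cells / %d cols",
        length(genes), nrow(m), length(cells), ncol(m)), call. = FALSE)
    }
    dimnames(m) <- list(genes, cells)
  } else {
    delim <- if (format == "csv") "," else "\t"
    df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
  }
  storage.mode(m) <- "integer"
  validate_counts(m)
  m
}

#' Write a count matrix
#'
#' @param counts Genes-by-cells matrix.
#' @param path Output file; `.csv`, `.tsv` or `.mtx` (with sidecar name
#'   files as in [read_counts()]).
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".genes.txt"))
    writeLines(colnames(counts), paste0(path, ".cells.txt"))
  } else {
    delim <- if (ext == "csv") "," else "\t"
    df <- tibble::as_tibble(counts, rownames = "gene")
    readr::write_delim(df, path, delim = delim)
  }
  invisible(path)
}

#' Write a ternary (or binary) state matrix as TSV
#'
#' Missing calls are written as the literal string `NA`.
#'
#' @param ternary Genes-by-cells matrix.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_ternary <- function(ternary, path) {
  df <- tibble::as_tibble(ternary, rownames = "gene")
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}

#' Read a ternary state matrix written by [write_ternary()]
#'
#' @param path TSV file.
#' @return Integer matrix with `NA` where the file says NA.
#' @export
read_ternary <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "integer"
  m
}

#' Read a gene list (one symbol per line)
#'
#' Stands in for externally curated gene subsets (e.g. an ontology-derived
#' olfactory list); blank lines and leading/trailing whitespace are dropped.
#'
#' @param path Text file.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Read cell-to-dataset labels
#'
#' Two-column TSV (cell, dataset), with or without a header line named
#' `cell`/`dataset`.
#'
#' @param path TSV file.
#' @return Named character vector of dataset labels, names = cell ids.
#' @export
read_cell_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("cell", "dataset"),
                          colClasses = "character")
  if (df$cell[1] == "cell" && df$dataset[1] == "dataset") df <- df[-1, ]
  stats::setNames(df$dataset, df$cell)
}
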