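#' Validate a genes-by-cells count matrix
#'
#' Checks the container contract used throughout the package: a numeric
#' matrix of non-negative integers with unique, non-empty gene (row) and
#' cell (column) names.
#'
#' @param counts Numeric matrix, genes as rows, cells as columns, with
#'   `rownames` (gene ids) and `colnames` (cell ids).
#' @return `counts`, invisibly, after validation.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix (genes x cells)", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have rownames (gene ids) and colnames (cell ids)", call. = FALSE)
  }
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g) > 0) {
    stop("duplicate gene ids: ", paste(utils::head(dup_g, 5), collapse = ", "), call. = FALSE)
  }
  dup_c <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_c) > 0) {
    stop("duplicate cell ids: ", paste(utils::head(dup_c, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "counts must be non-negative integers; first offender at gene '%s', cell '%s' (value %g)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      counts[bad[1, 1], bad[1, 2]]
    ), call. = FALSE)
  }
  invisible(counts)
}

#' Transform raw counts to log2 counts-per-million
#'
#' Computes `y_ij = log2(1 + 1e6 * r_ij / sum_k r_kj)`, the shifted-log CPM
#' transform on which all mixture modelling in this package operates. A zero
#' count maps exactly to zero, so the zero pattern of the count matrix is
#' preserved.
#'
#' @param counts Genes-by-cells matrix of non-negative integer counts with
#'   gene ids as rownames and cell ids as colnames.
#' @return A numeric matrix of the same shape and dimnames with non-negative
#'   log2CPM values.
#' @examples
#' counts <- matrix(c(0, 0, 4, 1, 1, 2), nrow = 3,
#'                  dimnames = list(paste0("g", 1:3), c("c1", "c2")))
#' log2cpm(counts)
#' @export
log2cpm <- function(counts) {
  validate_counts(counts)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("cells with zero total count: ",
         paste(utils::head(colnames(counts)[totals == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  log2(1 + sweep(counts, 2, totals, "/") * 1e6)
}
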