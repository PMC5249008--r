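#' Collapse ternary states to binary activity
#'
#' A gene is "active" in a cell when it was classified to the high (normal)
#' component: ternary 2 maps to 1, ternary 0 or 1 to 0. `NA` entries are
#' treated as inactive under the default `"zero"` policy (conservative), or
#' propagated as `NA` under `"drop"` so callers can exclude them.
#'
#' @param ternary Genes-by-cells matrix with entries in `{0, 1, 2, NA}`, or a
#'   `ternary_result`.
#' @param na_policy `"zero"` (default) or `"drop"`.
#' @return Integer matrix of the same shape with entries in `{0, 1}` (and
#'   `NA` under `"drop"`).
#' @export
binarize <- function(ternary, na_policy = c("zero", "drop")) {
  na_policy <- match.arg(na_policy)
  if (inherits(ternary, "ternary_result")) ternary <- ternary$ternary
  out <- ifelse(ternary == 2L, 1L, 0L)
  if (na_policy == "zero") out[is.na(out)] <- 0L
  dimnames(out) <- dimnames(ternary)
  out
}

#' Partition cells into mature / immature / excluded by anchor markers
#'
#' A cell is mature when the mature anchor (default OMP) is active and the
#' immature anchor (default GAP43) is not; immature in the mirror case. Cells
#' active for both or for neither are excluded from marker testing.
#'
#' @param binary Genes-by-cells binary activity matrix.
#' @param mature_marker,immature_marker Gene ids of the anchors; must be
#'   present among the rownames (matching is exact).
#' @return List of class `maturity_groups` with character vectors
#'   `mature_cells`, `immature_cells`, `excluded_cells` (a partition of all
#'   cells) and the marker names.
#' @export
define_maturity_groups <- function(binary, mature_marker = "OMP",
                                   immature_marker = "GAP43") {
  for (mk in c(mature_marker, immature_marker)) {
    if (!mk %in% rownames(binary)) {
      stop("marker gene not found in matrix: ", mk, call. = FALSE)
    }
  }
  mat <- binary[mature_marker, ] == 1
  imm <- binary[immature_marker, ] == 1
  mat[is.na(mat)] <- FALSE
  imm[is.na(imm)] <- FALSE
  cells <- colnames(binary)
  structure(
    list(mature_cells = cells[mat & !imm],
         immature_cells = cells[imm & !mat],
         excluded_cells = cells[!(xor(mat, imm))],
         mature_marker = mature_marker,
         immature_marker = immature_marker),
    class = "maturity_groups"
  )
}

#' @exportS3Method base::print
print.maturity_groups <- function(x, ...) {
  cat(sprintf("Maturity groups (%s+ / %s+): %d mature, %d immature, %d excluded\n",
              x$mature_marker, x$immature_marker,
              length(x$mature_cells), length(x$immature_cells),
              length(x$excluded_cells)))
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on the margins, sums the hypergeometric probabilities of all
#' tables as or less probable than the observed one (the minimum-likelihood
#' two-sided convention, with a 1e-7 relative slack for floating-point ties).
#' The odds ratio is the sample `ad/bc`, with `Inf`/0 for zero cells.
#'
#' @param table 2x2 matrix of non-negative integer counts (rows = groups,
#'   columns = active/inactive).
#' @return List with `odds_ratio`, `p_value`, and `degenerate` (TRUE when a
#'   margin is zero, in which case `p_value` is 1 and the odds ratio `NA`).
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2))
  if (any(table < 0) || any(table != round(table))) {
    stop("table must contain non-negative integers", call. = FALSE)
  }
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  m <- a + c      # first-column margin
  n_marg <- b + d # second-column margin
  k <- a + b      # first-row margin
  if (m == 0 || n_marg == 0 || k == 0 || c + d == 0) {
    return(list(odds_ratio = NA_real_, p_value = 1, degenerate = TRUE))
  }
  support <- max(0, k - n_marg):min(k, m)
  probs <- stats::dhyper(support, m, n_marg, k)
  p_obs <- stats::dhyper(a, m, n_marg, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (b == 0 && c == 0) {
    Inf
  } else if (a == 0 && d == 0) {
    0
  } else if (b * c == 0) {
    Inf
  } else {
    (a * d) / (b * c)
  }
  list(odds_ratio = or, p_value = p, degenerate = FALSE)
}

#' Scan all genes for coactivation with the maturity anchors
#'
#' For every gene in the test universe (anchors excluded), tabulates active
#' vs inactive cells in the mature and immature groups, applies
#' [fisher_exact_2x2()], and Bonferroni-corrects over the number of genes
#' actually tested. A gene is significant when its corrected p-value is below
#' `alpha`; its direction is mature-associated when the active fraction is
#' higher among mature cells.
#'
#' @param binary Genes-by-cells binary activity matrix.
#' @param groups A `maturity_groups` from [define_maturity_groups()].
#' @param alpha Significance level on the Bonferroni-corrected p, default 0.01.
#' @param test_universe Optional character vector of gene ids to test
#'   (default: all genes in `binary`); anchors are always dropped.
#' @param bonferroni_n Optional explicit Bonferroni factor (e.g. the full
#'   transcriptome size); default is the number of genes tested.
#' @return Tibble with one row per tested gene: `gene`, the 2x2 counts
#'   `n_mature_active`, `n_mature_inactive`, `n_immature_active`,
#'   `n_immature_inactive`, `odds_ratio`, `p_value`, `p_bonferroni`,
#'   `direction`, `significant`, sorted by `p_value`.
#' @export
marker_coactivation_scan <- function(binary, groups, alpha = 0.01,
                                     test_universe = NULL,
                                     bonferroni_n = NULL) {
  stopifnot(inherits(groups, "maturity_groups"))
  if (length(groups$mature_cells) == 0 || length(groups$immature_cells) == 0) {
    stop("both maturity groups must be non-empty", call. = FALSE)
  }
  universe <- if (is.null(test_universe)) rownames(binary) else test_universe
  missing <- setdiff(universe, rownames(binary))
  if (length(missing) > 0) {
    stop("universe genes absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  universe <- setdiff(universe, c(groups$mature_marker, groups$immature_marker))
  if (length(universe) == 0) stop("empty test universe", call. = FALSE)
  n_tests <- if (is.null(bonferroni_n)) length(universe) else bonferroni_n

  mat_block <- binary[universe, groups$mature_cells, drop = FALSE]
  imm_block <- binary[universe, groups$immature_cells, drop = FALSE]
  n_mat <- length(groups$mature_cells)
  n_imm <- length(groups$immature_cells)
  a <- rowSums(mat_block == 1, na.rm = TRUE)
  c_ <- rowSums(imm_block == 1, na.rm = TRUE)

  res <- purrr::map(seq_along(universe), function(i) {
    tab <- matrix(c(a[i], n_mat - a[i], c_[i], n_imm - c_[i]),
                  nrow = 2, byrow = TRUE)
    ft <- fisher_exact_2x2(tab)
    tibble::tibble(
      gene = universe[i],
      n_mature_active = a[[i]], n_mature_inactive = n_mat - a[[i]],
      n_immature_active = c_[[i]], n_immature_inactive = n_imm - c_[[i]],
      odds_ratio = ft$odds_ratio, p_value = ft$p_value
    )
  })
  out <- dplyr::bind_rows(res)
  out <- dplyr::mutate(
    out,
    p_bonferroni = pmin(1, .data$p_value * n_tests),
    direction = dplyr::case_when(
      .data$n_mature_active / n_mat > .data$n_immature_active / n_imm ~ "mature-associated",
      .data$n_mature_active / n_mat < .data$n_immature_active / n_imm ~ "immature-associated",
      TRUE ~ NA_character_
    ),
    significant = .data$p_bonferroni < alpha
  )
  dplyr::arrange(out, .data$p_value)
}

#' Leave-one-out k-nearest-neighbour accuracy on dataset labels
#'
#' Measures how well cells can be re-attributed to their dataset of origin:
#' each cell is classified by the majority label among its k nearest
#' neighbours (Euclidean distance) with itself held out. Lower accuracy means
#' better cross-dataset mixing. Ties are resolved deterministically:
#' neighbours tied in distance are taken in cell order, and vote ties go to
#' the label encountered first in cell order among the tied neighbours.
#'
#' @param features Genes-by-cells matrix (binary or continuous); cells are
#'   the classified units.
#' @param dataset_labels Vector of labels, one per cell (at least 2 classes).
#' @param k Number of neighbours, default 5; must satisfy `k < n cells`.
#' @return Accuracy in `[0, 1]`.
#' @export
knn_loocv_dataset_accuracy <- function(features, dataset_labels, k = 5L) {
  n <- ncol(features)
  stopifnot(length(dataset_labels) == n)
  if (length(unique(dataset_labels)) < 2) {
    stop("need at least 2 label classes", call. = FALSE)
  }
  if (k >= n) stop("k must be smaller than the number of cells", call. = FALSE)
  d <- as.matrix(stats::dist(t(features)))
  correct <- vapply(seq_len(n), function(i) {
    dd <- d[i, -i]
    nb <- order(dd)[seq_len(k)]  # order() breaks distance ties by position
    votes <- dataset_labels[-i][nb]
    tab <- table(factor(votes, levels = unique(votes)))
    pred <- names(tab)[which.max(tab)]  # vote ties -> first-encountered label
    pred == dataset_labels[i]
  }, logical(1))
  mean(correct)
}
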