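#' Population prevalence of every coactive gene pair
#'
#' For each unordered gene pair, the fraction of all cells in which both
#' genes are active. Pairs never co-active have prevalence 0 (stored
#' implicitly). Self-pairs are excluded (simple-graph convention).
#'
#' @param binary Genes-by-cells binary activity matrix.
#' @return Object of class `edge_prevalence`: list with `counts` (sparse
#'   symmetric genes-by-genes co-activity count matrix, zero diagonal) and
#'   `n_cells`.
#' @export
edge_prevalence <- function(binary) {
  stopifnot(ncol(binary) >= 1)
  b <- binary
  b[is.na(b)] <- 0L
  bs <- Matrix::Matrix(b, sparse = TRUE)
  co <- Matrix::tcrossprod(bs)
  diag(co) <- 0
  structure(list(counts = co, n_cells = ncol(binary)), class = "edge_prevalence")
}

#' @exportS3Method base::print
print.edge_prevalence <- function(x, ...) {
  n_pairs <- (Matrix::nnzero(x$counts)) / 2
  cat(sprintf("Edge prevalence over %d cells: %d gene pairs ever co-active\n",
              x$n_cells, as.integer(n_pairs)))
  invisible(x)
}

#' Edge-prevalence summary as a tibble
#'
#' @param prevalence An `edge_prevalence` object.
#' @return Tibble with `gene_a`, `gene_b`, `n_coactive`, `prevalence` for
#'   every pair co-active in at least one cell (`gene_a` < `gene_b`).
#' @export
tidy_edge_prevalence <- function(prevalence) {
  co <- methods::as(methods::as(prevalence$counts, "generalMatrix"), "TsparseMatrix")
  keep <- co@i < co@j & co@x > 0
  tibble::tibble(
    gene_a = rownames(co)[co@i[keep] + 1L],
    gene_b = rownames(co)[co@j[keep] + 1L],
    n_coactive = co@x[keep],
    prevalence = co@x[keep] / prevalence$n_cells
  )
}

#' Build one cell's uniqueness-filtered coactivation network
#'
#' Nodes are the genes active in the cell; before filtering, the network is
#' the complete graph on them (`choose(N, 2)` edges). An edge is removed when
#' its population prevalence exceeds the threshold strictly (removal requires
#' "more than" threshold; an edge exactly at it is kept). Isolated nodes are
#' retained.
#'
#' @param binary Genes-by-cells binary activity matrix.
#' @param cell Cell id (a colname of `binary`).
#' @param prevalence An [edge_prevalence()] summary over the whole population.
#' @param threshold Prevalence cutoff in `(0, 1]`, default 0.01.
#' @return Object of class `cell_network`: list with `cell`, `nodes`,
#'   `edges` (two-column character matrix), `centralization`, `group`.
#' @export
build_cell_network <- function(binary, cell, prevalence, threshold = 0.01) {
  stopifnot(threshold > 0, threshold <= 1, cell %in% colnames(binary))
  act <- binary[, cell]
  nodes <- rownames(binary)[!is.na(act) & act == 1]
  n <- length(nodes)
  if (n >= 2) {
    idx <- match(nodes, rownames(prevalence$counts))
    co <- as.matrix(prevalence$counts[idx, idx, drop = FALSE]) / prevalence$n_cells
    keep <- which(upper.tri(co) & co <= threshold, arr.ind = TRUE)
    edges <- cbind(nodes[keep[, 1]], nodes[keep[, 2]])
  } else {
    edges <- matrix(character(0), ncol = 2)
  }
  colnames(edges) <- c("gene_a", "gene_b")
  net <- structure(list(cell = cell, nodes = nodes, edges = edges,
                        centralization = NA_real_, group = "other"),
                   class = "cell_network")
  net$centralization <- degree_centralization(net)
  net
}

#' @exportS3Method base::print
print.cell_network <- function(x, ...) {
  cat(sprintf("Cell network '%s': %d nodes, %d edges, centralization %s (group %s)\n",
              x$cell, length(x$nodes), nrow(x$edges),
              ifelse(is.na(x$centralization), "undefined",
                     sprintf("%.3f", x$centralization)), x$group))
  invisible(x)
}

#' Freeman degree centralization of a cell network
#'
#' `C = sum_i (d_max - d_i) / ((N - 1)(N - 2))` over the network's `N` nodes
#' with degrees `d_i`. 1 for a star, 0 for any degree-regular graph (e.g. a
#' complete graph). Isolated nodes count toward `N`. Undefined (NA) for
#' `N < 3`; such networks are excluded downstream.
#'
#' @param network A `cell_network`, or a list with `nodes` and `edges`.
#' @return Centralization in `[0, 1]`, or `NA` when `N < 3`.
#' @export
degree_centralization <- function(network) {
  nodes <- network$nodes
  n <- length(nodes)
  if (n < 3) return(NA_real_)
  deg <- stats::setNames(integer(n), nodes)
  if (nrow(network$edges) > 0) {
    t1 <- table(network$edges[, 1])
    t2 <- table(network$edges[, 2])
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  sum(max(deg) - deg) / ((n - 1) * (n - 2))
}

#' Build the networks of all cells and summarize them
#'
#' @param binary Genes-by-cells binary activity matrix.
#' @param prevalence An [edge_prevalence()]; computed from `binary` if NULL.
#' @param threshold Prevalence cutoff, default 0.01.
#' @param groups Optional `maturity_groups`; stamps each network's `group`.
#' @return Tibble with one row per cell: `cell`, `group`, `n_nodes`,
#'   `n_edges`, `centralization`, and a list-column `network` of
#'   `cell_network` objects.
#' @export
build_cell_networks <- function(binary, prevalence = NULL, threshold = 0.01,
                                groups = NULL) {
  if (is.null(prevalence)) prevalence <- edge_prevalence(binary)
  nets <- purrr::map(colnames(binary), function(cl) {
    net <- build_cell_network(binary, cl, prevalence, threshold)
    if (!is.null(groups)) {
      net$group <- if (cl %in% groups$mature_cells) {
        "mature"
      } else if (cl %in% groups$immature_cells) {
        "immature"
      } else {
        "other"
      }
    }
    net
  })
  tibble::tibble(
    cell = colnames(binary),
    group = purrr::map_chr(nets, "group"),
    n_nodes = purrr::map_int(nets, ~ length(.x$nodes)),
    n_edges = purrr::map_int(nets, ~ nrow(.x$edges)),
    centralization = purrr::map_dbl(nets, "centralization"),
    network = nets
  )
}

#' Compare centralization between mature and immature cell networks
#'
#' For each prevalence threshold, rebuilds every cell's network, keeps
#' non-trivial networks with at least `min_nodes` nodes (and a defined
#' centralization), and runs a two-sided two-sample t-test on centralization
#' between the mature and immature groups.
#'
#' @param binary Genes-by-cells binary activity matrix.
#' @param groups A `maturity_groups`.
#' @param thresholds Prevalence cutoffs, default
#'   `c(0.005, 0.01, 0.02, 0.03, 0.04, 0.05)`.
#' @param min_nodes Minimum network size, default 5.
#' @param pooled Use the pooled-variance t-test instead of Welch, default
#'   FALSE.
#' @param prevalence Optional precomputed [edge_prevalence()].
#' @return Tibble with one row per threshold: `threshold`, `n_mature`,
#'   `n_immature`, `mean_mature`, `mean_immature`, `t_statistic`, `p_value`,
#'   `available` (FALSE when a group has fewer than 2 eligible networks).
#' @export
compare_group_centralization <- function(binary, groups,
                                         thresholds = c(0.005, 0.01, 0.02, 0.03, 0.04, 0.05),
                                         min_nodes = 5L, pooled = FALSE,
                                         prevalence = NULL) {
  stopifnot(inherits(groups, "maturity_groups"))
  if (is.null(prevalence)) prevalence <- edge_prevalence(binary)
  purrr::map_dfr(thresholds, function(th) {
    nets <- build_cell_networks(binary, prevalence, th, groups)
    elig <- dplyr::filter(nets, .data$n_nodes >= min_nodes,
                          !is.na(.data$centralization),
                          .data$group %in% c("mature", "immature"))
    cm <- elig$centralization[elig$group == "mature"]
    ci <- elig$centralization[elig$group == "immature"]
    if (length(cm) < 2 || length(ci) < 2) {
      return(tibble::tibble(threshold = th, n_mature = length(cm),
                            n_immature = length(ci),
                            mean_mature = mean(cm), mean_immature = mean(ci),
                            t_statistic = NA_real_, p_value = NA_real_,
                            available = FALSE))
    }
    # essentially-constant groups with equal means are a no-difference result
    tt <- tryCatch(stats::t.test(cm, ci, alternative = "two.sided", var.equal = pooled),
                   error = function(e) NULL)
    if (is.null(tt)) {
      tstat <- if (isTRUE(all.equal(mean(cm), mean(ci)))) 0 else NA_real_
      pval <- if (is.na(tstat)) NA_real_ else 1
    } else {
      tstat <- unname(tt$statistic)
      pval <- tt$p.value
    }
    tibble::tibble(threshold = th, n_mature = length(cm), n_immature = length(ci),
                   mean_mature = mean(cm), mean_immature = mean(ci),
                   t_statistic = tstat, p_value = pval,
                   available = TRUE)
  })
}
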