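#' Specification of a synthetic scRNA-seq dataset with known truth
#'
#' Defines the generative model the package's own mixture framework assumes:
#' per gene, a cell's log2CPM value is zero with probability `zero_prob`,
#' otherwise drawn from the high (normal) component with probability `rho`
#' or from the low (gamma) component. An optional marker plan overwrites the
#' activity of two mutually exclusive anchor genes and of planted
#' marker genes whose activity tracks cell maturity; an optional network plan
#' inserts per-cell private genes that create star-shaped unique-coactivation
#' topologies.
#'
#' Per-gene parameters recycle over genes. Defaults describe a
#' well-separated bimodal gene: low component Gamma(shape 2, rate 2) (mean 1
#' log2CPM), high component Normal(mean 8, sd 1), mixing weight 0.4, zero
#' probability 0.4.
#'
#' @param n_genes,n_cells Dimensions of the dataset.
#' @param zero_prob Per-gene probability of a structural zero.
#' @param gamma_shape,gamma_rate Low-component gamma parameters.
#' @param normal_mean,normal_sd High-component normal parameters (log2CPM).
#' @param rho Per-gene probability of the high component among non-zeros.
#' @param marker_plan `NULL`, or a list from [marker_plan()].
#' @param network_plan `NULL`, or a list from [network_plan()].
#' @param library_size Per-cell total count the back-conversion targets.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 500L, n_cells = 120L, zero_prob = 0.4,
                           gamma_shape = 2, gamma_rate = 2, normal_mean = 8,
                           normal_sd = 1, rho = 0.4, marker_plan = NULL,
                           network_plan = NULL, library_size = 1e6,
                           seed = 1L) {
  stopifnot(n_genes >= 1, n_cells >= 1, all(zero_prob >= 0 & zero_prob <= 1),
            all(rho >= 0 & rho <= 1), all(gamma_shape > 0), all(gamma_rate > 0),
            all(normal_sd > 0))
  structure(
    list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
         zero_prob = rep_len(zero_prob, n_genes),
         gamma_shape = rep_len(gamma_shape, n_genes),
         gamma_rate = rep_len(gamma_rate, n_genes),
         normal_mean = rep_len(normal_mean, n_genes),
         normal_sd = rep_len(normal_sd, n_genes),
         rho = rep_len(rho, n_genes),
         marker_plan = marker_plan, network_plan = network_plan,
         library_size = library_size, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Plan for planted maturity markers
#'
#' Cells are split into mature and immature halves. The mature anchor
#' (default `"OMP"`) is made active exactly in mature cells and the immature
#' anchor (`"GAP43"`) exactly in immature cells, guaranteeing the two groups
#' are mutually exclusive and recoverable from the anchors alone. Each
#' planted marker gene is active with probability `p_active_own` in its own
#' group and `p_active_other` in the other.
#'
#' @param n_mature_markers,n_immature_markers Planted marker counts per side.
#' @param p_active_own,p_active_other Activity probabilities (the planted
#'   contrast), defaults 0.8 vs 0.1.
#' @param mature_marker,immature_marker Anchor gene names.
#' @param frac_mature Fraction of cells that are mature, default 0.5.
#' @return A list of class `marker_plan`.
#' @export
marker_plan <- function(n_mature_markers = 10L, n_immature_markers = 10L,
                        p_active_own = 0.8, p_active_other = 0.1,
                        mature_marker = "OMP", immature_marker = "GAP43",
                        frac_mature = 0.5) {
  structure(list(n_mature_markers = as.integer(n_mature_markers),
                 n_immature_markers = as.integer(n_immature_markers),
                 p_active_own = p_active_own, p_active_other = p_active_other,
                 mature_marker = mature_marker, immature_marker = immature_marker,
                 frac_mature = frac_mature),
            class = "marker_plan")
}

#' Plan for planted per-cell network topology
#'
#' Star cells each receive one private gene, active in that cell only, whose
#' edges to a pool of commonly active partner genes are therefore unique to
#' the cell (a hub-partner star once prevalent partner-partner edges are
#' filtered). Dense cells each activate a random subset of a large pool, so
#' their pairwise coactivations are individually rare and survive filtering
#' as a densely connected network.
#'
#' @param n_star_cells,n_dense_cells Planted cell counts per topology.
#' @param n_common_genes Size of the commonly active partner pool.
#' @param n_dense_pool Size of the pool dense cells draw from.
#' @param genes_per_dense_cell Mean active pool genes per dense cell
#'   (jittered by up to 2 per cell so network sizes vary).
#' @param n_background_cells Extra cells with no planted activity, enlarging
#'   the prevalence denominator so cell-unique edges sit at or below the
#'   smallest sweep threshold.
#' @param p_second_hub Probability a star cell carries a second private hub
#'   (two-hub stars have centralization below 1, giving the star group
#'   realistic within-group spread).
#' @param n_semi_common,semi_per_dense_cell Dense cells also activate
#'   `semi_per_dense_cell` genes from a small semi-common set; the mutual
#'   edges of that set recur across dense cells, so some edges of a dense
#'   network are pruned and its centralization varies around a small value.
#' @return A list of class `network_plan`.
#' @export
network_plan <- function(n_star_cells = 50L, n_dense_cells = 50L,
                         n_common_genes = 9L, n_dense_pool = 400L,
                         genes_per_dense_cell = 10L,
                         n_background_cells = 100L,
                         p_second_hub = 0.3,
                         n_semi_common = 6L, semi_per_dense_cell = 2L) {
  structure(list(n_star_cells = as.integer(n_star_cells),
                 n_dense_cells = as.integer(n_dense_cells),
                 n_common_genes = as.integer(n_common_genes),
                 n_dense_pool = as.integer(n_dense_pool),
                 genes_per_dense_cell = as.integer(genes_per_dense_cell),
                 n_background_cells = as.integer(n_background_cells),
                 p_second_hub = p_second_hub,
                 n_semi_common = as.integer(n_semi_common),
                 semi_per_dense_cell = as.integer(semi_per_dense_cell)),
            class = "network_plan")
}

#' Generate a synthetic count matrix with full ground truth
#'
#' Draws per-gene log2CPM values from the zero-inflated gamma-normal model of
#' the spec, applies the marker plan (anchor and planted-marker activity
#' overwrites), and back-converts to integer counts: `r = round(2^y - 1)`
#' with each cell's total topped up to `library_size` by an explicit filler
#' gene `"FILLER"`, so that [log2cpm()] applied to the counts recovers the
#' drawn values up to count rounding.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `counts` (genes-by-cells integer matrix, includes the
#'   `FILLER` row) and `truth`, a list holding `component` (matrix, 0 zero /
#'   1 low / 2 high per gene and cell), `active` (binary truth),
#'   `log2cpm_drawn` (the drawn log2CPM-scale values before rounding),
#'   `cell_groups` (tibble cell, group), `markers` (tibble gene, side),
#'   `gene_params` (tibble of the per-gene generative parameters),
#'   `filler_gene`, and `spec`.
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, generate_impl(spec))
}

generate_impl <- function(spec) {
  ng <- spec$n_genes
  nc <- spec$n_cells
  genes <- sprintf("G%04d", seq_len(ng))
  cells <- sprintf("cell%04d", seq_len(nc))

  # latent component per gene x cell: 0 zero, 1 low (gamma), 2 high (normal)
  comp <- matrix(0L, ng, nc, dimnames = list(genes, cells))
  y <- matrix(0, ng, nc, dimnames = list(genes, cells))
  for (g in seq_len(ng)) {
    is_zero <- stats::runif(nc) < spec$zero_prob[g]
    is_high <- !is_zero & (stats::runif(nc) < spec$rho[g])
    is_low <- !is_zero & !is_high
    comp[g, is_high] <- 2L
    comp[g, is_low] <- 1L
    y[g, is_high] <- stats::rnorm(sum(is_high), spec$normal_mean[g], spec$normal_sd[g])
    y[g, is_low] <- stats::rgamma(sum(is_low), shape = spec$gamma_shape[g],
                                  rate = spec$gamma_rate[g])
  }
  y[y < 0] <- 0.01  # normal tail below zero is not representable on log2CPM

  cell_groups <- tibble::tibble(cell = cells, group = "other")
  markers <- tibble::tibble(gene = character(0), side = character(0))

  if (!is.null(spec$marker_plan)) {
    mp <- spec$marker_plan
    n_mat <- round(mp$frac_mature * nc)
    grp <- c(rep("mature", n_mat), rep("immature", nc - n_mat))
    cell_groups$group <- grp
    needed <- 2L + mp$n_mature_markers + mp$n_immature_markers
    stopifnot(ng >= needed)
    anchor_idx <- 1:2
    mat_idx <- seq_len(mp$n_mature_markers) + 2L
    imm_idx <- seq_len(mp$n_immature_markers) + 2L + mp$n_mature_markers
    genes[anchor_idx] <- c(mp$mature_marker, mp$immature_marker)
    rownames(comp) <- rownames(y) <- genes

    overwrite <- function(g, active) {
      crow <- integer(nc)
      crow[active] <- 2L
      crow[!active] <- ifelse(stats::runif(sum(!active)) < spec$zero_prob[g], 0L, 1L)
      yrow <- numeric(nc)
      yrow[crow == 2L] <- stats::rnorm(sum(crow == 2L), spec$normal_mean[g], spec$normal_sd[g])
      yrow[crow == 1L] <- stats::rgamma(sum(crow == 1L), shape = spec$gamma_shape[g],
                                        rate = spec$gamma_rate[g])
      yrow[yrow < 0] <- 0.01
      comp[g, ] <<- crow
      y[g, ] <<- yrow
    }
    overwrite(anchor_idx[1], grp == "mature")
    overwrite(anchor_idx[2], grp == "immature")
    for (g in mat_idx) {
      p <- ifelse(grp == "mature", mp$p_active_own, mp$p_active_other)
      overwrite(g, stats::runif(nc) < p)
    }
    for (g in imm_idx) {
      p <- ifelse(grp == "immature", mp$p_active_own, mp$p_active_other)
      overwrite(g, stats::runif(nc) < p)
    }
    markers <- tibble::tibble(
      gene = genes[c(mat_idx, imm_idx)],
      side = c(rep("mature", length(mat_idx)), rep("immature", length(imm_idx)))
    )
  }

  # back-conversion: counts whose log2CPM at library_size reproduces y;
  # non-zero draws keep at least one read so the zero pattern survives
  counts <- round((2^y - 1) * spec$library_size / 1e6)
  counts[comp > 0L & counts < 1] <- 1
  storage.mode(counts) <- "integer"
  totals <- colSums(counts)
  if (any(totals > spec$library_size)) {
    bad <- cells[totals > spec$library_size][1]
    stop(sprintf(
      "infeasible back-conversion: cell '%s' needs %d counts > library_size %g; increase library_size",
      bad, max(totals), spec$library_size
    ), call. = FALSE)
  }
  filler <- as.integer(spec$library_size - totals)
  counts <- rbind(counts, FILLER = filler)

  active <- matrix(0L, ng, nc, dimnames = list(genes, cells))
  active[comp == 2L] <- 1L

  list(counts = counts,
       truth = list(component = comp, active = active, log2cpm_drawn = y,
                    cell_groups = cell_groups, markers = markers,
                    gene_params = tibble::tibble(
                      gene = genes, zero_prob = spec$zero_prob,
                      gamma_shape = spec$gamma_shape, gamma_rate = spec$gamma_rate,
                      normal_mean = spec$normal_mean, normal_sd = spec$normal_sd,
                      rho = spec$rho),
                    filler_gene = "FILLER", spec = spec))
}

#' Generate null synthetic data (no planted contrast or topology)
#'
#' As [generate()] but any marker or network plan is stripped, while the
#' anchor gene names are kept (as ordinary genes) so downstream group
#' definitions remain expressible. Used for type-I-error and permutation
#' checks.
#'
#' @param spec A [synthetic_spec()].
#' @return As [generate()].
#' @export
generate_null <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  mp <- spec$marker_plan
  spec$marker_plan <- NULL
  spec$network_plan <- NULL
  out <- generate(spec)
  # keep anchor names available for group definitions, without planted signal
  anchors <- if (!is.null(mp)) c(mp$mature_marker, mp$immature_marker) else c("OMP", "GAP43")
  if (nrow(out$counts) >= 3) {
    rn <- rownames(out$counts)
    rn[1:2] <- anchors
    rownames(out$counts) <- rn
    rownames(out$truth$component) <- rn[-length(rn)]
    rownames(out$truth$active) <- rn[-length(rn)]
    rownames(out$truth$log2cpm_drawn) <- rn[-length(rn)]
    out$truth$gene_params$gene <- rn[-length(rn)]
  }
  out
}

#' Generate planted star vs dense binary activity for network analysis
#'
#' Builds a binary activity matrix realizing a [network_plan()]: star cells
#' (labelled mature) activate one private gene plus the common partner pool;
#' dense cells (labelled immature) activate a random subset of a large pool;
#' background cells activate only the common pool. After prevalence
#' filtering, star cells yield hub-partner networks (centralization near 1)
#' and dense cells near-cliques (centralization near 0).
#'
#' @param plan A [network_plan()].
#' @param seed Integer seed.
#' @return List with `binary` (genes-by-cells matrix), `groups` (a
#'   `maturity_groups` with star cells as mature and dense cells as
#'   immature), and `truth` (tibble cell, topology).
#' @export
generate_network_activity <- function(plan = network_plan(), seed = 1L) {
  stopifnot(inherits(plan, "network_plan"))
  withr::with_seed(seed, {
    n_cells <- plan$n_star_cells + plan$n_dense_cells + plan$n_background_cells
    cells <- sprintf("cell%04d", seq_len(n_cells))
    common <- sprintf("COMMON%02d", seq_len(plan$n_common_genes))
    private <- sprintf("PRIV%04d", seq_len(2L * plan$n_star_cells))
    semi <- sprintf("SEMI%02d", seq_len(plan$n_semi_common))
    pool <- sprintf("POOL%04d", seq_len(plan$n_dense_pool))
    genes <- c(common, private, semi, pool)
    binary <- matrix(0L, length(genes), n_cells, dimnames = list(genes, cells))

    star_cells <- cells[seq_len(plan$n_star_cells)]
    dense_cells <- cells[plan$n_star_cells + seq_len(plan$n_dense_cells)]
    bg_cells <- setdiff(cells, c(star_cells, dense_cells))

    binary[common, c(star_cells, bg_cells)] <- 1L
    for (i in seq_along(star_cells)) {
      binary[private[2 * i - 1], star_cells[i]] <- 1L
      if (stats::runif(1) < plan$p_second_hub) {
        binary[private[2 * i], star_cells[i]] <- 1L
      }
    }
    for (cl in dense_cells) {
      k <- plan$genes_per_dense_cell + sample(-2:2, 1)
      binary[sample(pool, max(3L, k)), cl] <- 1L
      if (plan$n_semi_common >= plan$semi_per_dense_cell) {
        binary[sample(semi, plan$semi_per_dense_cell), cl] <- 1L
      }
    }
    groups <- structure(
      list(mature_cells = star_cells, immature_cells = dense_cells,
           excluded_cells = bg_cells,
           mature_marker = NA_character_, immature_marker = NA_character_),
      class = "maturity_groups"
    )
    list(binary = binary, groups = groups,
         truth = tibble::tibble(
           cell = cells,
           topology = c(rep("star", length(star_cells)),
                        rep("dense", length(dense_cells)),
                        rep("background", length(bg_cells)))))
  })
}

#' Draw values from the zero-inflated gamma-normal generative model
#'
#' Convenience sampler for one gene: returns `n` log2CPM-scale values with
#' their latent components (0 zero, 1 low, 2 high).
#'
#' @param n Number of cells.
#' @param zero_prob,gamma_shape,gamma_rate,normal_mean,normal_sd,rho Model
#'   parameters as in [synthetic_spec()].
#' @return Tibble with `value` and `component`.
#' @export
rgammanormal <- function(n, zero_prob = 0, gamma_shape = 2, gamma_rate = 2,
                         normal_mean = 8, normal_sd = 1, rho = 0.4) {
  is_zero <- stats::runif(n) < zero_prob
  is_high <- !is_zero & (stats::runif(n) < rho)
  is_low <- !is_zero & !is_high
  value <- numeric(n)
  value[is_high] <- stats::rnorm(sum(is_high), normal_mean, normal_sd)
  value[is_low] <- stats::rgamma(sum(is_low), shape = gamma_shape, rate = gamma_rate)
  value[value < 0] <- 0.01
  tibble::tibble(value = value,
                 component = ifelse(is_zero, 0L, ifelse(is_high, 2L, 1L)))
}
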