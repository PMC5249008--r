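#' Run configuration for the end-to-end pipeline
#'
#' @param counts_path Count matrix file (csv/tsv/mtx), or `NULL` when a
#'   matrix is passed to [run_pipeline()] directly.
#' @param output_dir Directory for all artifacts (created if absent).
#' @param em An [em_config()].
#' @param ctx A [context_config()] or `NULL` to skip contextualization.
#' @param mature_marker,immature_marker Anchor gene names.
#' @param universe_path Optional gene-list file restricting the marker scan
#'   and the network stage.
#' @param alpha Bonferroni-corrected significance level for the marker scan.
#' @param thresholds Prevalence sweep for the network comparison.
#' @param min_nodes Minimum network size for the centralization comparison.
#' @param seed Master seed, propagated to every stochastic stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(counts_path = NULL, output_dir = "ternactive_out",
                       em = em_config(), ctx = context_config(),
                       mature_marker = "OMP", immature_marker = "GAP43",
                       universe_path = NULL, alpha = 0.01,
                       thresholds = c(0.005, 0.01, 0.02, 0.03, 0.04, 0.05),
                       min_nodes = 5L, seed = 1L) {
  if (!is.null(counts_path) && !file.exists(counts_path)) {
    stop("counts file does not exist: ", counts_path, call. = FALSE)
  }
  if (!is.null(universe_path) && !file.exists(universe_path)) {
    stop("universe file does not exist: ", universe_path, call. = FALSE)
  }
  em$seed <- as.integer(seed)
  if (!is.null(ctx)) ctx$seed <- as.integer(seed)
  structure(list(counts_path = counts_path, output_dir = output_dir, em = em,
                 ctx = ctx, mature_marker = mature_marker,
                 immature_marker = immature_marker,
                 universe_path = universe_path, alpha = alpha,
                 thresholds = thresholds, min_nodes = as.integer(min_nodes),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; `em` and `ctx` may be
#' nested maps of the respective config arguments.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  yml <- yaml::read_yaml(path)
  em_args <- yml$em %||% list()
  ctx_args <- yml$ctx %||% list()
  args <- yml[setdiff(names(yml), c("em", "ctx"))]
  args$em <- do.call(em_config, em_args)
  args$ctx <- if (identical(yml$ctx, FALSE)) NULL else do.call(context_config, ctx_args)
  do.call(run_config, args)
}

#' Run the full analysis pipeline
#'
#' log2CPM transform, per-gene mixture fits to a ternary matrix (with
#' optional contextualization of unfittable genes), binarization, maturity
#' grouping by the anchor markers, the genome-wide marker coactivation scan,
#' per-cell network construction and the centralization threshold sweep.
#' All stage outputs are written as TSV under `config$output_dir` together
#' with a run manifest (seed, config hash, per-stage counts).
#'
#' @param config A [run_config()].
#' @param counts Optional in-memory genes-by-cells count matrix; otherwise
#'   read from `config$counts_path`.
#' @return List of class `pipeline_result` with `logexpr`, `ternary`,
#'   `fits`, `binary`, `groups`, `scan`, `networks`, `comparison`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, counts = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- "read_counts"
  result <- tryCatch({
    if (is.null(counts)) counts <- read_counts(config$counts_path)
    validate_counts(counts)

    stage <- "log2cpm"
    logexpr <- log2cpm(counts)

    stage <- "ternary"
    tr <- build_ternary_matrix(logexpr, config$em)
    ternary <- tr$ternary
    n_na_genes <- sum(apply(is.na(ternary), 1, any))
    if (!is.null(config$ctx) && n_na_genes > 0) {
      stage <- "contextualize"
      ternary <- contextualize_ternary(ternary, logexpr, config$em, config$ctx)
    }

    stage <- "binarize"
    binary <- binarize(ternary)

    universe <- rownames(binary)
    if (!is.null(config$universe_path)) {
      universe <- intersect(read_gene_list(config$universe_path), universe)
      if (length(universe) == 0) stop("empty universe after intersection", call. = FALSE)
    }

    stage <- "maturity_groups"
    groups <- define_maturity_groups(binary, config$mature_marker,
                                     config$immature_marker)

    stage <- "marker_scan"
    scan <- marker_coactivation_scan(binary, groups, alpha = config$alpha,
                                     test_universe = universe)

    stage <- "networks"
    bin_net <- binary[intersect(universe, rownames(binary)), , drop = FALSE]
    prevalence <- edge_prevalence(bin_net)
    networks <- build_cell_networks(bin_net, prevalence,
                                    threshold = config$thresholds[
                                      which.min(abs(config$thresholds - 0.01))],
                                    groups = groups)

    stage <- "centralization"
    comparison <- compare_group_centralization(bin_net, groups,
                                               thresholds = config$thresholds,
                                               min_nodes = config$min_nodes,
                                               prevalence = prevalence)

    stage <- "write_outputs"
    manifest <- write_pipeline_outputs(config, logexpr, ternary, tr$fits,
                                       binary, groups, scan, networks,
                                       comparison, n_na_genes)

    structure(list(logexpr = logexpr, ternary = ternary, fits = tr$fits,
                   binary = binary, groups = groups, scan = scan,
                   networks = networks, comparison = comparison,
                   manifest = manifest),
              class = "pipeline_result")
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

write_pipeline_outputs <- function(config, logexpr, ternary, fits, binary,
                                   groups, scan, networks, comparison,
                                   n_na_genes) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)

  write_ternary(ternary, out("ternary.tsv"))
  write_ternary(binary, out("binary.tsv"))
  readr::write_tsv(fits, out("gene_fits.tsv"), na = "NA")
  readr::write_tsv(scan, out("marker_scan.tsv"), na = "NA")
  readr::write_tsv(dplyr::select(networks, -"network"), out("cell_networks.tsv"),
                   na = "NA")
  edge_rows <- purrr::map_dfr(networks$network, function(net) {
    if (nrow(net$edges) == 0) return(NULL)
    tibble::tibble(cell = net$cell, gene_a = net$edges[, 1], gene_b = net$edges[, 2])
  })
  readr::write_tsv(edge_rows, out("cell_network_edges.tsv"))
  readr::write_tsv(comparison, out("centralization_comparison.tsv"), na = "NA")

  cfg_for_hash <- config[setdiff(names(config), "output_dir")]
  manifest <- list(
    seed = config$seed,
    config_hash = digest_config(cfg_for_hash),
    n_genes = nrow(logexpr), n_cells = ncol(logexpr),
    n_genes_unfittable_before_context = n_na_genes,
    n_genes_na_final = sum(apply(is.na(ternary), 1, any)),
    n_mature = length(groups$mature_cells),
    n_immature = length(groups$immature_cells),
    n_excluded = length(groups$excluded_cells),
    n_genes_tested = nrow(scan),
    n_significant = sum(scan$significant),
    networks_per_threshold = stats::setNames(
      as.list(comparison$n_mature + comparison$n_immature),
      as.character(comparison$threshold))
  )
  yaml::write_yaml(manifest, out("manifest.yaml"))
  manifest
}

# Deterministic config fingerprint without external digest dependencies.
digest_config <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, give.attr = FALSE)), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647  # exact in doubles
  sprintf("%08x", as.integer(h))
}

#' @exportS3Method base::print
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("ternactive pipeline result\n")
  cat(sprintf("  %d genes x %d cells | %d mature, %d immature, %d excluded cells\n",
              m$n_genes, m$n_cells, m$n_mature, m$n_immature, m$n_excluded))
  cat(sprintf("  marker scan: %d genes tested, %d significant\n",
              m$n_genes_tested, m$n_significant))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
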