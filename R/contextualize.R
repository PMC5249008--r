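#' Contextualization configuration
#'
#' Controls for rescuing genes whose non-zero cells are too few for a mixture
#' fit: the gene's non-zero values are pooled with those of randomly selected
#' context genes, the mixture is fit on the pool, and the target cells inherit
#' the pooled calls; repetitions are majority-voted.
#'
#' @param n_context_genes Context genes pooled per repetition.
#' @param n_repetitions Number of repetitions; context genes are resampled
#'   independently each time.
#' @param seed Integer seed for the context-gene draws.
#' @return A list of class `context_config`.
#' @export
context_config <- function(n_context_genes = 10L, n_repetitions = 10L, seed = 1L) {
  stopifnot(n_context_genes >= 1, n_repetitions >= 1)
  structure(list(n_context_genes = as.integer(n_context_genes),
                 n_repetitions = as.integer(n_repetitions),
                 seed = as.integer(seed)),
            class = "context_config")
}

#' Ternary calls for a sparse gene via context pooling
#'
#' For each repetition, draws `n_context_genes` genes from the eligible pool
#' (all other genes with at least `em_config$min_nonzero_cells` non-zero
#' cells), concatenates their non-zero log2CPM values with the target gene's
#' non-zero values into one sample, fits the gamma-normal mixture on the
#' pool, and records the calls the target cells receive. The final call per
#' cell is the majority over repetitions among 1/2 calls; ties resolve to the
#' smaller value (the conservative choice). A repetition whose pool is still
#' too small abstains. Zero cells stay 0.
#'
#' @param gene Gene id (must be a rowname of `logexpr`).
#' @param logexpr Genes-by-cells log2CPM matrix.
#' @param em_config An [em_config()].
#' @param ctx_config A [context_config()].
#' @return Integer vector over all cells of `gene` with entries in
#'   `{0, 1, 2, NA}` (NA if every repetition abstained for that cell).
#' @export
contextual_fit <- function(gene, logexpr, em_config = ternactive::em_config(),
                           ctx_config = context_config()) {
  stopifnot(gene %in% rownames(logexpr))
  x <- logexpr[gene, ]
  nz <- which(x > 0)
  if (length(nz) < 1) stop("target gene has no non-zero cells", call. = FALSE)

  nonzero_per_gene <- rowSums(logexpr > 0)
  pool_genes <- setdiff(rownames(logexpr)[nonzero_per_gene >= em_config$min_nonzero_cells],
                        gene)
  if (length(pool_genes) == 0) stop("no eligible context genes", call. = FALSE)

  m <- length(nz)
  calls <- matrix(NA_integer_, nrow = ctx_config$n_repetitions, ncol = m)
  ctx_draws <- withr::with_seed(ctx_config$seed, {
    lapply(seq_len(ctx_config$n_repetitions), function(r) {
      sample(pool_genes, min(ctx_config$n_context_genes, length(pool_genes)))
    })
  })
  for (r in seq_len(ctx_config$n_repetitions)) {
    ctx_vals <- as.vector(logexpr[ctx_draws[[r]], , drop = FALSE])
    pooled <- c(x[nz], ctx_vals[ctx_vals > 0])
    cfg <- em_config
    cfg$seed <- gene_seed(em_config$seed, 7919L * r)
    fit <- fit_gamma_normal(pooled, cfg)
    if (inherits(fit, "gn_insufficient")) next
    pooled_calls <- classify_cells(fit, em_config$z_call_threshold)
    # target values sit first in the pool and are all non-zero
    calls[r, ] <- pooled_calls[seq_len(m)]
  }

  out <- rep(0L, length(x))
  names(out) <- names(x)
  out[nz] <- apply(calls, 2, majority_call)
  out
}

# Majority among 1/2 calls; ties to the smaller value; all-NA stays NA.
majority_call <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_integer_)
  n2 <- sum(v == 2L)
  if (n2 > length(v) - n2) 2L else 1L
}

#' Fill NA ternary calls by contextualization
#'
#' Applies [contextual_fit()] to every gene that has `NA` entries in a
#' ternary matrix (genes with too few non-zero cells for a direct fit) and
#' merges the rescued calls back in.
#'
#' @param ternary_result A `ternary_result` from [build_ternary_matrix()], or
#'   a bare ternary matrix.
#' @param logexpr The log2CPM matrix the ternary calls came from.
#' @param em_config,ctx_config Configurations as in [contextual_fit()].
#' @return A ternary matrix of the same shape with NAs replaced where a
#'   majority call was obtainable.
#' @export
contextualize_ternary <- function(ternary_result, logexpr,
                                  em_config = ternactive::em_config(),
                                  ctx_config = context_config()) {
  ternary <- if (inherits(ternary_result, "ternary_result")) {
    ternary_result$ternary
  } else {
    ternary_result
  }
  na_genes <- rownames(ternary)[apply(is.na(ternary), 1, any)]
  for (g in na_genes) {
    ternary[g, ] <- contextual_fit(g, logexpr, em_config, ctx_config)
  }
  ternary
}
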