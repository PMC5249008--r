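#' Tidy a gamma-normal mixture fit
#'
#' One row per parameter, broom-style.
#'
#' @param x A `gn_fit`.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate`.
#' @export
tidy.gn_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta", "mu", "sigma2", "rho"),
    estimate = c(x$alpha, x$beta, x$mu, x$sigma2, x$rho)
  )
}

#' One-row fit summary
#'
#' @param x A `gn_fit`.
#' @param ... Unused.
#' @return Tibble with `n_used`, `n_iter`, `converged`, `single_component`,
#'   `loglik` (final observed-data log-likelihood), `n_high` (cells with
#'   posterior at or above 0.5).
#' @export
glance.gn_fit <- function(x, ...) {
  tibble::tibble(
    n_used = x$n_used, n_iter = x$n_iter, converged = x$converged,
    single_component = x$single_component,
    loglik = x$loglik_trace[length(x$loglik_trace)],
    n_high = sum(x$z >= 0.5)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a fitted gamma-normal mixture over the data
#'
#' Histogram of the non-zero values with the fitted mixture density and its
#' weighted gamma and normal components.
#'
#' @param object A `gn_fit`.
#' @param x_values The non-zero values the fit used (the fit stores only
#'   posteriors, not data).
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gn_fit <- function(object, x_values, bins = 30, ...) {
  stopifnot(length(x_values) == object$n_used)
  grid <- seq(max(min(x_values) * 0.5, 1e-3), max(x_values) * 1.1, length.out = 300)
  dens <- tibble::tibble(
    x = rep(grid, 3),
    density = c(
      (1 - object$rho) * exp(gamma_log_density(grid, object$alpha, object$beta)),
      object$rho * exp(normal_log_density(grid, object$mu, object$sigma2)),
      (1 - object$rho) * exp(gamma_log_density(grid, object$alpha, object$beta)) +
        object$rho * exp(normal_log_density(grid, object$mu, object$sigma2))
    ),
    component = rep(c("gamma (low)", "normal (high)", "mixture"), each = length(grid))
  )
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = tibble::tibble(x = x_values),
      ggplot2::aes(x = .data$x, y = ggplot2::after_stat(density)),
      bins = bins, fill = "grey85", colour = "grey60"
    ) +
    ggplot2::geom_line(
      data = dens,
      ggplot2::aes(x = .data$x, y = .data$density, colour = .data$component)
    ) +
    ggplot2::labs(x = "log2CPM (non-zero)", y = "density",
                  title = "Gamma-normal mixture fit") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Violin plot of centralization by maturity group
#'
#' @param networks Tibble from [build_cell_networks()] (needs `group` and
#'   `centralization`).
#' @param min_nodes Minimum network size to display, default 5.
#' @return A ggplot object.
#' @export
plot_centralization <- function(networks, min_nodes = 5L) {
  df <- dplyr::filter(networks, .data$n_nodes >= min_nodes,
                      !is.na(.data$centralization),
                      .data$group %in% c("mature", "immature"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$centralization,
                                   fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.08, size = 0.8, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "degree centralization") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot the centralization threshold sweep
#'
#' @param comparison Tibble from [compare_group_centralization()].
#' @return A ggplot object showing mean centralization per group across
#'   prevalence thresholds, annotated with the t-test p-values.
#' @export
plot_centralization_sweep <- function(comparison) {
  df <- tidyr::pivot_longer(comparison, c("mean_mature", "mean_immature"),
                            names_to = "group", values_to = "mean_centralization")
  df$group <- sub("mean_", "", df$group)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold,
                                   y = .data$mean_centralization,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "edge prevalence threshold", y = "mean centralization") +
    ggplot2::theme_minimal()
}
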