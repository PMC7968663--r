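#' Plot a degree distribution on log-log axes
#'
#' The classical scale-free diagnostic: empirical `P(k)` against `k`, both
#' on logarithmic axes, optionally overlaid with a fitted power law.
#'
#' @param object A `dtn_degree_distribution`.
#' @param fit Optional `dtn_powerlaw_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dtn_degree_distribution
#' @export
autoplot.dtn_degree_distribution <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$k, y = .data$p)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "degree k", y = "P(k)",
      title = sprintf("%s-degree distribution", attr(object, "which"))
    )
  if (!is.null(fit)) {
    grid <- tibble(k = object$k, p = fit$A * object$k^(-fit$gamma))
    p <- p + ggplot2::geom_line(data = grid, colour = "red3",
                                linetype = "dashed")
  }
  p
}

#' Plot the community size distribution
#'
#' @param object A `dtn_partition`.
#' @param ... Unused.
#' @return A ggplot object: probability of each community size, log-log.
#' @method autoplot dtn_partition
#' @export
autoplot.dtn_partition <- function(object, ...) {
  sizes <- community_size_stats(object)$sizes
  df <- count(tibble(size = sizes), .data$size, name = "n")
  df$p <- df$n / sum(df$n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$p)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "community size", y = "P(size)",
                  title = sprintf("Community sizes (Q = %.3f)", object$Q))
}

#' Plot the clustering-coefficient curve C(k)
#'
#' @param object A `dtn_clustering`.
#' @param ... Unused.
#' @return A ggplot object: mean clustering coefficient per exact degree.
#' @method autoplot dtn_clustering
#' @export
autoplot.dtn_clustering <- function(object, ...) {
  ggplot2::ggplot(object$c_of_k,
                  ggplot2::aes(x = .data$k, y = .data$mean_c)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "degree k", y = "mean C(k)",
                  title = "Clustering profile")
}
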