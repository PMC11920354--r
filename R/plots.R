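# ggplot2 displays -------------------------------------------------------------

#' Heterogeneity factor as a function of depth and overdispersion
#'
#' Draws `omega = [1 + (R_T - 1) tau] / R_T` over a depth range for a set
#' of tau values: with no overdispersion omega decays as `1/R_T`, while
#' for `tau > 0` it flattens towards tau at high depth.
#'
#' @param tau Overdispersion values to draw.
#' @param depth_range Range of mean read depths.
#' @return A ggplot object.
#' @export
plot_heterogeneity <- function(tau = c(0, 0.1, 0.3, 0.6),
                               depth_range = c(1, 200)) {
  grid <- tidyr::expand_grid(
    tau = tau,
    depth = seq(depth_range[1], depth_range[2], length.out = 200)
  )
  grid$omega <- heterogeneity_factor(grid$tau, grid$depth)
  ggplot2::ggplot(grid, ggplot2::aes(.data$depth, .data$omega,
                                     colour = factor(.data$tau))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "mean total read depth", y = "heterogeneity factor",
                  colour = "tau") +
    ggplot2::theme_minimal()
}

#' Heatmap of a genomic relationship matrix
#'
#' @param object A `grm`.
#' @param max_n At most this many individuals are shown (evenly
#'   subsampled) to keep the tile map readable.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grm
#' @export
autoplot.grm <- function(object, max_n = 200, ...) {
  G <- object$G
  if (nrow(G) > max_n) {
    keep <- round(seq(1, nrow(G), length.out = max_n))
    G <- G[keep, keep]
  }
  df <- tibble::as_tibble(G, rownames = "i") |>
    tidyr::pivot_longer(-"i", names_to = "j", values_to = "g")
  df$i <- factor(df$i, levels = rownames(G))
  df$j <- factor(df$j, levels = rownames(G))
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$g)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(title = sprintf("G (%s scaling)", object$method),
                  x = NULL, y = NULL, fill = "G") +
    ggplot2::theme_void()
}

#' Restricted log-likelihood trajectory of an EM-REML run
#'
#' @param object A `reml_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot reml_fit
#' @export
autoplot.reml_fit <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(.data$iter, .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "EM iteration", y = "restricted log-likelihood") +
    ggplot2::theme_minimal()
}

#' Predictive ability and dispersion by trait and strategy
#'
#' @param object A `validation_report` from [run_validation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object, c("predictive_ability", "lr_slope"),
    names_to = "statistic", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$trait, .data$value,
                                   fill = .data$strategy)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
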