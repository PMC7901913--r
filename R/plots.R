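#' Plot weight trajectories for a set of dynamics
#'
#' Pulse-by-pulse weight evolution (continuous reference solution by
#' default) for each row of a dynamics parameter table, potentiation
#' from `w = 0` and depression from `w = 1`.
#'
#' @param dynamics Parameter table as in [dynamics_grid()].
#' @param n_pulses Pulses to plot.
#' @param mode `"continuous"` or `"discrete"`.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(dynamics = dynamics_grid(), n_pulses = 1000,
                              mode = c("continuous", "discrete")) {
  mode <- match.arg(mode)
  df <- purrr::pmap_dfr(dynamics, function(family, alpha, gamma = NA,
                                           n_stop = NA, ...) {
    spec <- as_dynamics_spec(list(family = family, alpha = alpha,
                                  gamma = gamma, n_stop = n_stop))
    lab <- paste0(family, " a=", alpha,
                  ifelse(is.na(gamma), "", paste0(" g=", gamma)),
                  ifelse(is.na(n_stop), "", paste0(" N=", n_stop)))
    dplyr::bind_rows(
      dplyr::mutate(
        weight_trajectory(spec, "potentiation", 0, n_pulses, mode),
        direction = "potentiation", dynamics = lab, family = family),
      dplyr::mutate(
        weight_trajectory(spec, "depression", 1, n_pulses, mode),
        direction = "depression", dynamics = lab, family = family)
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(pulse, weight, colour = dynamics,
                                   linetype = direction)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~family) +
    ggplot2::labs(x = "pulse number n", y = "weight w",
                  linetype = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname train_snn
#' @param object An `snn_fit` object.
#' @export
autoplot.snn_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, c("ca", "contrast"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(images_seen, value, colour = metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "training images seen", y = NULL, colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Histogram of the trained weight distribution
#'
#' Linear (weight-independent) dynamics drive the weights toward the
#' bounds (bimodal distribution); soft-bound dynamics concentrate them
#' mid-range (unimodal). This diagnostic shows which regime a trained
#' network is in.
#'
#' @param network An [snn_network()] (or weight matrix).
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_weight_distribution <- function(network, bins = 50) {
  w <- if (inherits(network, "snn_network")) network$weights else network
  df <- tibble::tibble(weight = as.numeric(w))
  ggplot2::ggplot(df, ggplot2::aes(weight)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0) +
    ggplot2::xlim(-0.02, 1.02) +
    ggplot2::labs(x = "synaptic weight", y = "count") +
    ggplot2::theme_minimal()
}
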