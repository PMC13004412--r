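#' Plot a one-sided power spectrum
#'
#' @param object A `chx_spectrum` from [power_spectrum()].
#' @param ... Unused.
#' @return A ggplot object (log-10 power against frequency).
#' @export
autoplot.chx_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frequency,
                                       y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Power",
                  title = "One-sided power spectrum") +
    ggplot2::theme_minimal()
}

#' Plot a tunneling probability trace
#'
#' @param object A `chx_tunneling_trace` from [simulate_base_pair()].
#' @param ... Unused.
#' @return A ggplot object of the right-well probability over time.
#' @export
autoplot.chx_tunneling_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$p_right)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time (s)", y = expression(P[R](t)),
      title = paste0("Right-well probability, ", attr(object, "pair"),
                     " pair (V0 = ", attr(object, "v0_ev"), " eV)")
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-region block series of a trajectory
#'
#' @param object A `chx_trajectory` from [propagate()].
#' @param ... Unused.
#' @return A ggplot object: mean amplitude and mean unwrapped phase per
#'   block over time.
#' @export
autoplot.chx_trajectory <- function(object, ...) {
  rs <- region_series(object) |>
    tidyr::pivot_longer(c("mean_amplitude", "mean_phase"),
                        names_to = "quantity", values_to = "value")
  ggplot2::ggplot(rs, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$block)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Time (s)", y = NULL, colour = "Block") +
    ggplot2::theme_minimal()
}

#' Plot the per-region entropy profile by class
#'
#' @param profile Tibble from [region_entropy_profile()].
#' @return A ggplot object: boxplots of Shannon and von Neumann entropy per
#'   region class.
#' @export
plot_entropy_profile <- function(profile) {
  long <- profile |>
    tidyr::pivot_longer(c("shannon_bits", "von_neumann_bits"),
                        names_to = "entropy", values_to = "bits")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$kind, y = .data$bits,
                                     fill = .data$kind)) +
    ggplot2::geom_boxplot(alpha = 0.7, show.legend = FALSE) +
    ggplot2::facet_wrap(~entropy, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Entropy (bits)") +
    ggplot2::theme_minimal()
}

#' Plot power ratios of a real-versus-control experiment
#'
#' @param x A `chx_power_ratio` object.
#' @return A ggplot object of per-replicate band-power ratios by condition.
#' @export
plot_power_ratio <- function(x) {
  stopifnot(inherits(x, "chx_power_ratio"))
  ggplot2::ggplot(x$replicates,
                  ggplot2::aes(x = .data$condition, y = .data$ratio)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.5) +
    ggplot2::geom_jitter(width = 0.1, height = 0) +
    ggplot2::labs(x = NULL, y = "Non-coding / coding band-power ratio") +
    ggplot2::theme_minimal()
}
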