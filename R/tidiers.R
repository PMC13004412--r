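#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a power-ratio experiment
#'
#' @param x A `chx_power_ratio` object.
#' @param ... Unused.
#' @return The per-replicate tibble with band powers and ratio.
#' @export
tidy.chx_power_ratio <- function(x, ...) x$replicates

#' One-row summary of a power-ratio experiment
#'
#' @param x A `chx_power_ratio` object.
#' @param ... Unused.
#' @return A one-row tibble with per-condition mean/sd ratios and the
#'   cross-condition comparison statistics.
#' @export
glance.chx_power_ratio <- function(x, ...) {
  wide <- x$summary |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("n", "mean_ratio", "sd_ratio"))
  dplyr::bind_cols(wide, dplyr::select(x$comparison, -"n_a", -"n_b"))
}

#' Tidy a region tunneling experiment
#'
#' @param x A `chx_tunneling_experiment` object.
#' @param ... Unused.
#' @return The per-base-pair tibble of time-averaged right-well
#'   probabilities.
#' @export
tidy.chx_tunneling_experiment <- function(x, ...) x$per_pair

#' Per-condition summary of a region tunneling experiment
#'
#' @param x A `chx_tunneling_experiment` object.
#' @param ... Unused.
#' @return The per-condition test tibble (paired and Welch t statistics for
#'   the coding vs non-coding contrast).
#' @export
glance.chx_tunneling_experiment <- function(x, ...) x$tests

#' Tidy a propagation trajectory into long format
#'
#' @param x A `chx_trajectory` from [propagate()].
#' @param ... Unused.
#' @return A long tibble: `time`, `site`, `amplitude`, `phase`.
#' @export
tidy.chx_trajectory <- function(x, ...) {
  n <- ncol(x$amplitudes)
  tibble::tibble(
    time = rep(x$times, times = n),
    site = rep(seq_len(n), each = length(x$times)),
    amplitude = as.vector(x$amplitudes),
    phase = as.vector(x$phases)
  )
}
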