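#' Remove a least-squares linear trend from a series
#'
#' Fits `x ~ index` by ordinary least squares and returns the residuals,
#' isolating oscillatory components before spectral analysis. The output has
#' mean (numerically) zero.
#'
#' @param series Numeric vector, length >= 3.
#' @return Detrended numeric vector of the same length.
#' @examples
#' detrend_series(3 * seq_len(10) + 2)  # ~0 everywhere
#' @export
detrend_series <- function(series) {
  stopifnot(is.numeric(series))
  if (length(series) < 3) {
    stop("detrending needs at least 3 points", call. = FALSE)
  }
  if (!all(is.finite(series))) {
    stop("non-finite values in series", call. = FALSE)
  }
  idx <- seq_along(series)
  unname(stats::lm.fit(cbind(1, idx), series)$residuals)
}

#' One-sided power spectrum of a real series
#'
#' Squared magnitude of the DFT on the non-negative frequency grid
#' `j/(n*dt)`, `j = 0..floor(n/2)`. Normalization: `power_j = |X_j|^2 / n`,
#' doubled for interior bins (neither DC nor, for even `n`, Nyquist), so that
#' Parseval's identity holds in the form `sum(power) == sum(series^2)` --
#' for a mean-zero (e.g. detrended) series this is `n` times the population
#' variance.
#'
#' @param series Real numeric vector, length >= 4, finite.
#' @param dt Sampling interval in seconds (> 0).
#' @return A tibble of class `chx_spectrum` with columns `frequency` (Hz) and
#'   `power`, plus attributes `dt` and `n`.
#' @export
power_spectrum <- function(series, dt) {
  stopifnot(is.numeric(series), dt > 0)
  n <- length(series)
  if (n < 4) stop("spectrum needs at least 4 samples", call. = FALSE)
  if (!all(is.finite(series))) {
    stop("non-finite values in series", call. = FALSE)
  }
  X <- stats::fft(series)
  half <- floor(n / 2)
  j <- 0:half
  power <- Mod(X[j + 1])^2 / n
  dbl <- j > 0 & !(n %% 2 == 0 & j == half)
  power[dbl] <- 2 * power[dbl]
  out <- tibble::tibble(frequency = j / (n * dt), power = power)
  class(out) <- c("chx_spectrum", class(out))
  attr(out, "dt") <- dt
  attr(out, "n") <- n
  out
}

#' Integrated spectral power in a frequency band
#'
#' Sum of the one-sided power over bins with `f_lo <= f <= f_hi`, both ends
#' inclusive.
#'
#' @param spec A spectrum from [power_spectrum()].
#' @param f_lo,f_hi Band edges in Hz, `0 <= f_lo < f_hi <= Nyquist`.
#' @return Scalar band power.
#' @export
band_power <- function(spec, f_lo, f_hi) {
  stopifnot(f_lo >= 0, f_hi > f_lo)
  nyquist <- 1 / (2 * attr(spec, "dt"))
  if (f_hi > nyquist * (1 + 1e-12)) {
    stop("band edge ", f_hi, " Hz exceeds the Nyquist frequency ",
         nyquist, " Hz", call. = FALSE)
  }
  sum(spec$power[spec$frequency >= f_lo & spec$frequency <= f_hi])
}

#' Band edges covering a chirped drive's frequency excursion
#'
#' The band swept by `f(t) = f0 + k*t` over a window of length `t_total`,
#' expanded by one spectral bin on each side (clamped to `[0, Nyquist]`).
#'
#' @param f0 Base frequency (Hz).
#' @param chirp_rate Drift rate k (Hz/s).
#' @param t_total Window length (s).
#' @param spec Spectrum whose bin width and Nyquist limit apply.
#' @return Numeric `c(f_lo, f_hi)`.
#' @export
doppler_band <- function(f0, chirp_rate, t_total, spec) {
  bin <- 1 / (attr(spec, "n") * attr(spec, "dt"))
  nyquist <- 1 / (2 * attr(spec, "dt"))
  f_end <- f0 + chirp_rate * t_total
  lo <- max(0, min(f0, f_end) - bin)
  hi <- min(nyquist, max(f0, f_end) + bin)
  c(lo, hi)
}

#' Welch t and Mann-Whitney U comparison of two samples
#'
#' Two-sided Welch two-sample t test and two-sided Mann-Whitney U with the
#' normal approximation. When both samples have zero variance the t
#' statistic is undefined and reported as `NA`.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return A one-row tibble: `welch_t`, `t_pvalue`, `mannwhitney_U`,
#'   `U_pvalue`, `n_a`, `n_b`.
#' @examples
#' compare_distributions(c(1, 2, 3), c(4, 5, 6))
#' @export
compare_distributions <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    welch_t <- NA_real_
    t_p <- NA_real_
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    welch_t <- unname(tt$statistic)
    t_p <- tt$p.value
  }
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  )
  tibble::tibble(
    welch_t = welch_t, t_pvalue = t_p,
    mannwhitney_U = unname(wt$statistic), U_pvalue = wt$p.value,
    n_a = length(a), n_b = length(b)
  )
}

#' Summarise a real-versus-control band-power experiment
#'
#' Takes per-replicate band-power reports (one row per replicate with its
#' condition and the non-coding / coding band powers) and returns
#' per-condition means and dispersions of the power ratio plus a two-sample
#' comparison of the ratios across conditions.
#'
#' @param replicates A tibble with columns `condition` (`"real"` /
#'   `"control"`), `replicate`, `power_nc`, `power_c` (and optionally
#'   `ratio`; recomputed if absent). At least 2 replicates per condition.
#' @return An object of class `chx_power_ratio`: list with `replicates`
#'   (ratio attached), `summary` (per-condition tibble) and `comparison`
#'   (tibble from [compare_distributions()], `NA` statistics when the
#'   ratios are degenerate).
#' @export
power_ratio_experiment <- function(replicates) {
  req <- c("condition", "power_nc", "power_c")
  if (!all(req %in% names(replicates))) {
    stop("replicates must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(replicates$power_c <= 0)) {
    stop("replicate with non-positive coding band power: ratio undefined",
         call. = FALSE)
  }
  replicates <- dplyr::mutate(replicates,
                              ratio = .data$power_nc / .data$power_c)
  counts <- table(replicates$condition)
  if (any(counts < 2)) {
    stop("need at least 2 replicates per condition", call. = FALSE)
  }
  summary <- replicates |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_ratio = mean(.data$ratio),
      sd_ratio = stats::sd(.data$ratio),
      .groups = "drop"
    )
  conds <- sort(unique(replicates$condition), decreasing = TRUE) # real first
  comparison <- compare_distributions(
    replicates$ratio[replicates$condition == conds[1]],
    replicates$ratio[replicates$condition == conds[2]]
  )
  comparison <- dplyr::mutate(comparison,
                              contrast = paste(conds, collapse = " vs "),
                              .before = 1)
  structure(
    list(replicates = replicates, summary = summary, comparison = comparison),
    class = "chx_power_ratio"
  )
}
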