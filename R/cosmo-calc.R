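#' Physical constants used throughout the package
#'
#' Returns the constants the simulations rely on: Planck's constant `h`,
#' the reduced constant `hbar`, the elementary charge `e_charge` (also the
#' eV-to-joule conversion factor), the proton mass `m_p`, and a default
#' Hubble rate `H0` corresponding to 70 km/s/Mpc.
#'
#' @param H0_km_s_Mpc Hubble constant in km/s/Mpc used to derive `H0` in 1/s.
#' @return A named list of positive numerics:
#'   `h` (J s), `hbar` (J s), `e_charge` (C), `m_p` (kg), `H0` (1/s).
#' @examples
#' physical_constants()$hbar
#' @export
physical_constants <- function(H0_km_s_Mpc = 70) {
  stopifnot(is.numeric(H0_km_s_Mpc), H0_km_s_Mpc > 0)
  Mpc_m <- 3.0856775814913673e22
  list(
    h = 6.62607015e-34,
    hbar = 1.0545718e-34,
    e_charge = 1.6021766e-19,
    m_p = 1.6726219e-27,
    H0 = H0_km_s_Mpc * 1e3 / Mpc_m
  )
}

#' Photon energy at a given frequency
#'
#' E = h f, returned in both joules and electron volts.
#'
#' @param f Frequency in Hz (non-negative).
#' @return A one-row tibble with columns `f_hz`, `energy_j`, `energy_ev`.
#' @examples
#' photon_energy(34e9)
#' @export
photon_energy <- function(f) {
  stopifnot(is.numeric(f), all(f >= 0))
  const <- physical_constants()
  e_j <- const$h * f
  tibble::tibble(f_hz = f, energy_j = e_j, energy_ev = e_j / const$e_charge)
}

#' Period of a wave
#'
#' @param f Frequency in Hz, strictly positive.
#' @return Period in seconds, `1 / f`.
#' @examples
#' wave_period(34e9)
#' @export
wave_period <- function(f) {
  stopifnot(is.numeric(f))
  if (any(f <= 0)) {
    stop("wave_period() requires strictly positive frequency", call. = FALSE)
  }
  1 / f
}

#' Cosmological frequency drift of a carrier
#'
#' Linearised redshift drift: over an interval `delta_t` a carrier at `f0`
#' shifts by `f0 * H0 * delta_t`, the fractional drift `H0 * delta_t` expected
#' from cosmic expansion.
#'
#' @param f0 Carrier frequency in Hz.
#' @param delta_t Elapsed time in seconds.
#' @param H0 Hubble rate in 1/s; default from 70 km/s/Mpc.
#' @return Frequency drift in Hz.
#' @examples
#' redshift_drift(34e9, 3 * 3600)
#' @export
redshift_drift <- function(f0, delta_t, H0 = physical_constants()$H0) {
  stopifnot(is.numeric(f0), is.numeric(delta_t), all(f0 >= 0),
            all(delta_t >= 0), H0 >= 0)
  f0 * H0 * delta_t
}

#' Convert electron volts to joules
#'
#' @param E Energy in eV.
#' @return Energy in joules.
#' @examples
#' ev_to_joules(0.1)
#' @export
ev_to_joules <- function(E) {
  stopifnot(is.numeric(E))
  E * physical_constants()$e_charge
}

#' Convert joules to electron volts
#'
#' @param E Energy in joules.
#' @return Energy in eV.
#' @export
joules_to_ev <- function(E) {
  stopifnot(is.numeric(E))
  E / physical_constants()$e_charge
}

#' Time to accumulate an activation energy from a weak per-site flux
#'
#' Under the additive-antenna assumption the total absorbed power of a chain
#' of `n_nucleotides` sites is `flux_per_nt * n_nucleotides`; the time to
#' accumulate `activation_energy` is their quotient.
#'
#' @param activation_energy Energy threshold in joules.
#' @param flux_per_nt Power absorbed per nucleotide in J/s (> 0).
#' @param n_nucleotides Number of nucleotides in the chain (>= 1).
#' @return A one-row tibble with `total_flux_j_s`, `seconds`, `days`.
#' @examples
#' accumulation_time(1.6e-20, 1e-32, 3e6)
#' @export
accumulation_time <- function(activation_energy, flux_per_nt, n_nucleotides) {
  stopifnot(is.numeric(activation_energy), activation_energy >= 0,
            is.numeric(n_nucleotides), n_nucleotides >= 1)
  if (!is.numeric(flux_per_nt) || flux_per_nt <= 0) {
    stop("flux_per_nt must be a positive power in J/s", call. = FALSE)
  }
  total <- flux_per_nt * n_nucleotides
  secs <- activation_energy / total
  tibble::tibble(total_flux_j_s = total, seconds = secs, days = secs / 86400)
}
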