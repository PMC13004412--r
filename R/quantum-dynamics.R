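# Energies enter in eV and are converted to joules at one single point
# (ev_to_joules) before propagation; hbar is in J s. This keeps the
# mixed-unit parameter tables coherent.

#' Specification of a two-block tight-binding Hamiltonian
#'
#' Describes the non-coding and coding chains: site energies drawn uniformly
#' from `diag_energy_range`, nearest-neighbour coupling on the off-diagonal,
#' and a single boundary coupling `g` linking the last non-coding site to the
#' first coding site.
#'
#' @param n_nc,n_c Number of non-coding and coding sites (`n_nc + n_c >= 1`).
#' @param diag_energy_range Two-vector `(lo, hi)` in eV for the site
#'   (binding) energies; default `c(0.01, 0.05)`.
#' @param neighbor_coupling Nearest-neighbour coupling in eV; default 0.025.
#' @param boundary_coupling Inter-block coupling `g` in eV; default 0.01.
#' @param seed Optional integer seed used when the Hamiltonian is realised.
#' @return A list of class `chx_hamiltonian_spec`.
#' @export
hamiltonian_spec <- function(n_nc, n_c,
                             diag_energy_range = c(0.01, 0.05),
                             neighbor_coupling = 0.025,
                             boundary_coupling = 0.01,
                             seed = NULL) {
  stopifnot(n_nc >= 0, n_c >= 0, n_nc + n_c >= 1,
            length(diag_energy_range) == 2,
            diag_energy_range[1] <= diag_energy_range[2])
  structure(
    list(n_nc = as.integer(n_nc), n_c = as.integer(n_c),
         diag_energy_range = diag_energy_range,
         neighbor_coupling = neighbor_coupling,
         boundary_coupling = boundary_coupling, seed = seed),
    class = "chx_hamiltonian_spec"
  )
}

#' Specification of the weak chirped diagonal drive
#'
#' The drive adds `lambda * gain_linear * cos(2*pi*f(t)*t)` to the diagonal
#' of the target block, with instantaneous frequency `f(t) = f0 + k*t` and
#' `gain_linear = 10^(gain_dBi/10)`. The phase is taken literally as
#' `2*pi*(f0 + k*t)*t`; set `integrated_phase = TRUE` for the conventional
#' integrated chirp phase `2*pi*(f0*t + k*t^2/2)`.
#'
#' @param amplitude_ev Drive amplitude lambda in eV. Default 1e-4 eV (the
#'   photon-energy-scale value at 34 GHz); see [drive_presets()] for the
#'   other, mutually inconsistent values quoted for this parameter.
#' @param f0 Base frequency in Hz (>= 0); default 34 GHz.
#' @param chirp_rate Linear frequency drift k in Hz/s; default 0.
#' @param gain_dbi Antenna gain in dBi applied as a linear rescaling of the
#'   amplitude; default 0 (no gain). The fractal-antenna figure is 1.7 dBi.
#' @param target Which sites are driven: `"noncoding_block"` (default) or
#'   `"all"`.
#' @param integrated_phase Use the integrated-phase chirp convention.
#' @return A list of class `chx_drive_spec`.
#' @export
drive_spec <- function(amplitude_ev = 1e-4, f0 = 34e9, chirp_rate = 0,
                       gain_dbi = 0,
                       target = c("noncoding_block", "all"),
                       integrated_phase = FALSE) {
  target <- match.arg(target)
  stopifnot(f0 >= 0)
  structure(
    list(amplitude_ev = amplitude_ev, f0 = f0, chirp_rate = chirp_rate,
         gain_dbi = gain_dbi, target = target,
         integrated_phase = integrated_phase),
    class = "chx_drive_spec"
  )
}

#' Documented presets for the drive amplitude
#'
#' The source parameter tables quote amplitudes that disagree by many orders
#' of magnitude (1e-4 eV justified from the 34 GHz photon energy; 1e-41 eV
#' and a range 1e-5 eV to 1e-31 neV elsewhere). All are exposed here; the
#' package default is 1e-4 eV and no claim is made about which produced any
#' published figure.
#'
#' @return A tibble with columns `preset`, `amplitude_ev`, `note`.
#' @export
drive_presets <- function() {
  tibble::tibble(
    preset = c("photon_energy_scale", "ultraweak", "range_lo", "range_hi"),
    amplitude_ev = c(1e-4, 1e-41, 1e-5, 1e-40),
    note = c(
      "default; justified from the ~1.4e-4 eV photon energy at 34 GHz",
      "as printed in the perturbed-evolution methods; internally inconsistent",
      "low end of the quoted exploratory range",
      "high end (1e-31 neV) of the quoted exploratory range"
    )
  )
}

#' Build one region's tight-binding Hamiltonian
#'
#' Real symmetric tridiagonal matrix in eV: diagonal energies i.i.d. uniform
#' over `spec$diag_energy_range`, super/sub-diagonal equal to
#' `spec$neighbor_coupling`.
#'
#' @param n Number of sites (>= 1).
#' @param spec A [hamiltonian_spec()]; only the energy range and coupling are
#'   used here. If `spec$seed` is non-NULL the draw is seeded.
#' @return An `n x n` numeric matrix (eV).
#' @export
build_region_hamiltonian <- function(n, spec = hamiltonian_spec(n, 0)) {
  stopifnot(n >= 1)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  H <- diag(stats::runif(n, spec$diag_energy_range[1],
                         spec$diag_energy_range[2]), n, n)
  if (n > 1) {
    idx <- cbind(seq_len(n - 1), seq_len(n - 1) + 1)
    H[idx] <- spec$neighbor_coupling
    H[idx[, 2:1, drop = FALSE]] <- spec$neighbor_coupling
  }
  H
}

#' Combine region Hamiltonians with a boundary coupling
#'
#' Block-diagonal embedding of the two chains plus exactly one Hermitian
#' pair of cross terms `g`, `Conj(g)` linking the last site of the first
#' block to the first site of the second.
#'
#' @param H_nc,H_c Square region Hamiltonians (eV). `H_c` may be 0x0.
#' @param g Boundary coupling in eV (may be complex).
#' @return The combined `(n_nc + n_c)` square matrix.
#' @export
build_total_hamiltonian <- function(H_nc, H_c, g = 0.01) {
  n1 <- nrow(H_nc)
  n2 <- if (is.null(H_c)) 0L else nrow(H_c)
  if (n2 == 0 && g != 0) {
    stop("boundary coupling supplied with no second block", call. = FALSE)
  }
  n <- n1 + n2
  cplx <- is.complex(H_nc) || (n2 > 0 && is.complex(H_c)) || is.complex(g)
  H <- matrix(if (cplx) 0 + 0i else 0, n, n)
  H[seq_len(n1), seq_len(n1)] <- H_nc
  if (n2 > 0) {
    H[n1 + seq_len(n2), n1 + seq_len(n2)] <- H_c
    H[n1, n1 + 1] <- g
    H[n1 + 1, n1] <- Conj(g)
  }
  H
}

# Instantaneous drive energy per driven site, in eV.
drive_scalar <- function(t, drive) {
  gain <- 10^(drive$gain_dbi / 10)
  phase <- if (drive$integrated_phase) {
    2 * pi * (drive$f0 * t + drive$chirp_rate * t^2 / 2)
  } else {
    2 * pi * (drive$f0 + drive$chirp_rate * t) * t
  }
  drive$amplitude_ev * gain * cos(phase)
}

# Diagonal of the drive term as a vector (eV).
drive_diag <- function(t, drive, n_nc, n_total) {
  v <- numeric(n_total)
  idx <- if (drive$target == "all") seq_len(n_total) else seq_len(n_nc)
  v[idx] <- drive_scalar(t, drive)
  v
}

#' Time-dependent drive term as a diagonal matrix
#'
#' Diagonal entries `lambda * 10^(gain_dBi/10) * cos(2*pi*f(t)*t)` on the
#' target sites, zero elsewhere.
#'
#' @param t Time in seconds (>= 0).
#' @param drive A [drive_spec()].
#' @param n_nc Number of non-coding (leading) sites.
#' @param n_total Total number of sites.
#' @return An `n_total x n_total` diagonal matrix in eV.
#' @export
drive_term <- function(t, drive, n_nc, n_total) {
  stopifnot(t >= 0, n_nc >= 0, n_total >= n_nc)
  diag(drive_diag(t, drive, n_nc, n_total), n_total, n_total)
}

phase_unwrap <- function(p) {
  if (length(p) < 2) return(p)
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

#' Propagate a site-amplitude vector through time
#'
#' Integrates the time-dependent Schrodinger equation for a tight-binding
#' chain. `"exact_step"` applies the exact one-step unitary of the
#' Hamiltonian frozen at each step time (via eigendecomposition), which
#' conserves norm to machine precision; `"euler"` applies the first-order
#' explicit update followed by renormalization (the renormalization can be
#' switched off to expose the first-order norm drift).
#'
#' A warning is emitted when the largest Hamiltonian energy advances the
#' phase by more than pi radians per step: the dynamics are then
#' undersampled and recorded amplitudes/phases alias. This is the case for
#' the paper-replication parameter set (0.01-0.05 eV energies with
#' dt = 1e-13 s).
#'
#' @param psi0 Complex unit-norm initial state, e.g. from
#'   [encode_site_amplitudes()].
#' @param H_base Hermitian base Hamiltonian in eV (site basis).
#' @param drive Optional [drive_spec()]; `NULL` for free evolution.
#' @param n_nc Number of leading non-coding sites (needed when the drive
#'   targets that block; defaults to all sites).
#' @param dt Time step in seconds (> 0).
#' @param steps Number of steps (>= 1).
#' @param method `"exact_step"` or `"euler"`.
#' @param record_every Record the state every this many steps (default 1);
#'   the initial state is always recorded.
#' @param renormalize Renormalize after each Euler step (default TRUE;
#'   ignored for `"exact_step"`).
#' @return An object of class `chx_trajectory`: list with `times` (s),
#'   `amplitudes` and `phases` (T x N matrices), `norm_log` (norm before any
#'   renormalization at each recorded step), `n_nc`, `dt`, `method`.
#' @export
propagate <- function(psi0, H_base, drive = NULL, n_nc = length(psi0),
                      dt, steps, method = c("exact_step", "euler"),
                      record_every = 1, renormalize = TRUE) {
  method <- match.arg(method)
  n <- length(psi0)
  stopifnot(dt > 0, steps >= 1, record_every >= 1)
  if (nrow(H_base) != n || ncol(H_base) != n) {
    stop("dimension mismatch: state has ", n, " sites but H is ",
         nrow(H_base), "x", ncol(H_base), call. = FALSE)
  }
  const <- physical_constants()
  to_j <- const$e_charge
  hbar <- const$hbar

  max_e <- max(abs(H_base)) +
    if (is.null(drive)) 0 else abs(drive$amplitude_ev) * 10^(drive$gain_dbi / 10)
  if (max_e * to_j * dt / hbar > pi) {
    warning("per-step phase ", signif(max_e * to_j * dt / hbar, 3),
            " rad exceeds pi: this time step undersamples the dynamics ",
            "and recorded phases alias", call. = FALSE)
  }

  n_rec <- floor(steps / record_every) + 1
  amps <- matrix(NA_real_, n_rec, n)
  phases <- matrix(NA_real_, n_rec, n)
  norms <- numeric(n_rec)
  times <- numeric(n_rec)

  psi <- as.complex(psi0)
  amps[1, ] <- Mod(psi); phases[1, ] <- Arg(psi); norms[1] <- sqrt(sum(Mod(psi)^2))
  rec <- 1

  static_u <- NULL
  if (method == "exact_step" && is.null(drive)) {
    es <- eigen(H_base * to_j, symmetric = TRUE)
    static_u <- es$vectors %*% (exp(-1i * es$values * dt / hbar) *
                                  Conj(t(es$vectors)))
  }

  for (s in seq_len(steps)) {
    t_n <- (s - 1) * dt
    if (method == "exact_step") {
      if (is.null(static_u)) {
        H_t <- H_base
        diag(H_t) <- diag(H_t) + drive_diag(t_n, drive, n_nc, n)
        es <- eigen(H_t * to_j, symmetric = TRUE)
        psi <- es$vectors %*% (exp(-1i * es$values * dt / hbar) *
                                 (Conj(t(es$vectors)) %*% psi))
      } else {
        psi <- static_u %*% psi
      }
      psi <- as.vector(psi)
    } else {
      H_t <- H_base
      if (!is.null(drive)) {
        diag(H_t) <- diag(H_t) + drive_diag(t_n, drive, n_nc, n)
      }
      psi <- psi - (1i * dt / hbar) * as.vector((H_t * to_j) %*% psi)
      if (!all(is.finite(Re(psi)) & is.finite(Im(psi)))) {
        stop("euler update produced non-finite state at step ", s,
             call. = FALSE)
      }
      if (renormalize) {
        nrm <- sqrt(sum(Mod(psi)^2))
        if (s %% record_every == 0) norms[rec + 1] <- nrm
        psi <- psi / nrm
      }
    }
    if (s %% record_every == 0) {
      rec <- rec + 1
      times[rec] <- s * dt
      amps[rec, ] <- Mod(psi)
      phases[rec, ] <- Arg(psi)
      if (norms[rec] == 0) norms[rec] <- sqrt(sum(Mod(psi)^2))
    }
  }

  structure(
    list(times = times[seq_len(rec)],
         amplitudes = amps[seq_len(rec), , drop = FALSE],
         phases = phases[seq_len(rec), , drop = FALSE],
         norm_log = norms[seq_len(rec)],
         n_nc = n_nc, dt = dt, method = method),
    class = "chx_trajectory"
  )
}

#' Per-region amplitude and phase series of a trajectory
#'
#' Mean site amplitude per block at each recorded time, and the block mean
#' of the per-site unwrapped phases (each site's phase series is unwrapped
#' over time before averaging, avoiding wrap-around artefacts).
#'
#' @param traj A `chx_trajectory` from [propagate()].
#' @param n_nc Number of leading non-coding sites; defaults to the value
#'   recorded in the trajectory.
#' @return A tibble with `time`, `block` (`"noncoding"`/`"coding"`),
#'   `mean_amplitude`, `mean_phase` (unwrapped radians).
#' @export
region_series <- function(traj, n_nc = traj$n_nc) {
  n <- ncol(traj$amplitudes)
  stopifnot(n_nc >= 0, n_nc <= n)
  blocks <- list(noncoding = seq_len(n_nc),
                 coding = if (n_nc < n) (n_nc + 1):n else integer(0))
  purrr::imap_dfr(blocks, function(idx, name) {
    if (length(idx) == 0) return(NULL)
    unwrapped <- apply(traj$phases[, idx, drop = FALSE], 2, phase_unwrap)
    tibble::tibble(
      time = traj$times,
      block = name,
      mean_amplitude = rowMeans(traj$amplitudes[, idx, drop = FALSE]),
      mean_phase = rowMeans(matrix(unwrapped, nrow = length(traj$times)))
    )
  })
}
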