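# One-dimensional driven double-well proton dynamics per base pair,
# propagated with Strang (split-operator) steps: half kinetic step in
# momentum space, full potential step in position space, half kinetic step.

#' Spatial grid for the wavepacket simulations
#'
#' Uniform periodic grid of `n_points` (a power of two, for the spectral
#' kinetic step) spanning `[x_min, x_max)`; with the symmetric default
#' domain the point `x = 0` lies exactly on the grid.
#'
#' @param n_points Number of grid points, a power of two (default 512).
#' @param x_min,x_max Domain bounds in meters (defaults -5e-10, 5e-10).
#' @return A list of class `chx_grid`: `x` (m), `dx` (m), `k` (angular
#'   wavenumbers, 1/m, FFT ordering), `n_points`, `x_min`, `x_max`.
#' @export
grid_spec <- function(n_points = 512, x_min = -5e-10, x_max = 5e-10) {
  stopifnot(n_points >= 8, x_max > x_min)
  if (bitwAnd(n_points, n_points - 1L) != 0) {
    stop("n_points must be a power of two for the spectral kinetic step",
         call. = FALSE)
  }
  dx <- (x_max - x_min) / n_points
  x <- x_min + (seq_len(n_points) - 1) * dx
  k <- 2 * pi / (n_points * dx) *
    c(0:(n_points / 2 - 1), -(n_points / 2):-1)
  structure(list(x = x, dx = dx, k = k, n_points = as.integer(n_points),
                 x_min = x_min, x_max = x_max),
            class = "chx_grid")
}

#' Quartic double-well potential on a grid
#'
#' `V(x) = V0 * ((x/a)^4 - 2*(x/a)^2 + 1)`: minima with `V = 0` at
#' `x = +/- a` and a barrier of height `V0` at `x = 0`.
#'
#' @param grid A [grid_spec()].
#' @param v0_ev Barrier height in eV (> 0); 0.065 eV for A-T pairs, 0.108 eV
#'   for G-C pairs.
#' @param a Characteristic half-separation of the wells in meters
#'   (default 1e-10); `2a` must fit in the domain.
#' @return Potential values in joules, one per grid point.
#' @export
quartic_potential <- function(grid, v0_ev, a = 1e-10) {
  stopifnot(inherits(grid, "chx_grid"), v0_ev > 0, a > 0)
  if (2 * a >= grid$x_max - grid$x_min) {
    stop("well separation 2a does not fit in the spatial domain",
         call. = FALSE)
  }
  u <- grid$x / a
  ev_to_joules(v0_ev) * (u^4 - 2 * u^2 + 1)
}

#' Normalized Gaussian wavepacket
#'
#' `psi(x) = (1/(pi*sigma^2))^(1/4) * exp(-(x - x0)^2 / (2*sigma^2))`,
#' renormalized on the discrete grid so that `sum(|psi|^2) * dx = 1`.
#'
#' @param grid A [grid_spec()].
#' @param x0 Packet centre in meters (within the grid); the left well `-a`
#'   for the tunneling runs.
#' @param sigma Standard deviation in meters (> 2*dx); default 5e-11.
#' @return Complex vector of grid values.
#' @export
gaussian_packet <- function(grid, x0 = -1e-10, sigma = 5e-11) {
  stopifnot(inherits(grid, "chx_grid"))
  if (x0 < grid$x_min || x0 > grid$x_max) {
    stop("packet centre outside the grid", call. = FALSE)
  }
  if (sigma <= 2 * grid$dx) {
    stop("sigma must exceed 2*dx for the grid to resolve the packet",
         call. = FALSE)
  }
  psi <- (1 / (pi * sigma^2))^0.25 * exp(-(grid$x - x0)^2 / (2 * sigma^2))
  psi <- psi / sqrt(sum(Mod(psi)^2) * grid$dx)
  as.complex(psi)
}

#' Drive specification for the tunneling simulations
#'
#' The external tilt `V_ext(x, t) = (lambda_pert + xi(t)) * cos(2*pi*f(t)*t)
#' * (x/a)` with `lambda_pert = e * E0 * a * 10^(gain_dBi/10)` and zero-mean
#' Gaussian noise `xi(t)` of standard deviation
#' `noise_amplitude * lambda_pert` (the dimensionless noise amplitude scales
#' the drive; an absolute noise level in joules can be given instead).
#' The frequency either drifts linearly, `f(t) = f0 + k*t` (`mode =
#' "chirp"`, default, with `k` chosen so the drift accumulates `delta_f`
#' over 3 hours), or is statically shifted, `f = f0 + delta_f`
#' (`mode = "static"`).
#'
#' @param E0 Electric field amplitude in V/m (default 1e-6).
#' @param gain_dbi Antenna gain in dBi (default 1.7).
#' @param f0 Base frequency in Hz (default 34e9).
#' @param delta_f Total frequency shift in Hz (default 8e-4, the
#'   redshift-drift figure over 3 hours at 34 GHz).
#' @param chirp_rate Drift rate in Hz/s; default `delta_f / 10800`.
#' @param mode `"chirp"` or `"static"`.
#' @param noise_amplitude Dimensionless noise scale (>= 0, default 0.05).
#' @param noise_sd_j Absolute noise standard deviation in joules; overrides
#'   `noise_amplitude` when non-NULL.
#' @param a Length scale of the tilt in meters (default 1e-10).
#' @param seed Optional integer seed for the per-step noise draws.
#' @return A list of class `chx_tunnel_drive` including the derived
#'   `lambda_pert` in joules.
#' @export
tunnel_drive_spec <- function(E0 = 1e-6, gain_dbi = 1.7, f0 = 34e9,
                              delta_f = 8e-4,
                              chirp_rate = delta_f / 10800,
                              mode = c("chirp", "static"),
                              noise_amplitude = 0.05, noise_sd_j = NULL,
                              a = 1e-10, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(noise_amplitude >= 0, f0 >= 0, a > 0)
  lambda <- physical_constants()$e_charge * E0 * a * 10^(gain_dbi / 10)
  structure(
    list(E0 = E0, gain_dbi = gain_dbi, f0 = f0, delta_f = delta_f,
         chirp_rate = chirp_rate, mode = mode,
         noise_amplitude = noise_amplitude, noise_sd_j = noise_sd_j,
         lambda_pert = lambda, a = a, seed = seed),
    class = "chx_tunnel_drive"
  )
}

#' External driving potential at one instant
#'
#' @param t Time in seconds (>= 0).
#' @param grid A [grid_spec()].
#' @param drive A [tunnel_drive_spec()].
#' @param a Tilt length scale in meters (defaults to the drive's).
#' @param noise_draw Realisation of the noise term xi(t) in joules
#'   (default 0).
#' @return Potential values in joules per grid point.
#' @export
external_potential <- function(t, grid, drive, a = drive$a, noise_draw = 0) {
  stopifnot(t >= 0, inherits(grid, "chx_grid"))
  f_inst <- if (drive$mode == "chirp") {
    drive$f0 + drive$chirp_rate * t
  } else {
    drive$f0 + drive$delta_f
  }
  (drive$lambda_pert + noise_draw) * cos(2 * pi * f_inst * t) * (grid$x / a)
}

# Half-step kinetic phase factor in momentum space.
kinetic_half_factor <- function(grid, dt, mass, hbar) {
  exp(-1i * hbar * grid$k^2 * dt / (4 * mass))
}

#' One Strang split-operator step
#'
#' Applies `exp(-i*T*dt/2) * exp(-i*V*dt) * exp(-i*T*dt/2)` with the kinetic
#' factor in momentum space (FFT) and the potential factor pointwise in
#' position space. Both factors are unitary, so the discrete norm is
#' preserved.
#'
#' @param psi Complex wavefunction on the grid.
#' @param V_total Total potential in joules per grid point (well + drive).
#' @param dt Time step in seconds (> 0).
#' @param mass Particle mass in kg (default: proton mass).
#' @param grid The [grid_spec()] `psi` lives on.
#' @return The advanced wavefunction.
#' @export
split_operator_step <- function(psi, V_total, dt,
                                mass = physical_constants()$m_p, grid) {
  stopifnot(dt > 0, length(psi) == grid$n_points,
            length(V_total) == grid$n_points)
  hbar <- physical_constants()$hbar
  kin <- kinetic_half_factor(grid, dt, mass, hbar)
  pot <- exp(-1i * V_total * dt / hbar)
  psi <- stats::fft(kin * stats::fft(psi), inverse = TRUE) / grid$n_points
  psi <- pot * psi
  psi <- stats::fft(kin * stats::fft(psi), inverse = TRUE) / grid$n_points
  if (!all(is.finite(Re(psi)) & is.finite(Im(psi)))) {
    stop("non-finite wavefunction after split-operator step", call. = FALSE)
  }
  psi
}

#' Probability of finding the particle in the right well
#'
#' Discrete version of the integral of `|psi|^2` over `x >= 0`, with the
#' grid point at exactly `x = 0` given half weight to remove a grid-parity
#' bias.
#'
#' @param psi Complex wavefunction.
#' @param grid Its [grid_spec()].
#' @param norm_tol Error if the discrete norm deviates from 1 by more than
#'   this (default 1e-6).
#' @return A probability in `[0, 1]`.
#' @export
right_well_probability <- function(psi, grid, norm_tol = 1e-6) {
  dens <- Mod(psi)^2 * grid$dx
  total <- sum(dens)
  if (abs(total - 1) > norm_tol) {
    stop("wavefunction is not normalized (norm^2 = ", signif(total, 8), ")",
         call. = FALSE)
  }
  w <- as.numeric(grid$x > 0) + 0.5 * as.numeric(grid$x == 0)
  sum(w * dens) / total
}

# Barrier height (eV) by base-pair type; A-T and T-A share parameters, as do
# G-C and C-G.
base_pair_v0 <- c(AT = 0.065, TA = 0.065, GC = 0.108, CG = 0.108)

#' Base-pair label for one nucleotide via the complement rule
#'
#' @param base One of `A, C, G, T`.
#' @return `"AT"`, `"TA"`, `"GC"` or `"CG"`.
#' @export
base_pair_of <- function(base) {
  switch(base,
    A = "AT", T = "TA", G = "GC", C = "CG",
    stop("no base pair defined for '", base, "'", call. = FALSE)
  )
}

#' Simulate driven, noisy proton tunneling for one base pair
#'
#' Propagates a Gaussian packet starting in the left well of the pair's
#' quartic double well under the external chirped drive plus per-step i.i.d.
#' Gaussian noise (stochastic resonance), and records the right-well
#' probability over time. The same seed reproduces the trace bit for bit.
#'
#' @param pair Base-pair type: `"AT"`, `"TA"`, `"GC"` or `"CG"`.
#' @param drive A [tunnel_drive_spec()]; set `E0 = 0` (and
#'   `noise_amplitude = 0`) for undriven dynamics.
#' @param grid A [grid_spec()].
#' @param dt Time step in seconds (default 1e-15).
#' @param steps Number of steps (default 10000, the desk-scale profile; the
#'   full-scale profile uses 1e5 steps on a 512-point grid).
#' @param record_every Record the trace every this many steps (default 10).
#' @param sigma,x0 Initial packet width and centre; defaults 5e-11 m and the
#'   left well `-a`.
#' @param a Well half-separation in meters (default 1e-10).
#' @return A tibble of class `chx_tunneling_trace` with columns `time` and
#'   `p_right`, and attributes `pair`, `v0_ev`, `seed`, `dt`.
#' @export
simulate_base_pair <- function(pair, drive = tunnel_drive_spec(),
                               grid = grid_spec(256), dt = 1e-15,
                               steps = 10000, record_every = 10,
                               sigma = 5e-11, x0 = -a, a = 1e-10) {
  stopifnot(pair %in% names(base_pair_v0), steps >= 1, record_every >= 1)
  v0 <- base_pair_v0[[pair]]
  V_well <- quartic_potential(grid, v0, a)
  psi <- gaussian_packet(grid, x0 = x0, sigma = sigma)

  hbar <- physical_constants()$hbar
  mass <- physical_constants()$m_p
  kin <- kinetic_half_factor(grid, dt, mass, hbar)
  pot_well <- exp(-1i * V_well * dt / hbar)
  tilt <- grid$x / a

  noise_sd <- if (!is.null(drive$noise_sd_j)) {
    drive$noise_sd_j
  } else {
    drive$noise_amplitude * drive$lambda_pert
  }
  if (!is.null(drive$seed)) set.seed(drive$seed)
  xi <- if (noise_sd > 0) stats::rnorm(steps, 0, noise_sd) else numeric(steps)

  n_rec <- floor(steps / record_every) + 1
  times <- numeric(n_rec)
  p_r <- numeric(n_rec)
  p_r[1] <- right_well_probability(psi, grid)
  rec <- 1
  n <- grid$n_points

  for (s in seq_len(steps)) {
    t_n <- (s - 1) * dt
    f_inst <- if (drive$mode == "chirp") {
      drive$f0 + drive$chirp_rate * t_n
    } else {
      drive$f0 + drive$delta_f
    }
    coef <- (drive$lambda_pert + xi[s]) * cos(2 * pi * f_inst * t_n)
    pot <- pot_well * exp((-1i * coef * dt / hbar) * tilt)
    psi <- stats::fft(kin * stats::fft(psi), inverse = TRUE) / n
    psi <- pot * psi
    psi <- stats::fft(kin * stats::fft(psi), inverse = TRUE) / n
    if (s %% record_every == 0) {
      rec <- rec + 1
      times[rec] <- s * dt
      p_r[rec] <- right_well_probability(psi, grid, norm_tol = 1e-5)
    }
  }

  out <- tibble::tibble(time = times[seq_len(rec)], p_right = p_r[seq_len(rec)])
  class(out) <- c("chx_tunneling_trace", class(out))
  attr(out, "pair") <- pair
  attr(out, "v0_ev") <- v0
  attr(out, "seed") <- drive$seed
  attr(out, "dt") <- dt
  out
}

#' Region-level tunneling experiment on real and control segments
#'
#' Runs one tunneling simulation per base pair of the non-coding and coding
#' segments of each condition (each nucleotide forms its pair by the
#' complement rule), summarises each base pair by its time-averaged
#' right-well probability, and compares coding against non-coding per
#' condition with paired and Welch t tests. Seeds are derived
#' deterministically from `base_seed` per condition, region and position.
#'
#' @param real_segments List with character elements `noncoding` and
#'   `coding` (e.g. from [extract_window()]).
#' @param control_segments Same structure, built from a single non-coding
#'   stretch falsely split in two (see [make_control()]).
#' @param drive A [tunnel_drive_spec()]; its seed field is overridden per
#'   simulation.
#' @param grid,dt,steps,record_every Passed to [simulate_base_pair()].
#' @param base_seed Root seed for the per-simulation noise streams.
#' @return An object of class `chx_tunneling_experiment`: list with
#'   `per_pair` (tibble: condition, region, position, base, pair, v0_ev,
#'   seed, mean_p_right, max_p_right) and `tests` (per-condition paired and
#'   Welch t comparisons of coding vs non-coding mean probabilities).
#' @export
region_tunneling_experiment <- function(real_segments, control_segments,
                                        drive = tunnel_drive_spec(),
                                        grid = grid_spec(256), dt = 1e-15,
                                        steps = 10000, record_every = 10,
                                        base_seed = 1) {
  run_segment <- function(seq, condition, region, seed0) {
    bases <- strsplit(seq, "")[[1]]
    bases <- bases[bases != "N"]
    if (length(bases) == 0) {
      stop("empty ", condition, " ", region, " segment", call. = FALSE)
    }
    purrr::imap_dfr(bases, function(b, i) {
      pair <- base_pair_of(b)
      seed_i <- (seed0 + i) %% 2147483647L
      d <- drive
      d$seed <- seed_i
      tr <- simulate_base_pair(pair, d, grid, dt, steps, record_every)
      tibble::tibble(
        condition = condition, region = region, position = i,
        base = b, pair = pair, v0_ev = attr(tr, "v0_ev"), seed = seed_i,
        mean_p_right = mean(tr$p_right), max_p_right = max(tr$p_right)
      )
    })
  }

  per_pair <- dplyr::bind_rows(
    run_segment(real_segments$noncoding, "real", "noncoding", base_seed),
    run_segment(real_segments$coding, "real", "coding", base_seed + 10000L),
    run_segment(control_segments$noncoding, "control", "noncoding",
                base_seed + 20000L),
    run_segment(control_segments$coding, "control", "coding",
                base_seed + 30000L)
  )

  tests <- purrr::map_dfr(unique(per_pair$condition), function(cond) {
    nc <- per_pair$mean_p_right[per_pair$condition == cond &
                                  per_pair$region == "noncoding"]
    cc <- per_pair$mean_p_right[per_pair$condition == cond &
                                  per_pair$region == "coding"]
    k <- min(length(nc), length(cc))
    diffs <- cc[seq_len(k)] - nc[seq_len(k)]
    paired <- if (stats::sd(diffs) == 0) {
      # degenerate pairing (e.g. duplicated-sequence control at equal seeds)
      list(statistic = if (all(diffs == 0)) 0 else NA_real_,
           p.value = NA_real_)
    } else {
      stats::t.test(diffs)
    }
    welch <- compare_distributions(cc, nc)
    tibble::tibble(
      condition = cond, n_pairs = k,
      paired_t = unname(paired$statistic), paired_p = paired$p.value,
      welch_t = welch$welch_t, welch_p = welch$t_pvalue,
      mannwhitney_U = welch$mannwhitney_U, U_pvalue = welch$U_pvalue
    )
  })

  structure(list(per_pair = per_pair, tests = tests,
                 base_seed = base_seed),
            class = "chx_tunneling_experiment")
}
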