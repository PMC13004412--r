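e_ch <- physical_constants()$e_charge
hbar <- physical_constants()$hbar

test_that("region Hamiltonian is symmetric tridiagonal with bounded diagonal", {
  spec <- hamiltonian_spec(3, 0, seed = 5)
  h1 <- build_region_hamiltonian(1, spec)
  expect_true(h1[1, 1] >= 0.01 && h1[1, 1] <= 0.05)

  h3 <- build_region_hamiltonian(3, spec)
  expect_equal(h3, t(h3))
  expect_equal(h3[cbind(1:2, 2:3)], c(0.025, 0.025))
  expect_equal(h3[1, 3], 0)
  expect_true(all(diag(h3) >= 0.01 & diag(h3) <= 0.05))
  expect_error(build_region_hamiltonian(0, spec))
})

test_that("total Hamiltonian couples only the boundary sites", {
  spec <- hamiltonian_spec(3, 3, seed = 1)
  h_nc <- build_region_hamiltonian(3, spec)
  h_c <- build_region_hamiltonian(3, spec)

  h0 <- build_total_hamiltonian(h_nc, h_c, g = 0)
  expect_equal(h0[1:3, 4:6], matrix(0, 3, 3))

  h <- build_total_hamiltonian(h_nc, h_c, g = 0.01)
  expect_equal(h[3, 4], 0.01)
  expect_equal(h[4, 3], 0.01)
  cross <- h[1:3, 4:6]
  cross[3, 1] <- 0
  expect_equal(cross, matrix(0, 3, 3))

  hc <- build_total_hamiltonian(h_nc + 0i, h_c + 0i, g = 0.01 + 0.002i)
  expect_equal(hc, Conj(t(hc)))
  expect_error(build_total_hamiltonian(h_nc, NULL, g = 0.01), "no second")
})

test_that("drive term is diagonal on the target block with gain rescaling", {
  drv <- drive_spec(amplitude_ev = 2e-4, f0 = 1e9, gain_dbi = 1.7)
  gain <- 10^0.17
  d0 <- drive_term(0, drv, n_nc = 2, n_total = 4)
  expect_equal(diag(d0), c(2e-4 * gain, 2e-4 * gain, 0, 0))
  expect_equal(d0[1, 2], 0)

  expect_equal(drive_term(0, drive_spec(amplitude_ev = 0), 2, 4),
               matrix(0, 4, 4))
  # k = 0, t = 1/(2 f0): cos(pi) = -1
  d_half <- drive_term(1 / (2 * 1e9), drv, 2, 4)
  expect_equal(diag(d_half)[1], -2e-4 * gain, tolerance = 1e-9)
})

test_that("zero Hamiltonian leaves the state constant", {
  psi0 <- encode_site_amplitudes("ATCA")
  tr <- propagate(psi0, matrix(0, 4, 4), dt = 1e-15, steps = 50,
                  method = "exact_step")
  expect_equal(tr$amplitudes[nrow(tr$amplitudes), ], Mod(psi0),
               tolerance = 1e-12)
  expect_equal(tr$phases[nrow(tr$phases), ], Arg(psi0), tolerance = 1e-12)
})

test_that("single-site evolution follows the closed-form phase", {
  E <- 0.001            # eV; per-step phase ~0.0015 rad at dt = 1e-18
  dt <- 1e-18
  tr <- propagate(c(1 + 0i), matrix(E, 1, 1), dt = dt, steps = 1000,
                  method = "exact_step", record_every = 1000)
  t_end <- 1000 * dt
  expected <- -E * e_ch * t_end / hbar
  expected <- ((expected + pi) %% (2 * pi)) - pi
  expect_equal(tr$phases[2, 1], expected, tolerance = 1e-9)
  expect_equal(tr$amplitudes[2, 1], 1, tolerance = 1e-12)
})

test_that("two-site Rabi transfer matches sin^2(g t / hbar)", {
  g <- 1e-4
  H <- matrix(c(0, g, g, 0), 2, 2)
  gJ <- g * e_ch
  t_full <- pi * hbar / (2 * gJ)
  steps <- 400
  dt <- t_full / steps
  tr <- propagate(c(1 + 0i, 0 + 0i), H, dt = dt, steps = steps,
                  method = "exact_step", record_every = 40)
  occ2 <- tr$amplitudes[, 2]^2
  expect_equal(occ2, sin(gJ * tr$times / hbar)^2, tolerance = 1e-9)
  expect_equal(occ2[length(occ2)], 1, tolerance = 1e-9)  # full transfer
})

test_that("exact stepping conserves norm over 1e5 steps", {
  spec <- hamiltonian_spec(4, 0, seed = 2)
  H <- build_region_hamiltonian(4, spec)
  psi0 <- encode_site_amplitudes("ATCA")
  tr <- propagate(psi0, H, dt = 1e-18, steps = 1e5, method = "exact_step",
                  record_every = 1e4)
  expect_true(all(abs(tr$norm_log - 1) < 1e-9))
})

test_that("euler without renormalization drifts upward, worse for larger dt", {
  H <- matrix(c(0.002, 0.001, 0.001, 0.002), 2, 2)
  run <- function(dt) {
    tr <- propagate(c(1 + 0i, 0i), H, dt = dt, steps = 200, method = "euler",
                    renormalize = FALSE, record_every = 200)
    tr$norm_log[2] - 1
  }
  drift1 <- run(1e-16)
  drift2 <- run(2e-16)
  expect_gt(drift1, 0)
  expect_gt(drift2, drift1)
})

test_that("euler agrees with exact stepping to first order (O(dt^2) gap)", {
  spec <- hamiltonian_spec(3, 0, seed = 9)
  H <- build_region_hamiltonian(3, spec)
  psi0 <- encode_site_amplitudes("ATC")
  gap <- function(dt) {
    a <- propagate(psi0, H, dt = dt, steps = 100, method = "exact_step",
                   record_every = 100)
    b <- propagate(psi0, H, dt = dt, steps = 100, method = "euler",
                   record_every = 100)
    max(Mod(a$amplitudes[2, ] * exp(1i * a$phases[2, ]) -
              b$amplitudes[2, ] * exp(1i * b$phases[2, ])))
  }
  dt0 <- 1e-17        # per-step phase ~7.6e-4 rad, well under 0.01
  r <- gap(dt0) / gap(dt0 / 2)
  expect_gt(r, 3)
  expect_lt(r, 5)
})

test_that("amplitude crosses the block boundary only through the coupling", {
  spec <- hamiltonian_spec(3, 3, seed = 4)
  h_nc <- build_region_hamiltonian(3, spec)
  h_c <- build_region_hamiltonian(3, spec)
  psi0 <- c(encode_site_amplitudes("ATC"), rep(0 + 0i, 3))

  h_free <- build_total_hamiltonian(h_nc, h_c, g = 0)
  tr <- propagate(psi0, h_free, dt = 1e-17, steps = 500,
                  method = "exact_step", record_every = 100)
  expect_lt(max(rowSums(tr$amplitudes[, 4:6]^2)), 1e-12)

  h_cpl <- build_total_hamiltonian(h_nc, h_c, g = 0.01)
  tr2 <- propagate(psi0, h_cpl, dt = 1e-17, steps = 500,
                   method = "exact_step", record_every = 100)
  expect_gt(max(rowSums(tr2$amplitudes[, 4:6]^2)), 1e-6)
})

test_that("a paper-scale time step triggers the undersampling warning", {
  H <- matrix(0.05, 1, 1)
  expect_warning(
    propagate(c(1 + 0i), H, dt = 1e-13, steps = 2, method = "exact_step"),
    "undersamples"
  )
})

test_that("region series aggregates blocks correctly", {
  spec <- hamiltonian_spec(2, 2, seed = 6)
  H <- build_total_hamiltonian(build_region_hamiltonian(2, spec),
                               build_region_hamiltonian(2, spec), 0.01)
  psi0 <- rep(0.5 + 0i, 4)
  tr <- propagate(psi0, H, n_nc = 2, dt = 1e-17, steps = 100,
                  method = "exact_step", record_every = 10)
  rs <- region_series(tr)
  expect_setequal(unique(rs$block), c("noncoding", "coding"))
  expect_true(all(rs$mean_amplitude >= 0 & rs$mean_amplitude <= 1))
  # identical sites: block mean equals the common site value at t = 0
  expect_equal(rs$mean_amplitude[rs$time == 0], c(0.5, 0.5))

  # single-site blocks reproduce that site's series
  tr1 <- propagate(psi0[1:2] / sqrt(0.5), H[1:2, 1:2], n_nc = 1, dt = 1e-17,
                   steps = 50, method = "exact_step", record_every = 10)
  rs1 <- region_series(tr1)
  expect_equal(rs1$mean_amplitude[rs1$block == "noncoding"],
               tr1$amplitudes[, 1])
})
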