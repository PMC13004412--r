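test_that("quartic double well has the defining geometry", {
  # domain chosen so that 0, +/-a and 2a fall exactly on grid points
  gr <- grid_spec(512, -5.12e-10, 5.12e-10)
  a <- 1e-10
  v0 <- 0.065
  V <- quartic_potential(gr, v0, a)
  v_at <- function(x) V[which.min(abs(gr$x - x))]
  expect_lt(abs(v_at(a)), 1e-30)
  expect_lt(abs(v_at(-a)), 1e-30)
  expect_equal(v_at(0), ev_to_joules(v0), tolerance = 1e-12)
  expect_equal(v_at(2 * a), 9 * ev_to_joules(v0), tolerance = 1e-12)
  expect_error(quartic_potential(gr, v0, a = 6e-10), "domain")
  expect_error(grid_spec(100), "power of two")
})

test_that("gaussian packet is normalized, centred, and left-well localised", {
  gr <- grid_spec(256)
  sigma <- 5e-11
  a <- 1e-10
  psi <- gaussian_packet(gr, x0 = -a, sigma = sigma)
  expect_equal(sum(Mod(psi)^2) * gr$dx, 1, tolerance = 1e-9)
  expect_lt(abs(gr$x[which.max(Mod(psi))] - (-a)), gr$dx)
  p_r <- right_well_probability(psi, gr)
  expect_lt(p_r, 0.01)
  # Gaussian tail integral: density sd is sigma/sqrt(2)
  expect_equal(p_r, stats::pnorm(-a / (sigma / sqrt(2))), tolerance = 0.02)
  expect_error(gaussian_packet(gr, x0 = 1e-9), "outside")
  expect_error(gaussian_packet(gr, sigma = 1e-12), "resolve")
})

test_that("external drive tilt has the defined amplitude, gain and zeros", {
  gr <- grid_spec(64)
  a <- 1e-10
  off <- tunnel_drive_spec(E0 = 0, noise_amplitude = 0)
  expect_equal(external_potential(1e-12, gr, off), rep(0, 64))

  drv <- tunnel_drive_spec(E0 = 1e-6, gain_dbi = 0)
  v0 <- external_potential(0, gr, drv)
  expect_equal(v0[which.min(abs(gr$x - a))],
               drv$lambda_pert * (gr$x[which.min(abs(gr$x - a))] / a),
               tolerance = 1e-30)
  expect_true(all(abs(v0 - drv$lambda_pert * gr$x / a) < 1e-40))

  gained <- tunnel_drive_spec(E0 = 1e-6, gain_dbi = 1.7)
  expect_equal(gained$lambda_pert / drv$lambda_pert, 10^0.17,
               tolerance = 1e-12)
})

test_that("free-packet spreading matches the analytic Gaussian law", {
  gr <- grid_spec(256)
  const <- physical_constants()
  sigma <- 3e-11
  psi <- gaussian_packet(gr, 0, sigma)
  dt <- 1e-16
  V0 <- rep(0, gr$n_points)
  for (s in 1:1000) psi <- split_operator_step(psi, V0, dt, const$m_p, gr)
  t <- 1000 * dt
  s0 <- sigma / sqrt(2)                       # density sd at t = 0
  s_t <- s0 * sqrt(1 + (const$hbar * t / (2 * const$m_p * s0^2))^2)
  xm <- sum(gr$x * Mod(psi)^2 * gr$dx)
  s_num <- sqrt(sum((gr$x - xm)^2 * Mod(psi)^2 * gr$dx))
  expect_equal(s_num / s_t, 1, tolerance = 0.005)
})

test_that("coherent-state oscillation in a harmonic well follows Ehrenfest", {
  gr <- grid_spec(256)
  const <- physical_constants()
  sigma <- 4e-11                              # ground-state width
  omega <- const$hbar / (const$m_p * sigma^2)
  x0 <- 1.2e-10
  V <- 0.5 * const$m_p * omega^2 * gr$x^2
  psi <- gaussian_packet(gr, x0, sigma)
  period <- 2 * pi / omega
  steps <- 1600
  dt <- period / steps
  mean_x <- function(p) sum(gr$x * Mod(p)^2 * gr$dx)
  for (s in 1:(steps / 4)) psi <- split_operator_step(psi, V, dt, const$m_p, gr)
  expect_equal(mean_x(psi) / x0, cos(omega * period / 4), tolerance = 0.01)
  for (s in 1:(3 * steps / 4)) psi <- split_operator_step(psi, V, dt, const$m_p, gr)
  expect_equal(mean_x(psi) / x0, 1, tolerance = 0.01)   # back after a period
})

test_that("split-operator stepping is unitary over 1e5 steps", {
  gr <- grid_spec(64)
  const <- physical_constants()
  V <- quartic_potential(gr, 0.065)
  psi <- gaussian_packet(gr, -1e-10, 5e-11)
  hbar <- const$hbar
  kinetic <- exp(-1i * hbar * gr$k^2 * 1e-16 / (4 * const$m_p))
  pot <- exp(-1i * V * 1e-16 / hbar)
  n <- gr$n_points
  for (s in 1:1e5) {
    psi <- stats::fft(kinetic * stats::fft(psi), inverse = TRUE) / n
    psi <- pot * psi
    psi <- stats::fft(kinetic * stats::fft(psi), inverse = TRUE) / n
  }
  expect_equal(sum(Mod(psi)^2) * gr$dx, 1, tolerance = 1e-7)
})

test_that("right-well probability respects symmetry and complementarity", {
  gr <- grid_spec(256)
  centered <- gaussian_packet(gr, 0, 4e-11)
  expect_equal(right_well_probability(centered, gr), 0.5, tolerance = 1e-6)
  right <- gaussian_packet(gr, 1e-10, 5e-11)
  expect_gt(right_well_probability(right, gr), 0.99)
  left <- gaussian_packet(gr, -1e-10, 5e-11)
  # complement: the mirrored packet carries the complementary weight
  expect_equal(right_well_probability(left, gr),
               1 - right_well_probability(right, gr), tolerance = 1e-3)
  expect_error(right_well_probability(left * 2, gr), "not normalized")
})

test_that("split-operator agrees with a dense Crank-Nicolson oracle", {
  gr <- grid_spec(64)
  const <- physical_constants()
  V <- quartic_potential(gr, 0.065)
  psi0 <- gaussian_packet(gr, -1e-10, 5e-11)
  dt <- 1e-16
  steps <- 200
  psi_s <- psi0
  for (s in seq_len(steps)) {
    psi_s <- split_operator_step(psi_s, V, dt, const$m_p, gr)
  }
  psi_cn <- oracle_crank_nicolson(psi0, V, dt, const$m_p, gr, steps)
  psi_cn <- psi_cn / sqrt(sum(Mod(psi_cn)^2) * gr$dx)
  expect_lt(abs(right_well_probability(psi_s, gr) -
                  right_well_probability(psi_cn, gr)), 1e-4)
})

test_that("halving dt shows second-order convergence of P_R", {
  gr <- grid_spec(64)
  const <- physical_constants()
  V <- quartic_potential(gr, 0.065)
  run <- function(dt, steps) {
    psi <- gaussian_packet(gr, -1e-10, 5e-11)
    for (s in seq_len(steps)) psi <- split_operator_step(psi, V, dt, const$m_p, gr)
    right_well_probability(psi, gr)
  }
  t_total <- 4e-14
  ref <- run(t_total / 3200, 3200)
  e1 <- abs(run(t_total / 400, 400) - ref)
  e2 <- abs(run(t_total / 800, 800) - ref)
  expect_gt(e1 / e2, 3)
  expect_lt(e1 / e2, 5.5)
})

test_that("base-pair traces are seeded, barrier-ordered and drive-sensitive", {
  gr <- grid_spec(128)
  quiet <- tunnel_drive_spec(E0 = 0, noise_amplitude = 0, seed = 3)
  # 5 ps window: long enough for tunneling (not the initial sloshing
  # transient) to dominate the transfer
  at <- simulate_base_pair("AT", quiet, gr, dt = 1e-15, steps = 5000,
                           record_every = 50)
  gc <- simulate_base_pair("GC", quiet, gr, dt = 1e-15, steps = 5000,
                           record_every = 50)
  expect_true(all(at$p_right >= 0 & at$p_right <= 1))
  # deeper barrier transfers less at equal elapsed time
  expect_gt(max(at$p_right), max(gc$p_right))
  expect_equal(attr(at, "v0_ev"), 0.065)
  expect_equal(attr(gc, "v0_ev"), 0.108)

  noisy <- tunnel_drive_spec(seed = 11)
  tr1 <- simulate_base_pair("AT", noisy, gr, dt = 1e-15, steps = 300,
                            record_every = 30)
  tr2 <- simulate_base_pair("AT", noisy, gr, dt = 1e-15, steps = 300,
                            record_every = 30)
  expect_identical(tr1$p_right, tr2$p_right)   # same seed, same trace

  strong <- tunnel_drive_spec(E0 = 1e8, noise_amplitude = 0, seed = 11)
  tr3 <- simulate_base_pair("AT", strong, gr, dt = 1e-15, steps = 300,
                            record_every = 30)
  expect_gt(max(abs(tr3$p_right - tr1$p_right)), 0)
})

test_that("duplicated-sequence control yields exactly zero paired t", {
  gr <- grid_spec(64)
  quiet <- tunnel_drive_spec(E0 = 0, noise_amplitude = 0)
  seg <- "ATGA"
  res <- region_tunneling_experiment(
    real_segments = list(noncoding = "AAAA", coding = "GGGG"),
    control_segments = list(noncoding = seg, coding = seg),
    drive = quiet, grid = gr, dt = 1e-15, steps = 150, record_every = 15,
    base_seed = 5
  )
  ctrl <- res$tests[res$tests$condition == "control", ]
  expect_equal(ctrl$paired_t, 0)
  # composition difference between classes drives a real contrast (the
  # noiseless runs are deterministic, so compare the group means directly)
  means <- tapply(res$per_pair$mean_p_right,
                  list(res$per_pair$condition, res$per_pair$region), mean)
  expect_gt(abs(means["real", "coding"] - means["real", "noncoding"]), 1e-4)
  expect_equal(means["control", "coding"], means["control", "noncoding"])
  expect_equal(nrow(tidy(res)), 16)
  expect_equal(nrow(glance(res)), 2)
})
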