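test_that("shannon entropy matches closed-form compositions", {
  expect_equal(shannon_entropy("ACGT"), 2)
  expect_equal(shannon_entropy("AAAA"), 0)
  expect_equal(shannon_entropy("AATC"), 1.5)  # -(0.5 lg 0.5 + 2*0.25 lg 0.25)
  expect_equal(shannon_entropy("AANN"), 0)    # N removed before counting
  expect_error(shannon_entropy("NNN"), "all-N")
  expect_error(shannon_entropy(""), "empty")
})

test_that("region density matrix reproduces the three-site worked case", {
  rho <- region_density_matrix("ATC")
  expect_equal(Re(rho), matrix(c(0.5, 1 / 6, 1 / 6, 0.5), 2, 2),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(Im(rho), matrix(0, 2, 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  lam <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(lam, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(attr(rho, "n_effective"), 3L)
})

test_that("pure states and the vacuum rule behave as defined", {
  expect_equal(Re(region_density_matrix("A")),
               matrix(c(1, 0, 0, 0), 2, 2), ignore_attr = TRUE)
  # G contributes nothing: same matrix, same effective count
  rho_g <- region_density_matrix("ATCG")
  expect_equal(rho_g, region_density_matrix("ATC"),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(rho_g, "n_effective"), 3L)
  expect_error(region_density_matrix("GG"), "zero effective")
})

test_that("von Neumann entropy evaluates eigenvalue mixtures in bits", {
  expect_equal(von_neumann_entropy(region_density_matrix("ATC")),
               -(2 / 3) * log2(2 / 3) - (1 / 3) * log2(1 / 3),
               tolerance = 1e-12)
  expect_equal(von_neumann_entropy(region_density_matrix("A")), 0)
  expect_equal(von_neumann_entropy(diag(2) / 2 + 0i), 1)
  expect_error(von_neumann_entropy(matrix(c(1, 1, 0, 1), 2, 2)),
               "Hermitian")
  expect_error(von_neumann_entropy(diag(2) + 0i), "trace")
})

test_that("every constructed density matrix passes the contract checks", {
  set.seed(19)
  for (i in 1:20) {
    rho <- region_density_matrix(random_seq(sample(2:40, 1)))
    expect_lt(max(Mod(rho - Conj(t(rho)))), 1e-10)
    expect_equal(Re(sum(diag(rho))), 1, tolerance = 1e-10)
    lam <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(lam), -1e-10)
    expect_lte(von_neumann_entropy(rho), 1 + 1e-12)
    expect_gte(von_neumann_entropy(rho), 0)
  }
})

test_that("joint density matrix equals the explicit double sum", {
  # single-pair case: |0><0| (x) |1><1|
  j <- joint_density_matrix("A", "T")
  exp_j <- matrix(0 + 0i, 4, 4)
  exp_j[2, 2] <- 1        # |01> in (coding, noncoding) ordering
  expect_equal(j, exp_j, tolerance = 1e-12)

  set.seed(23)
  for (i in 1:10) {
    sa <- random_seq(sample(2:12, 1))
    sb <- random_seq(sample(2:12, 1))
    expect_equal(joint_density_matrix(sa, sb), oracle_joint_density(sa, sb),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(Re(sum(diag(joint_density_matrix(sa, sb)))), 1,
                 tolerance = 1e-10)
  }
})

test_that("partial trace recovers marginals and handles the Bell state", {
  set.seed(29)
  for (i in 1:10) {
    rho_a <- random_density_2()
    rho_b <- random_density_2()
    joint <- kronecker(rho_a, rho_b)
    expect_equal(partial_trace(joint, "first"), rho_a, tolerance = 1e-10)
    expect_equal(partial_trace(joint, "second"), rho_b, tolerance = 1e-10)
    expect_equal(Re(sum(diag(partial_trace(joint, "first")))), 1,
                 tolerance = 1e-10)
  }
  bell <- c(1, 0, 0, 1) / sqrt(2) + 0i
  rho_bell <- bell %o% Conj(bell)
  expect_equal(partial_trace(rho_bell, "first"), diag(2) / 2 + 0i,
               tolerance = 1e-12)
  expect_error(partial_trace(diag(2) / 2 + 0i), "4x4")
})

test_that("entanglement statistic equals the coding marginal entropy", {
  expect_equal(entanglement_entropy("A", "T"), 0)
  expect_equal(entanglement_entropy("ATC", "A"),
               von_neumann_entropy(region_density_matrix("ATC")),
               tolerance = 1e-12)
  # separability identity on random pairs, the module's sharpest self-test
  set.seed(31)
  for (i in 1:15) {
    sa <- random_seq(sample(2:20, 1))
    sb <- random_seq(sample(2:20, 1))
    s_red <- von_neumann_entropy(
      partial_trace(joint_density_matrix(sa, sb), "first"))
    s_marg <- von_neumann_entropy(region_density_matrix(sa))
    expect_equal(s_red, s_marg, tolerance = 1e-9)
  }
})

test_that("entropy profile reports one row per region with bounded values", {
  part <- small_partition(seed = 4)
  prof <- region_entropy_profile(part)
  expect_equal(nrow(prof), nrow(part))
  expect_true(all(prof$shannon_bits >= 0 & prof$shannon_bits <= 2))
  expect_true(all(prof$von_neumann_bits >= 0 & prof$von_neumann_bits <= 1))
  expect_true(all(prof$n_effective_sites <= prof$length))

  summ <- entropy_class_summary(prof)
  expect_setequal(summ$summary$kind, c("coding", "noncoding"))
  expect_equal(nrow(summ$tests), 2)
})

test_that("entanglement profile pairs leading regions in genomic order", {
  part <- small_partition(seed = 4)
  ep <- entanglement_profile(part, n_pairs = 3)
  expect_equal(ep$pair, 1:3)
  expect_true(all(ep$entanglement_bits >= 0 & ep$entanglement_bits <= 1))
  first_coding <- part[part$kind == "coding", ][1, ]
  expect_equal(
    ep$entanglement_bits[1],
    von_neumann_entropy(region_density_matrix(first_coding$sequence)),
    tolerance = 1e-9
  )
  expect_equal(attr(ep, "mean_bits"), mean(ep$entanglement_bits))
})
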