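# Independent oracles and small fixture builders used across the suite.

# Explicit O(n1*n2) double-sum joint density matrix, the construction the
# package's kron-of-marginals shortcut must reproduce.
oracle_joint_density <- function(seq_a, seq_b) {
  states <- function(seq) {
    bases <- strsplit(seq, "")[[1]]
    out <- list()
    for (b in bases) {
      q <- chronohelix::encode_qubit(b)
      if (!q$vacuum) out[[length(out) + 1]] <- q$components
    }
    out
  }
  sa <- states(seq_a)
  sb <- states(seq_b)
  rho <- matrix(0 + 0i, 4, 4)
  for (va in sa) for (vb in sb) {
    v <- as.vector(va %o% vb)   # kron of the two 2-vectors
    v <- c(va[1] * vb, va[2] * vb)
    rho <- rho + v %o% Conj(v)
  }
  rho / (length(sa) * length(sb))
}

# Random sequence over ACGT guaranteed to contain a non-vacuum base.
random_seq <- function(n, include_g = TRUE) {
  alpha <- if (include_g) c("A", "C", "G", "T") else c("A", "C", "T")
  repeat {
    s <- paste(sample(alpha, n, replace = TRUE), collapse = "")
    if (grepl("[ACT]", s)) return(s)
  }
}

# Crank-Nicolson propagator on the same grid, dense linear algebra, spectral
# kinetic operator assembled as an explicit matrix: an independent
# time-integration scheme for cross-checking the split-operator stepper.
oracle_crank_nicolson <- function(psi, V_total, dt, mass, grid, steps) {
  const <- chronohelix::physical_constants()
  hbar <- const$hbar
  n <- grid$n_points
  Fm <- stats::mvfft(diag(n))                    # DFT matrix
  Tk <- Conj(t(Fm)) %*% (hbar^2 * grid$k^2 / (2 * mass) * Fm) / n
  H <- Tk + diag(V_total)
  A <- diag(n) + (1i * dt / (2 * hbar)) * H
  B <- diag(n) - (1i * dt / (2 * hbar)) * H
  M <- solve(A, B)
  for (s in seq_len(steps)) psi <- M %*% psi
  as.vector(psi)
}

# Tiny FASTA/GFF writers for genome_io tests.
write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_tmp_gff <- function(rows) {
  path <- withr::local_tempfile(fileext = ".gff3",
                                .local_envir = parent.frame())
  writeLines(c("##gff-version 3", rows), path)
  path
}

# Small deterministic partition for report-level tests.
small_partition <- function(seed = 1, length = 6000, n_regions = 3) {
  g <- chronohelix::generate_genome(
    chronohelix::synth_genome_config(length = length, n_regions = n_regions,
                                     seed = seed)
  )
  chronohelix::partition_regions(g$genome, g$features)
}

# Random valid 2x2 density matrix (mixture of two random pure states).
random_density_2 <- function() {
  v1 <- complex(real = rnorm(2), imaginary = rnorm(2))
  v2 <- complex(real = rnorm(2), imaginary = rnorm(2))
  v1 <- v1 / sqrt(sum(Mod(v1)^2))
  v2 <- v2 / sqrt(sum(Mod(v2)^2))
  w <- runif(1)
  w * (v1 %o% Conj(v1)) + (1 - w) * (v2 %o% Conj(v2))
}
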