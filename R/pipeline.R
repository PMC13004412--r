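# End-to-end orchestration with reproducible seeding. All randomness flows
# from one root seed via fixed per-stage/per-replicate offsets (kept below
# 2^31).

derive_seed <- function(root, offset) {
  as.integer((as.numeric(root) + offset) %% 2147483647)
}

#' One chirped-drive evolution replicate with band-power readout
#'
#' Encodes the two segments as a joint site-amplitude vector, draws fresh
#' region Hamiltonians, propagates under the boundary-coupled total
#' Hamiltonian with the chirped diagonal drive on the non-coding block,
#' detrends each block's mean unwrapped phase, and integrates the power
#' spectrum over the band swept by the drive.
#'
#' @param nc_seq,c_seq Non-coding and coding segments (characters).
#' @param h_spec A [hamiltonian_spec()] (its seed field is ignored; use
#'   `seed`).
#' @param drive A [drive_spec()]. Its `f0`/`chirp_rate` should be resolvable
#'   on the recorded window (several periods, shift of at least one bin).
#' @param dt Integration step in seconds.
#' @param steps Number of steps.
#' @param record_every Recording stride.
#' @param seed Seed for the Hamiltonian diagonal draw.
#' @return One-row tibble: `power_nc`, `power_c`, `ratio`, `band_lo`,
#'   `band_hi`, `seed`.
#' @export
run_doppler_replicate <- function(nc_seq, c_seq, h_spec, drive,
                                  dt = 1e-17, steps = 4096,
                                  record_every = 4, seed = 1) {
  set.seed(seed)
  n_nc <- nchar(nc_seq)
  n_c <- nchar(c_seq)
  H_nc <- build_region_hamiltonian(n_nc, h_spec)
  H_c <- build_region_hamiltonian(n_c, h_spec)
  H <- build_total_hamiltonian(H_nc, H_c, h_spec$boundary_coupling)
  psi0 <- c(encode_site_amplitudes(nc_seq), encode_site_amplitudes(c_seq))
  psi0 <- psi0 / sqrt(sum(Mod(psi0)^2))
  traj <- propagate(psi0, H, drive = drive, n_nc = n_nc, dt = dt,
                    steps = steps, method = "exact_step",
                    record_every = record_every)
  rs <- region_series(traj, n_nc)
  dt_rec <- dt * record_every
  t_total <- steps * dt
  bp <- vapply(c("noncoding", "coding"), function(block) {
    ph <- rs$mean_phase[rs$block == block]
    spec <- power_spectrum(detrend_series(ph), dt_rec)
    band <- doppler_band(drive$f0, drive$chirp_rate, t_total, spec)
    band_power(spec, band[1], band[2])
  }, numeric(1))
  spec0 <- power_spectrum(
    detrend_series(rs$mean_phase[rs$block == "noncoding"]), dt_rec)
  band <- doppler_band(drive$f0, drive$chirp_rate, t_total, spec0)
  tibble::tibble(power_nc = bp[["noncoding"]], power_c = bp[["coding"]],
                 ratio = bp[["noncoding"]] / bp[["coding"]],
                 band_lo = band[1], band_hi = band[2], seed = seed)
}

#' Replicated real-versus-control band-power experiment
#'
#' Runs `n_replicates` chirped-drive evolutions on the real coding /
#' non-coding window and the same number on the control construction (a
#' non-coding stretch falsely split in two), with distinct seeds per
#' replicate, then summarises the power ratios per condition.
#'
#' @param partition Region tibble from [partition_regions()].
#' @param n_replicates Replicates per condition (>= 2; 10 in the full-scale
#'   design).
#' @param nc_len,c_len Window lengths in bp.
#' @param h_spec,drive,dt,steps,record_every See [run_doppler_replicate()].
#' @param seed Root seed.
#' @return A `chx_power_ratio` object (see [power_ratio_experiment()]).
#' @export
replicate_experiment <- function(partition, n_replicates = 10,
                                 nc_len = 12, c_len = 12,
                                 h_spec = hamiltonian_spec(nc_len, c_len),
                                 drive = drive_spec(f0 = 2e14,
                                                    chirp_rate = 1.2e27),
                                 dt = 1e-17, steps = 4096,
                                 record_every = 4, seed = 1) {
  stopifnot(n_replicates >= 2)
  real <- extract_window(partition, nc_len, c_len)
  ctrl <- make_control(partition, nc_len, c_len)
  reps <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    dplyr::bind_rows(
      dplyr::mutate(
        run_doppler_replicate(real$noncoding, real$coding, h_spec, drive,
                              dt, steps, record_every,
                              seed = derive_seed(seed, 1000 * r)),
        condition = "real", replicate = r
      ),
      dplyr::mutate(
        run_doppler_replicate(ctrl$noncoding, ctrl$coding, h_spec, drive,
                              dt, steps, record_every,
                              seed = derive_seed(seed, 500000 + 1000 * r)),
        condition = "control", replicate = r
      )
    )
  })
  power_ratio_experiment(reps)
}

#' Seeded positive control: injected on-band oscillation
#'
#' Synthesises per-replicate phase series in which only the "real"
#' condition's non-coding block carries an oscillation inside the analysis
#' band (plus white noise everywhere), then runs the band-power / power
#' ratio machinery. With the defaults the real-condition ratio exceeds the
#' control ratio in almost every seeded replicate, which is the designed
#' detectability check of the spectral pipeline.
#'
#' @param n_replicates Replicates per condition (default 10).
#' @param n_samples Samples per phase series (default 512).
#' @param dt Sampling interval in seconds (default 1).
#' @param f_signal Injected frequency in Hz; default 32 bins above DC.
#' @param amplitude Oscillation amplitude (default 1).
#' @param noise_sd White-noise standard deviation (default 0.5).
#' @param seed Root seed.
#' @return A list with the `chx_power_ratio` object (`result`) and the
#'   per-replicate-pair detection tibble (`detections`: logical
#'   `real_gt_control` per replicate index).
#' @export
injected_oscillation_experiment <- function(n_replicates = 10,
                                            n_samples = 512, dt = 1,
                                            f_signal = 32 / (512 * 1),
                                            amplitude = 1, noise_sd = 0.5,
                                            seed = 1) {
  tt <- (seq_len(n_samples) - 1) * dt
  bin <- 1 / (n_samples * dt)
  band <- c(f_signal - bin, f_signal + bin)
  one_series <- function(with_signal) {
    x <- stats::rnorm(n_samples, 0, noise_sd)
    if (with_signal) x <- x + amplitude * sin(2 * pi * f_signal * tt)
    band_power(power_spectrum(detrend_series(x), dt), band[1], band[2])
  }
  reps <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    set.seed(derive_seed(seed, 7 * r))
    tibble::tibble(
      condition = c("real", "control"),
      replicate = r,
      power_nc = c(one_series(TRUE), one_series(FALSE)),
      power_c = c(one_series(FALSE), one_series(FALSE))
    )
  })
  result <- power_ratio_experiment(reps)
  wide <- result$replicates |>
    dplyr::select("condition", "replicate", "ratio") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "ratio")
  detections <- dplyr::transmute(wide, replicate = .data$replicate,
                                 real_gt_control = .data$real > .data$control)
  list(result = result, detections = detections)
}

#' Type-I-error calibration of the entropy pipeline
#'
#' Generates genomes with `codon_bias_strength = 0` (no designed class
#' difference) across many seeds, runs the per-region entropy comparison on
#' each, and collects the Welch-t p-values for the Shannon-entropy class
#' contrast. Under the null construction these p-values should be
#' approximately uniform; the return value includes a Kolmogorov-Smirnov
#' uniformity check.
#'
#' @param n_seeds Number of independent genomes (default 50).
#' @param length,n_regions Genome size parameters for each draw (desk-scale
#'   defaults 20000 bp / 8 coding blocks).
#' @param gc_content,coding_fraction Passed through to the generator.
#' @param seed Root seed.
#' @return A list with `p_values` (tibble: seed, p_value) and `ks` (the
#'   `ks.test` result against the uniform distribution).
#' @export
null_entropy_calibration <- function(n_seeds = 50, length = 20000,
                                     n_regions = 8, gc_content = 0.65,
                                     coding_fraction = 0.91, seed = 1) {
  p_values <- purrr::map_dfr(seq_len(n_seeds), function(i) {
    cfg <- synth_genome_config(
      length = length, gc_content = gc_content,
      coding_fraction = coding_fraction, n_regions = n_regions,
      codon_bias_strength = 0, seed = derive_seed(seed, 31 * i)
    )
    g <- generate_genome(cfg)
    part <- partition_regions(g$genome, g$features)
    prof <- region_entropy_profile(part)
    tests <- entropy_class_summary(prof)$tests
    tibble::tibble(
      seed = cfg$seed,
      p_value = tests$t_pvalue[tests$statistic_of == "shannon_bits"]
    )
  })
  ks <- suppressWarnings(stats::ks.test(p_values$p_value, "punif"))
  list(p_values = p_values, ks = ks)
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages on a synthetic genome (or user-supplied
#' FASTA/GFF paths) and returns their reports together with a reproducible
#' run manifest (config snapshot, derived seeds, package version, per-stage
#' wall time).
#'
#' @param config A named list (or path to a YAML file with the same
#'   structure). Recognised entries: `seed` (root seed, default 1); `stages`
#'   (subset of `"synth"`, `"entropy"`, `"entangle"`, `"evolve"`,
#'   `"tunnel"`, `"cosmo"`); `genome` (list passed to
#'   [synth_genome_config()], or `fasta`/`gff` paths); `dynamics`
#'   (arguments of [replicate_experiment()]); `tunnel` (arguments of
#'   [region_tunneling_experiment()] plus `nc_len`, `c_len`, `profile`).
#'   The full-scale tunneling profile (`profile = "paper"`) is refused
#'   unless `allow_full_scale = TRUE` is set, as it takes orders of
#'   magnitude longer.
#' @return A list of stage outputs plus `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed %||% 1L
  stages <- config$stages %||% c("synth", "entropy", "entangle")
  known <- c("synth", "entropy", "entangle", "evolve", "tunnel", "cosmo")
  if (length(setdiff(stages, known)) > 0) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  manifest <- list(config = config, seed = seed,
                   version = as.character(utils::packageVersion("chronohelix")),
                   timings = list())
  tic <- function() proc.time()[["elapsed"]]

  t0 <- tic()
  if (!is.null(config$genome$fasta)) {
    genome <- read_fasta(config$genome$fasta)[1, ]
    features <- read_gff(config$genome$gff %||%
                           stop("genome$gff required with genome$fasta",
                                call. = FALSE))
  } else {
    gcfg <- do.call(synth_genome_config, utils::modifyList(
      list(seed = derive_seed(seed, 11)),
      config$genome %||% list(length = 50000, n_regions = 10)
    ))
    synth <- generate_genome(gcfg)
    genome <- synth$genome
    features <- synth$features
    if ("synth" %in% stages) out$synth <- synth
  }
  partition <- partition_regions(genome, features)
  out$partition <- partition
  manifest$timings$partition <- tic() - t0

  if ("entropy" %in% stages) {
    t0 <- tic()
    prof <- region_entropy_profile(partition)
    out$entropy <- list(profile = prof, summary = entropy_class_summary(prof))
    manifest$timings$entropy <- tic() - t0
  }
  if ("entangle" %in% stages) {
    t0 <- tic()
    out$entangle <- entanglement_profile(partition, n_pairs = 5)
    manifest$timings$entangle <- tic() - t0
  }
  if ("evolve" %in% stages) {
    t0 <- tic()
    dyn <- config$dynamics %||% list()
    dyn$partition <- partition
    dyn$seed <- derive_seed(seed, 101)
    out$evolve <- do.call(replicate_experiment, dyn)
    manifest$timings$evolve <- tic() - t0
  }
  if ("tunnel" %in% stages) {
    t0 <- tic()
    tcfg <- config$tunnel %||% list()
    if (identical(tcfg$profile, "paper") &&
        !isTRUE(config$allow_full_scale)) {
      stop("full-scale tunneling profile (512-point grid, 1e5 steps, ",
           "100 bp regions) refused: set allow_full_scale = TRUE to ",
           "override, or use the desk profile", call. = FALSE)
    }
    nc_len <- tcfg$nc_len %||% 20
    c_len <- tcfg$c_len %||% 20
    full <- identical(tcfg$profile, "paper")
    real <- extract_window(partition, nc_len, c_len)
    ctrl <- make_control(partition, nc_len, c_len)
    out$tunnel <- region_tunneling_experiment(
      real, ctrl,
      drive = tcfg$drive %||% tunnel_drive_spec(),
      grid = grid_spec(if (full) 512 else tcfg$n_points %||% 256),
      dt = tcfg$dt %||% 1e-15,
      steps = tcfg$steps %||% (if (full) 1e5 else 2000),
      record_every = tcfg$record_every %||% 10,
      base_seed = derive_seed(seed, 202)
    )
    manifest$timings$tunnel <- tic() - t0
  }
  if ("cosmo" %in% stages) {
    f0 <- config$cosmo$f0 %||% 34e9
    out$cosmo <- dplyr::bind_cols(
      photon_energy(f0),
      tibble::tibble(period_s = wave_period(f0),
                     drift_hz_3h = redshift_drift(f0, 3 * 3600))
    )
  }
  out$manifest <- manifest
  out
}
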