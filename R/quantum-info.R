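#' Shannon entropy of a nucleotide sequence
#'
#' Entropy in bits of the observed nucleotide composition:
#' `-sum p_i log2 p_i` over the relative frequencies of A, C, G, T after
#' removing ambiguous (`N`) sites. Bounded by 2 bits for the 4-letter
#' alphabet.
#'
#' @param sequence Character scalar over `{A,C,G,T,N}`, non-empty after
#'   removing `N`.
#' @return Entropy in bits, in `[0, 2]`.
#' @examples
#' shannon_entropy("ACGT")  # 2
#' shannon_entropy("AATC")  # 1.5
#' @export
shannon_entropy <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  bases <- strsplit(gsub("N", "", sequence), "")[[1]]
  if (length(bases) == 0) {
    stop("empty (or all-N) sequence has no defined entropy", call. = FALSE)
  }
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  p <- as.numeric(table(bases)) / length(bases)
  -sum(p * log2(p))
}

# Validate the density-matrix contract: Hermitian, unit trace, PSD.
check_density_matrix <- function(rho, tol = 1e-10) {
  stopifnot(is.matrix(rho), nrow(rho) == ncol(rho))
  if (max(Mod(rho - Conj(t(rho)))) > tol) {
    stop("density matrix is not Hermitian within tolerance", call. = FALSE)
  }
  if (abs(Re(sum(diag(rho))) - 1) > tol || abs(Im(sum(diag(rho)))) > tol) {
    stop("density matrix trace differs from 1 beyond tolerance", call. = FALSE)
  }
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    stop("density matrix has a negative eigenvalue beyond tolerance",
         call. = FALSE)
  }
  invisible(rho)
}

#' Region density matrix under the discrete qubit encoding
#'
#' Averages the pure-state projectors `|phi(s_i)><phi(s_i)|` over all
#' non-vacuum sites (G and N contribute nothing) and renormalizes to unit
#' trace. The result is a 2x2 Hermitian, positive-semidefinite, unit-trace
#' matrix.
#'
#' @param sequence Character scalar over `{A,C,G,T,N}` with at least one
#'   non-G, non-N base.
#' @return A 2x2 complex matrix with attribute `n_effective` giving the
#'   number of contributing sites.
#' @examples
#' region_density_matrix("ATC")  # [[0.5, 1/6], [1/6, 0.5]]
#' @export
region_density_matrix <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  bases <- strsplit(sequence, "")[[1]]
  if (length(bases) == 0) stop("empty sequence", call. = FALSE)
  counts <- table(factor(bases, levels = c("A", "C", "G", "T", "N")))
  n_eff <- sum(counts[c("A", "C", "T")])
  if (n_eff == 0) {
    stop("zero effective sites: no non-vacuum base to average", call. = FALSE)
  }
  rho <- matrix(0 + 0i, 2, 2)
  for (b in c("A", "C", "T")) {
    if (counts[[b]] > 0) {
      v <- encode_qubit(b)$components
      rho <- rho + counts[[b]] * (v %o% Conj(v))
    }
  }
  rho <- rho / Re(sum(diag(rho)))    # unit-trace renormalization
  check_density_matrix(rho)
  attr(rho, "n_effective") <- as.integer(n_eff)
  rho
}

#' Von Neumann entropy of a density matrix
#'
#' `-sum lambda_k log2 lambda_k` over the eigenvalues of `rho`; eigenvalues
#' below `cutoff` (default 1e-12) are excluded from the sum.
#'
#' @param rho A valid density matrix (Hermitian, unit trace, PSD).
#' @param cutoff Eigenvalues below this are treated as exactly zero.
#' @return Entropy in bits, `>= 0`; at most `log2(d)` for a d-dimensional
#'   state.
#' @examples
#' von_neumann_entropy(region_density_matrix("ATC"))  # ~0.9183
#' @export
von_neumann_entropy <- function(rho, cutoff = 1e-12) {
  check_density_matrix(rho)
  lam <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > cutoff]
  -sum(lam * log2(lam))
}

#' Joint density matrix of a coding / non-coding sequence pair
#'
#' The average of `|psi_i (x) phi_j><psi_i (x) phi_j|` over all non-vacuum
#' site pairs. Because the double sum factorises, this equals the Kronecker
#' product of the two marginal region density matrices; the package computes
#' it that way (the explicit double sum is kept as an independent oracle in
#' the test suite).
#'
#' @param seq_coding,seq_noncoding Sequences with at least one non-vacuum
#'   site each.
#' @return A 4x4 complex density matrix (coding subsystem first).
#' @export
joint_density_matrix <- function(seq_coding, seq_noncoding) {
  rho_a <- region_density_matrix(seq_coding)
  rho_b <- region_density_matrix(seq_noncoding)
  rho <- kronecker(rho_a, rho_b)
  check_density_matrix(rho)
  rho
}

#' Partial trace of a two-qubit density matrix
#'
#' Reduces a 4x4 joint density matrix to the 2x2 marginal of one subsystem
#' by tracing out the other; the trace is preserved.
#'
#' @param rho_joint A 4x4 density matrix with subsystem ordering
#'   (first (x) second).
#' @param keep Which subsystem to keep: `"first"` or `"second"`.
#' @return A 2x2 density matrix.
#' @export
partial_trace <- function(rho_joint, keep = c("first", "second")) {
  keep <- match.arg(keep)
  if (!is.matrix(rho_joint) || any(dim(rho_joint) != c(4, 4))) {
    stop("partial_trace() expects a 4x4 joint density matrix", call. = FALSE)
  }
  check_density_matrix(rho_joint)
  out <- matrix(0 + 0i, 2, 2)
  # index (i, j) of subsystem A and (k, l) of B map to rows 2*(i-1)+k etc.
  for (i in 1:2) for (j in 1:2) {
    acc <- 0 + 0i
    for (k in 1:2) {
      if (keep == "first") {
        acc <- acc + rho_joint[2 * (i - 1) + k, 2 * (j - 1) + k]
      } else {
        acc <- acc + rho_joint[2 * (k - 1) + i, 2 * (k - 1) + j]
      }
    }
    out[i, j] <- acc
  }
  out
}

#' Entanglement-entropy statistic between two sequences
#'
#' Von Neumann entropy of the reduced (coding) state obtained by tracing the
#' non-coding subsystem out of the joint density matrix. Because the joint
#' state is a product of the two marginals by construction, this equals the
#' coding region's own von Neumann entropy: the statistic measures marginal
#' mixedness rather than genuine quantum entanglement, and the package
#' asserts that identity.
#'
#' @inheritParams joint_density_matrix
#' @return Entropy in bits.
#' @examples
#' entanglement_entropy("ATC", "A")  # ~0.9183
#' @export
entanglement_entropy <- function(seq_coding, seq_noncoding) {
  joint <- joint_density_matrix(seq_coding, seq_noncoding)
  reduced <- partial_trace(joint, keep = "first")
  s <- von_neumann_entropy(reduced)
  s_marginal <- von_neumann_entropy(region_density_matrix(seq_coding))
  if (abs(s - s_marginal) > 1e-9) {
    stop("separability identity violated: reduced-state entropy differs ",
         "from the marginal entropy", call. = FALSE)
  }
  s
}

#' Per-region entropy profile of a partition
#'
#' Shannon and von Neumann entropies for every region of a coding /
#' non-coding partition, the per-region report underlying the genome-wide
#' class comparison.
#'
#' @param partition Region tibble from [partition_regions()].
#' @param min_len Regions shorter than this are skipped (they carry too few
#'   sites for a stable composition estimate); default 1 keeps everything
#'   with at least one scorable site.
#' @return A tibble with `region_id`, `kind`, `length`, `shannon_bits`,
#'   `von_neumann_bits`, `n_effective_sites`. Regions with no scorable sites
#'   (all G/N for the quantum entropy) get `NA`.
#' @export
region_entropy_profile <- function(partition, min_len = 1) {
  rows <- dplyr::filter(partition,
                        .data$end - .data$start >= min_len)
  purrr::pmap_dfr(
    list(rows$seq_id, rows$start, rows$end, rows$kind, rows$sequence),
    function(seq_id, start, end, kind, sequence) {
      has_classical <- grepl("[ACGT]", sequence)
      has_quantum <- grepl("[ACT]", sequence)
      rho <- if (has_quantum) region_density_matrix(sequence) else NULL
      tibble::tibble(
        region_id = paste0(seq_id, ":", start, "-", end),
        kind = kind,
        length = end - start,
        shannon_bits = if (has_classical) shannon_entropy(sequence) else NA_real_,
        von_neumann_bits = if (has_quantum) von_neumann_entropy(rho) else NA_real_,
        n_effective_sites = if (has_quantum) attr(rho, "n_effective") else 0L
      )
    }
  )
}

#' Class-level summary of an entropy profile
#'
#' Means and standard deviations per region kind, plus Welch-t and
#' Mann-Whitney comparisons of the per-region entropies between classes.
#' Regions are averaged unweighted (each region one observation); set
#' `weighted = TRUE` for length-weighted means.
#'
#' @param profile Tibble from [region_entropy_profile()].
#' @param weighted Length-weight the class means? Default FALSE.
#' @return A list with `summary` (per-kind tibble) and `tests` (tibble from
#'   [compare_distributions()] for Shannon and von Neumann entropies).
#' @export
entropy_class_summary <- function(profile, weighted = FALSE) {
  wmean <- function(x, w) {
    ok <- !is.na(x)
    if (weighted) stats::weighted.mean(x[ok], w[ok]) else mean(x[ok])
  }
  summary <- profile |>
    dplyr::group_by(.data$kind) |>
    dplyr::summarise(
      n_regions = dplyr::n(),
      mean_shannon = wmean(.data$shannon_bits, .data$length),
      sd_shannon = stats::sd(.data$shannon_bits, na.rm = TRUE),
      mean_von_neumann = wmean(.data$von_neumann_bits, .data$length),
      sd_von_neumann = stats::sd(.data$von_neumann_bits, na.rm = TRUE),
      .groups = "drop"
    )
  pick <- function(col, kind) {
    x <- profile[[col]][profile$kind == kind]
    x[!is.na(x)]
  }
  tests <- dplyr::bind_rows(
    dplyr::mutate(
      compare_distributions(pick("shannon_bits", "coding"),
                            pick("shannon_bits", "noncoding")),
      statistic_of = "shannon_bits", .before = 1
    ),
    dplyr::mutate(
      compare_distributions(pick("von_neumann_bits", "coding"),
                            pick("von_neumann_bits", "noncoding")),
      statistic_of = "von_neumann_bits", .before = 1
    )
  )
  list(summary = summary, tests = tests)
}

#' Entanglement-entropy profile of the leading region pairs
#'
#' Pairs the i-th coding region with the i-th non-coding region in genomic
#' order (i = 1..n_pairs) and reports the entanglement-entropy statistic for
#' each pair plus its mean, the "first 5 regions" analysis.
#'
#' @param partition Region tibble from [partition_regions()].
#' @param n_pairs Number of leading pairs (default 5).
#' @return A tibble with `pair`, `coding_id`, `noncoding_id`,
#'   `entanglement_bits`; the mean is attached as attribute `mean_bits`.
#' @export
entanglement_profile <- function(partition, n_pairs = 5) {
  coding <- dplyr::filter(partition, .data$kind == "coding")
  noncoding <- dplyr::filter(partition, .data$kind == "noncoding")
  k <- min(n_pairs, nrow(coding), nrow(noncoding))
  if (k < 1) stop("partition lacks regions of both kinds", call. = FALSE)
  out <- purrr::map_dfr(seq_len(k), function(i) {
    tibble::tibble(
      pair = i,
      coding_id = paste0(coding$seq_id[i], ":", coding$start[i], "-",
                         coding$end[i]),
      noncoding_id = paste0(noncoding$seq_id[i], ":", noncoding$start[i],
                            "-", noncoding$end[i]),
      entanglement_bits = entanglement_entropy(coding$sequence[i],
                                               noncoding$sequence[i])
    )
  })
  attr(out, "mean_bits") <- mean(out$entanglement_bits)
  out
}
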