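#' Discrete nucleotide-to-qubit encoding
#'
#' Maps a single nucleotide to a two-component qubit state:
#' A maps to (1, 0) (the |0> state), T to (0, 1) (|1>), C to the normalized
#' superposition (1, 1)/sqrt(2), and G to the vacuum (erasure) state, which
#' carries zero amplitude and contributes no projector to density-matrix
#' averages.
#'
#' @param base A single letter in `{A, C, G, T}`.
#' @return A list with `components` (length-2 complex vector) and `vacuum`
#'   (logical). Non-vacuum states have unit Euclidean norm.
#' @examples
#' encode_qubit("A")$components
#' encode_qubit("G")$vacuum
#' @export
encode_qubit <- function(base) {
  stopifnot(is.character(base), length(base) == 1)
  switch(base,
    A = list(components = c(1 + 0i, 0 + 0i), vacuum = FALSE),
    T = list(components = c(0 + 0i, 1 + 0i), vacuum = FALSE),
    C = list(components = c(1 + 0i, 1 + 0i) / sqrt(2), vacuum = FALSE),
    G = list(components = c(0 + 0i, 0 + 0i), vacuum = TRUE),
    stop("unencodable site: '", base,
         "' is not in {A,C,G,T}; caller policy decides drop vs abort",
         call. = FALSE)
  )
}

#' Default Bloch-sphere parameters reproducing the discrete encoding
#'
#' Each base gets polar/azimuthal angles `(theta, phi)`; the defaults place
#' A at the north pole, T at the south pole and C on the equator, so
#' [encode_bloch()] with these parameters reproduces [encode_qubit()] for the
#' non-vacuum bases. G is retained at the south pole by convention but is
#' normally handled by the vacuum rule of the discrete scheme; angle tables
#' derived from biochemical descriptors can be supplied instead.
#'
#' @return A tibble with columns `base`, `theta`, `phi` (radians).
#' @export
bloch_params <- function() {
  tibble::tibble(
    base = c("A", "T", "C", "G"),
    theta = c(0, pi, pi / 2, pi),
    phi = c(0, 0, 0, 0)
  )
}

#' Bloch-parameterised nucleotide-to-qubit encoding
#'
#' `cos(theta/2)|0> + exp(i phi) sin(theta/2)|1>` for the angles assigned to
#' `base`; unit norm by construction.
#'
#' @param base A single letter in `{A, C, G, T}`.
#' @param params A tibble like [bloch_params()] with columns `base`, `theta`
#'   in `[0, pi]` and `phi` in `[0, 2*pi)`.
#' @return A list with `components` and `vacuum = FALSE`, as [encode_qubit()].
#' @examples
#' encode_bloch("C")$components  # reproduces the discrete C state
#' @export
encode_bloch <- function(base, params = bloch_params()) {
  stopifnot(is.character(base), length(base) == 1)
  stopifnot(all(c("base", "theta", "phi") %in% names(params)),
            all(c("A", "C", "G", "T") %in% params$base))
  row <- params[params$base == base, ]
  if (nrow(row) != 1) {
    stop("unencodable site: '", base, "' has no Bloch parameters",
         call. = FALSE)
  }
  if (row$theta < 0 || row$theta > pi) {
    stop("theta must lie in [0, pi]", call. = FALSE)
  }
  list(
    components = c(
      complex(real = cos(row$theta / 2)),
      exp(1i * row$phi) * sin(row$theta / 2)
    ),
    vacuum = FALSE
  )
}

# Scalar site-basis embedding: A -> 1, T -> i, C -> (1+i)/sqrt(2), G -> 0.
# Consistent with the qubit mapping under |0> -> 1, |1> -> i, |vac> -> 0.
site_alpha <- c(
  A = 1 + 0i,
  T = 0 + 1i,
  C = (1 + 1i) / sqrt(2),
  G = 0 + 0i
)

#' Encode a sequence as a unit-norm site-amplitude vector
#'
#' Each position gets the scalar amplitude `alpha(base)` of the site-basis
#' embedding (A: 1, T: i, C: (1+i)/sqrt(2), G: 0), and the whole vector is
#' then normalized to unit Euclidean norm. `N` sites receive amplitude 0 with
#' a warning, so positions stay aligned with genome coordinates.
#'
#' @param sequence Non-empty character scalar over `{A,C,G,T,N}`.
#' @return A complex vector of length `nchar(sequence)` with unit norm.
#' @examples
#' encode_site_amplitudes("AT")  # (1, i) / sqrt(2)
#' @export
encode_site_amplitudes <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  bases <- strsplit(sequence, "")[[1]]
  if (length(bases) == 0) stop("empty sequence", call. = FALSE)
  known <- bases %in% c(names(site_alpha), "N")
  if (!all(known)) {
    stop("unencodable character '", bases[which(!known)[1]], "' at position ",
         which(!known)[1], call. = FALSE)
  }
  n_amb <- sum(bases == "N")
  if (n_amb > 0) {
    warning(n_amb, " ambiguous (N) site(s) encoded with zero amplitude",
            call. = FALSE)
  }
  amp <- ifelse(bases == "N", 0 + 0i, site_alpha[bases])
  nrm <- sqrt(sum(Mod(amp)^2))
  if (nrm == 0) {
    stop("zero-norm encoding: sequence has no site with nonzero amplitude",
         call. = FALSE)
  }
  unname(amp / nrm)
}
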