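---
title: "chronohelix: models, parameters and numerical design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chronohelix: models, parameters and numerical design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronohelix)
```

`chronohelix` treats an annotated genome as a constrained quantum system
and quantifies how its coding and non-coding regions differ under that
description. This vignette is the package's own account of the models it
implements, the parameters that matter, and the numerical decisions taken
where the design was genuinely open. Nothing here should be read as a claim
that DNA physically realises these states; the package implements a toy
quantum-information description and the statistics defined on it, so that
its behaviour can be studied reproducibly.

## Region partitioning

Genomes are read from FASTA (alphabet `{A,C,G,T,N}` enforced; other letters
are rejected with the offending position, or mapped to `N` on request) and
annotations from GFF3. "Coding" is defined as the strand-insensitive union
of the selected feature type (default `CDS`), merged across overlaps; the
non-coding class is its complement. GFF coordinates are 1-based inclusive
and converted once, at ingestion, to 0-based half-open intervals used
everywhere internally — BED round-trips are then exact. All analysis is on
the forward strand of the reported sequence; spliced gene models beyond
interval union, translation and alignment are out of scope. Whether
"coding" should instead mean `gene` features, and how overlapping genes
should combine, is not fixed by the problem statement; CDS-union is the
package's documented choice and the feature type is a parameter.

## Qubit encodings

The discrete mapping sends A → |0⟩ = (1,0)ᵀ, T → |1⟩ = (0,1)ᵀ,
C → (|0⟩+|1⟩)/√2, and G to a vacuum/erasure state orthogonal to the qubit
basis, represented computationally as the zero vector: it carries no
amplitude and contributes no projector. The C state is stored normalized;
density matrices are therefore always built from unit-norm projectors. A
Bloch-parameterised generalisation
cos(θ_b/2)|0⟩ + e^{iφ_b} sin(θ_b/2)|1⟩ is available with angles per base;
its defaults reproduce the discrete mapping (A at the north pole, T at the
south pole, C on the equator). Angle tables derived from biochemical
descriptors (stacking energies, dipole moments, …) can be supplied, but no
default table ships: there is no validated assignment to hard-code.

For Schrödinger evolution the scalar site-basis embedding α(A) = 1,
α(T) = i, α(C) = (1+i)/√2, α(G) = 0 is used; the site-amplitude vector
ψᵢ(0) = α(sᵢ) is normalized to unit Euclidean norm. `N` sites get amplitude
0 with a warning, which keeps vector indices aligned with genome
coordinates; an all-G (or all-N) sequence has no valid encoding and is an
explicit error rather than a silent zero state.

## Entropy and the entanglement-entropy statistic

Shannon entropy is the plug-in estimate −Σ pᵢ log₂ pᵢ of the nucleotide
composition (N removed first), bounded by 2 bits. The region density matrix
averages the non-vacuum projectors and renormalizes to unit trace; its von
Neumann entropy −Σ λ_k log₂ λ_k excludes eigenvalues below 10⁻¹², and every
constructed matrix is checked for Hermiticity, unit trace and positive
semidefiniteness at 10⁻¹⁰.

The joint density matrix of a region pair is the average of
|ψᵢ ⊗ φⱼ⟩⟨ψᵢ ⊗ φⱼ| over all non-vacuum site pairs. That double sum
factorises exactly into the Kronecker product of the two marginal density
matrices, and the package computes it that way; the explicit O(n₁n₂) sum is
retained in the test suite as an independent oracle. A consequence worth
stating plainly: the joint state is a *product* state, so the
"entanglement entropy" S(Tr_B ρ_joint) equals the coding region's own
marginal entropy and measures marginal mixedness, not quantum
entanglement. The package implements the statistic as defined, asserts the
separability identity to 10⁻⁹ on every call, and the test suite names the
property accordingly.

Two aggregation questions are open in the source description and resolved
as follows. Genome-wide class means average per-region entropies
unweighted (each region is one observation, which is how "mean entropy of
coding regions" reads); length-weighted means are available via
`entropy_class_summary(weighted = TRUE)`. The "first 5 region pairs"
statistic pairs the i-th coding with the i-th non-coding region in genomic
order and averages the five values; full region sequences are used without
truncation to a common length, since the product structure makes the
statistic independent of the partner region's length anyway.

## Tight-binding dynamics

Each region contributes a real symmetric tridiagonal Hamiltonian: site
energies i.i.d. uniform on [0.01, 0.05] eV (redrawn per replicate),
nearest-neighbour coupling 0.025 eV. The total Hamiltonian embeds the two
blocks block-diagonally and adds exactly one Hermitian pair of boundary
terms g (default 0.01 eV) between the last non-coding and first coding
site — the minimal channel through which amplitude can cross between
blocks, and the package's tests verify that with g = 0 and no drive no
probability crosses (to 10⁻¹²) while any g > 0 transfers measurably.

The drive adds λ·10^(gain_dBi/10)·cos(2πf(t)t) to the diagonal of the
non-coding block with f(t) = f₀ + kt. Two deliberate literalisms:

* The chirp phase is exactly `2π(f₀+kt)t` as specified, although the
  physically conventional instantaneous-frequency chirp integrates to
  `2π(f₀t + kt²/2)`; a flag (`integrated_phase = TRUE`) selects the
  conventional form. At the default k = 0 they coincide.
* The quoted drive amplitudes are mutually inconsistent by tens of orders
  of magnitude (1 × 10⁻⁴ eV justified from the 34 GHz photon energy;
  1 × 10⁻⁴¹ eV elsewhere; a range "10⁻⁵ eV to 10⁻³¹ neV"). All are exposed
  in `drive_presets()`; the default is 1 × 10⁻⁴ eV, and the package makes
  no claim about which value produced any published figure.

Energies are entered in eV and converted to joules at a single point
(`ev_to_joules`, elementary charge 1.6021766 × 10⁻¹⁹ C), with
ℏ = 1.0545718 × 10⁻³⁴ J·s; one conversion boundary prevents silent unit
errors. Two propagation schemes are provided: the exact one-step unitary
exp(−iH(t_n)Δt/ℏ) of the Hamiltonian frozen at each step (via
eigendecomposition; unitary to machine precision), and the first-order
Euler update ψ ← ψ − (iΔt/ℏ)H(t_n)ψ followed by renormalization, matching
the first-order description of the perturbed evolution. Renormalization
can be disabled to expose the Euler scheme's positive norm drift, which the
tests verify grows with Δt, and the two schemes are verified to agree at
O(Δt²) over fixed step counts.

**Step-phase warning.** With site energies up to 0.05 eV, a time step of
10⁻¹³ s advances the phase by E·Δt/ℏ ≈ 7.6 rad > π per step: that parameter
set undersamples the dynamics and recorded phases alias. `propagate()`
emits a prominent warning whenever the per-step phase exceeds π. The
package's own test and default configurations therefore use smaller steps
(10⁻¹⁷–10⁻¹⁸ s for 0.01–0.05 eV energies); runs at the historical
parameters remain possible, with the warning documenting their status.

## Spectral band power and the power-ratio experiment

Per-block series are the mean site amplitude and the block mean of
per-site unwrapped phases (each site's phase series is unwrapped over time
before averaging — averaging wrapped phases across sites would introduce
2π-jump artefacts). Phases are detrended by ordinary least squares before
Fourier analysis. The one-sided power spectrum uses |X_j|²/n with interior
bins doubled, so Parseval's identity holds as Σ power = Σ x²; the identity
is asserted to 10⁻⁶ in the tests. Band power sums bins inclusively between
the edges, and a band edge beyond Nyquist is an error naming the limit.

The analysis band is the interval swept by the chirp,
[min(f₀, f₀+kT), max(f₀, f₀+kT)], expanded by one bin on each side — the
band edges are otherwise unspecified in the source description. The
power-ratio statistic is power_nc/power_c per replicate, summarised per
condition (real vs control) with Welch-t and Mann–Whitney comparisons; no
multiple-testing correction is applied (none is applied in the source
design), and every replicate row carries its seed.

A 34 GHz drive on a 10 ns window sampled as described is unresolvable
(and the dynamics are undersampled at that Δt anyway), so the package's
default experiment rescales the drive so that several periods fit the
recorded window and the chirp sweeps at least one bin: the desk
configuration uses 12-site blocks, Δt = 10⁻¹⁷ s, 4096 steps recorded every
4, f₀ = 2 × 10¹⁴ Hz and k = 1.2 × 10²⁷ Hz/s. These are resolution-driven
choices of this implementation, documented here rather than hidden; the
qualitative design — weak chirped drive on the non-coding block, boundary
coupling, band-power readout — is unchanged. No coherence estimator is
exposed: the source reports "coherence" qualitatively without defining one,
and the package does not guess.

## Proton tunneling

Per base pair, the proton coordinate along the hydrogen bond sees the
symmetric quartic double well V(x) = V₀[(x/a)⁴ − 2(x/a)² + 1] with minima
at ±a (a = 1 Å) and barrier V₀ at 0: 0.065 eV for A–T/T–A, 0.108 eV for
G–C/C–G (each nucleotide forms its pair by the complement rule, and the
reversed pair shares parameters). Real proton-transfer potentials are
asymmetric and environment-dependent; ab initio (DFT/QM-MM) surfaces are
explicitly out of scope, so tunneling outputs are qualitative.

The initial state is the normalized Gaussian (1/πσ²)^{1/4}
exp(−(x−x₀)²/2σ²) with σ = 5 × 10⁻¹¹ m and x₀ = −a, renormalized on the
grid; σ ≤ 2dx is rejected as unresolvable. The drive is the linear tilt
(λ_pert + ξ(t))·cos(2πf(t)t)·(x/a) with λ_pert = e·E₀·a·10^(gain/10)
(E₀ = 10⁻⁶ V/m, gain 1.7 dBi). Both frequency conventions are implemented:
the static shift f₀ + Δf and the chirp f₀ + kt; the default is the chirp
with k = Δf/3 h so the drift accumulates Δf = 8 × 10⁻⁴ Hz over three
hours. The noise amplitude 0.05 is dimensionless; it is read as ξ's
standard deviation being 0.05·λ_pert, the only dimensionally coherent
interpretation of adding ξ to λ_pert, with an absolute level in joules
accepted as an alternative. ξ is drawn i.i.d. per step (the correlation
time is unspecified in the source; per-step independence is the documented
choice), seeded per simulation.

Propagation is Strang splitting, exp(−iT̂Δt/2ℏ)·exp(−iV̂Δt/ℏ)·
exp(−iT̂Δt/2ℏ), with the kinetic factor applied in momentum space on a
power-of-two grid (default 512 points over ±5 × 10⁻¹⁰ m; both factors are
unitary, and unitarity is tested to 10⁻⁷ over 10⁵ steps). P_R(t) sums
|ψ|²dx over x > 0 with the x = 0 grid point given half weight — removing a
grid-parity bias at the symmetric default domain. Correctness is
cross-checked three ways: free-Gaussian spreading against the closed form
(0.5%), coherent-state oscillation in a harmonic well against Ehrenfest
(1% per period), and agreement with an independent dense Crank–Nicolson
propagator to 10⁻⁴ in P_R on a 64-point grid, plus a second-order
Δt-convergence check.

**Profiles.** The full-scale profile (512-point grid, 10⁵ steps of
10⁻¹⁵ s, 100 bp per region) is available but deliberately kept behind an
explicit override in the pipeline; the desk profile (256 points, 10⁴
steps, 20 bp per region) exercises identical code at sizes suited to
routine reruns, and the test suite works at 64–128 points with hundreds to
thousands of steps. Region comparisons pool equally over base pairs, then
over runs (run weighting is unspecified in the source; equal weighting is
the documented choice). The barrier-ordering check (A–T transfers more
than G–C) is run on a 5 ps window: on shorter windows the initial
intra-well transient, not tunneling, dominates the transfer and the
ordering is not yet physics-forced.

## Synthetic genomes and what passing tests show

The generator emulates the analysed genome's gross features at
configurable scale: GC ≈ 0.65, coding fraction ≈ 0.91, alternating
coding/non-coding blocks, and a class entropy difference with coding
higher — the observed direction. Mechanism: pooled Shannon entropy depends
only on pooled composition, so codon-periodic structure alone cannot
separate the classes; instead the non-coding composition is sharpened
(interpolated toward a renormalized p² profile, lowering its entropy), the
coding pool is counter-shifted so the length-weighted genome composition
still hits the GC target exactly in expectation, and zero-sum per-codon-
position perturbations add periodic structure to coding blocks without
moving their pooled composition. At `codon_bias_strength = 0` the two
classes are drawn from identical compositions — the null construction used
for type-I-error calibration, where the class-contrast p-values are
checked for approximate uniformity over 50 seeded genomes.

What the synthetic genomes do *not* emulate: real k-mer statistics, gene
structure (start/stop codons, RBS), repeats, strand asymmetries, or the
specific entropy values of any real assembly. Tests passing on these
genomes show the pipeline's statistics behave as designed under known
composition structure; they do not certify the biological claims, and the
genome-accession entropy means are only reproducible from the real
assembly, which the package deliberately does not download.

One estimator caveat surfaced during design: the plug-in entropy estimate
is biased low by ≈ (K−1)/(2N ln 2) bits for an N-base region, so classes
with very different typical region lengths differ slightly in entropy even
under the null composition. The generator-null test therefore compares
classes at matched block lengths; the calibration test keeps the realistic
unbalanced layout and checks the resulting p-value distribution instead.

## Reproducibility and degenerate inputs

All randomness flows from explicit integer seeds (Hamiltonian diagonals,
tunneling noise, genome draws); derived seeds stay below 2³¹. Identical
configuration and seed reproduce deterministic stages bit for bit, which
`run_pipeline()` records in its manifest (config snapshot, seeds, package
version, per-stage wall time). Degenerate inputs fail loudly rather than
silently: empty FASTA records, features beyond sequence bounds, all-G
encodings (zero norm), zero effective sites in a density matrix,
non-finite Euler states (reported with the step index), unnormalized
wavefunctions, bands beyond Nyquist, and zero-variance t statistics
(reported as `NA` rather than fabricated).

Configuration files for `run_pipeline()` are YAML (or an R list); unknown
stage names are errors, so typos cannot silently skip physics.

## Known limitations

* The encodings are a modelling choice, not physics; in particular the
  G → vacuum rule erases guanine from all density-matrix statistics, so
  GC-rich sequences have few effective sites per base.
* The "entanglement entropy" is, by construction, a marginal entropy of a
  product state; the package computes it faithfully and says so.
* Tight-binding parameters and the quartic well are toy models; none of
  the dynamical outputs are calibrated to measured DNA physics.
* The historical drive amplitudes and the chirp magnitude quoted for the
  34 GHz scenario are internally inconsistent (the quoted k = −10¹⁸ Hz/s
  over 10⁻⁸ s shifts by 10 GHz, not the stated ~1 GHz); the package
  exposes them as presets without adjudicating.
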