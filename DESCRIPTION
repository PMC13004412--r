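Package: chronohelix
Title: Quantum-Information Statistics and Driven Quantum Dynamics for
    Annotated Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps annotated genome sequences onto constrained qubit states and
    quantifies their informational structure with Shannon and von Neumann
    entropies, joint density matrices, partial traces and an
    entanglement-entropy statistic contrasting coding and non-coding regions.
    Propagates sequence-derived site-amplitude vectors under tight-binding
    Hamiltonians with weak chirped diagonal drives and boundary coupling,
    analyses detrended phase series by FFT band power and a real-versus-control
    power-ratio statistic, and simulates driven, noisy proton tunneling in a
    quartic double well per base pair with Strang split-operator propagation.
    Includes closed-form physical calculators, a seeded synthetic
    annotated-genome generator emulating a GC-rich, coding-dense bacterial
    genome so every stage is testable without downloads, and pipeline
    orchestration with reproducible seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
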