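Package: nucbarrier
Title: Nucleosome Occupancy Around Transcription-Factor Barriers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of MNase-seq nucleosome occupancy around
    transcription-factor barriers in fission yeast style genomes:
    dyad-centered coverage from single-end reads, reads-per-million
    normalization, FFT low-pass smoothing, nucleosome and
    nucleosome-depleted-region (NDR) calling, +1 nucleosome assignment,
    feature-anchored composite log2 occupancy profiles with phasing
    metrics, and the matching low-throughput quantifications
    (nucleosome-scanning qPCR, strand-specific RT-qPCR fold changes).
    Includes a synthetic MNase-seq generator implementing a
    transcription-factor barrier model of statistical nucleosome
    positioning, so every pipeline stage is testable against ground
    truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
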