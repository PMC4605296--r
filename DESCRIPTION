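Package: nucmap
Title: Nucleosome Positioning and Depleted-Region Analysis from MNase-Seq Fragments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping nucleosome positions from paired-end MNase-Seq
    fragment data: single-nucleosome size selection, per-base occupancy tracks
    with frequency-domain (Fourier) smoothing, non-parametric scored peak
    calling, nucleosome-depleted region (NDR) detection and size
    distributions, meta-occupancy profiles around scored feature sites such as
    ORC binding sites, a sequence-based nucleosome preference model
    (dinucleotide periodicity plus poly(dA:dT) exclusion) with equilibrium
    occupancy computed by an exact hard-rod partition-function recursion, and
    quantitative track comparisons. Includes a fully deterministic synthetic
    MNase-library generator with planted ground truth so every stage of the
    pipeline can be validated without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
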