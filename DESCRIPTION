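Package: retroproteo
Title: Repeat-Aware Proteomics of LINE-1 ORF1p and ORF2p
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for hunting LINE-1 (L1) ORF1p and ORF2p in shotgun and
    affinity-purification mass spectrometry data. Implements repeat-aware
    peptide-spectrum-match filtering driven by b/y fragment-ion quality metrics
    (matched-intensity fraction, fragmentation gaps, tryptic status), the four
    recommended ORF2p false-positive rejection flags, sequence analytics over
    families of near-identical L1 loci (in-silico tryptic digestion, alignment
    to a reference ORF, variant counting, per-position identity, antibody
    epitope conservation scanning, amino-acid to nucleotide coordinate
    mapping, and two-step locus-database orthogonalization), a label-free
    quantitative IP-MS differential-enrichment pipeline with left-censored
    missing-value imputation and cross-comparison significance integration,
    and the gel-band identification ranking heuristic. Ships seeded synthetic
    generators (locus families, noisy fragmentation spectra, replicate
    IP-vs-control intensity matrices with spiked proteins) so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
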