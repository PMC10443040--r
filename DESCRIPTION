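Package: bescan
Title: Amplicon Deep-Sequencing Analysis of CRISPR Base-Editor Mutation
    Spectra and Editing Windows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes dCas9-deaminase base editors from paired-end
    amplicon deep sequencing of a target gene: merges perfectly overlapping
    read pairs, aligns merged reads, builds per-position allele-count
    pileups, and derives depth-filtered, WT-subtracted mutation spectra and
    substitution-class profiles with empirical WT background bands.
    Includes read-level editing-diversity statistics (distinct reads, SNP
    counts, per-kiloread normalization, replicate significance tests),
    guide/PAM geometry with PAM-relative coordinates and editing windows,
    canavanine-resistance frequencies from serial-dilution drop counts, and
    Sanger clone mutation rates. A seeded synthetic-data generator emulates
    editor-specific mutagenesis so the full pipeline is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
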