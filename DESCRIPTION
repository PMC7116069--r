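Package: picseq
Title: Segmentation, Classification and Sequence Analysis of Mouse Pup
    Isolation Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of mouse pup ultrasonic isolation calls:
    band-pass filtering and spectrogram-based syllable segmentation of
    375 kHz recordings, pitch-jump syllable classification into five
    types (noisy, tonal, single-jump, harmonic, multi-jump), parsing of
    syllable sequences into bouts from inter-syllable silence statistics,
    and information-theoretic analysis of sequence structure:
    Krichevsky-Trofimov smoothed joint distributions, bootstrap-debiased
    mutual information and Kullback-Leibler divergence with scrambled-
    sequence null models, positional mutual-information matrices,
    pair/triplet transition distributions, extraction of significant
    syllable sequences, and correlation-distance clustering of pups.
    Includes a synthetic-cohort generator with known Markov structure and
    ground-truth annotations so every stage is testable without
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
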