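Package: phagerecomb
Title: Recombination-Intensity Scanning for Phage Pan-Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects recombination-intense viral groups and genes in phage
    pan-genome data. Computes per-gene Hudson-Kaplan minimum recombination
    event counts (four-gamete test) and nucleotide diversity from gapped
    multiple sequence alignments, aggregates them per species-level viral
    group, flags groups and genes whose recombination intensity exceeds a
    regression-based expectation given diversity and sample size, and runs
    the categorical association battery linking recombination intensity to
    sample origin and host-bacterial immune-system frequencies. Includes a
    coalescent-style synthetic cohort generator with known recombination
    truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
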