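Package: evibnet
Title: Vibrational-Energy Diffusion Networks for Allosteric Modulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models allosteric communication in proteins as diffusion of
    vibrational energy on a residue-level continuous-time Markov chain.
    Builds the transition-frequency (generator) matrix from pairwise
    energy-exchange times, identifies metastable residue clusters by
    robust Perron cluster analysis (PCCA+), computes committors and
    reactive energy currents between clusters with transition path
    theory, and compares two liganded states of the same receptor via
    the relative current change (overall and per residue) to rank
    modulation hotspots. Includes a synthetic-data generator with
    planted metastable blocks and Monte-Carlo jump-chain oracles so the
    whole pipeline is testable without molecular-dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
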