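Package: padock
Title: Docking, Trajectory Analytics and Variant Evaluation for Polyamidase Engineering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational support for directed-evolution campaigns on
    polyamide-degrading hydrolases (nylonases). Builds flexible
    6-aminohexanoic-acid oligomer substrates and docks them into an enzyme
    pocket by incremental fragment growth with a Lennard-Jones plus Coulomb
    score; computes trajectory-derived statistics used to nominate and
    rationalise beneficial substitutions (per-residue contact frequencies
    and hotspot selection, hydrogen-bond and salt-bridge occupancies,
    interaction-energy decomposition conditioned on bond state, aromatic
    side-chain conformation classification); evaluates variant libraries
    (specific activities, fold-changes with error propagation, conventional
    and inverse Michaelis-Menten fits, degree of depolymerization, melting
    temperatures, epistasis classification); and profiles per-column
    conservation of family alignments. Ships synthetic-data generators with
    planted ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    minpack.lm,
    Biostrings
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
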