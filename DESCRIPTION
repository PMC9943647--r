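Package: bindpoly
Title: Binding-Polynomial Analysis of Protein-DNA Titrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Equilibrium binding analysis for a protein ligand binding a DNA
    molecule carrying three tandem recognition repeats. Implements the
    three-site binding polynomial with pairwise cooperativity, estimation of
    macroscopic association constants from mobility-shift (EMSA) titrations,
    bootstrap uncertainty and cooperativity-ratio verdicts, reduction to a
    per-site association constant under the identical-independent-site model,
    single-site hyperbolic affinity fits for EMSA and steady-state SPR data,
    dissociation-chase half-life estimation with a censored upper-bound rule,
    quantitative footprint densitometry, and seeded generators that emulate
    each experimental input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
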