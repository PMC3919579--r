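Package: rf3kin
Title: Equilibrium Binding and Rapid Kinetics of the RF3 Nucleotide Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for the guanine-nucleotide cycle of the
    bacterial translation termination factor RF3. Implements
    depletion-corrected (tight-binding) titration isotherms, an exact
    mass-action solver for two-ligand competition equilibria,
    competitor-corrected affinity estimation and ratio re-plots,
    1-3 exponential fitting of stopped-flow fluorescence transients with
    nested-model phase selection, first-order peptide-release fits, and a
    mass-action ODE model of the ribosome-dependent RF3 GTPase cycle.
    Includes a synthetic-data generator that emulates FRET-reported
    mant-nucleotide stopped-flow traces and fluorimeter titrations from
    ground-truth rate and equilibrium constants, for validation by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
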