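Package: mabpliers
Title: Mechanism-of-Action Analysis for Bivalent Anti-Tryptase Antibodies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the "molecular pliers" mechanism by which a
    bivalent IgG can dissociate the ring-shaped beta-tryptase tetramer.
    Implements the hinge-wingspan geometric model (relaxed/tense spans,
    reach and strain assessment, inhibition-class prediction for upper-hinge
    variants), a hydrogen-deuterium exchange (HDX-MS) analysis pipeline
    (isotope-envelope modelling, n-population binomial mixture fitting with
    F-test model selection, back-exchange correction, the duplicate-range
    differential-protection criterion, intrinsic exchange rates and
    empirical protection factors, residue-level consolidation), structural
    interface analytics (4 Angstrom contact maps, Shrake-Rupley solvent
    accessibility and buried surface area, anchor distances, Kabsch
    superposition RMSD), binding and inhibition curve fitting (reaction
    velocities, four-parameter logistic and bell-shaped hook fits, 1:1
    Langmuir kinetics, a minimal bivalent-avidity equilibrium simulator),
    and deterministic synthetic-data generators so every stage runs at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
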