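Package: tcassign
Title: Temperature-Coefficient-Assisted Amino-Acid-Type Recognition for
    NMR Resonance Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Supports backbone resonance assignment of intrinsically
    disordered proteins by combining chemical shifts with amide
    temperature coefficients. Reads Sparky peak lists acquired at
    several temperatures, tracks peaks across temperatures by
    minimum-cost assignment, computes per-interval temperature
    coefficients (ppb/K), assembles spin systems from triple-resonance
    experiments, classifies spin systems into amino-acid types with a
    linear discriminant model fitted either on the assigned part of the
    same protein or on a per-type chemical-shift statistics table
    (with automatic subset refitting for incomplete spin systems), and
    maps short spin-system chains onto the protein sequence by
    classification probability. Includes a synthetic-data generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
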