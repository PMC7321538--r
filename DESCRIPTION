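Package: photraits
Title: Leaf Photosynthetic Trait Derivation from Gas Exchange and
    Chlorophyll Fluorescence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Derives leaf photosynthetic traits from steady-state gas
    exchange and pulse-amplitude-modulated chlorophyll fluorescence
    records of the kind produced by a Li-6400 style open system.  Fits
    exponential light-response and Farquhar-type A-Ci models, computes
    PSII quenching parameters and the Valentini partition of electron
    transport into carboxylation and oxygenation streams, estimates
    mesophyll CO2 diffusion traits by the variable-J method together
    with Rubisco CO2/O2 specificity, partitions leaf nitrogen into
    carboxylation, bioenergetics and light-harvesting pools, and
    computes xanthophyll-cycle de-epoxidation indices.  Includes a
    synthetic-leaf generator emulating a three-level nitrogen-supply
    experiment for fully reproducible testing, plus treatment-level
    summaries with compact-letter significance displays.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr,
    jsonlite
Config/testthat/edition: 3
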